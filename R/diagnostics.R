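#' Discrete L2 error between two fields
#'
#' Cell-area-weighted L2 norm of the pointwise difference,
#' `sqrt(sum((a - b)^2) * h^2)`, a discrete approximation of the
#' domain-integrated L2 distance, comparable across grid resolutions on a
#' fixed physical domain.
#'
#' @param field_a,field_b matrices of identical shape.
#' @param h grid spacing.
#' @return Non-negative scalar.
#' @export
l2_error <- function(field_a, field_b, h) {
  if (!all(dim(field_a) == dim(field_b)))
    stop("fields must have identical shapes", call. = FALSE)
  sqrt(sum((field_a - field_b)^2) * h^2)
}

#' Fitted order of convergence
#'
#' Least-squares slope of `log(error)` against `log(h)`.
#'
#' @param h_values grid spacings (>= 3 values, positive).
#' @param errors corresponding errors (positive).
#' @return List with `order` (the slope), `fit_residual` (residual standard
#'   error of the log-log fit) and the fitted `intercept`.
#' @examples
#' convergence_order(c(4, 2, 1), c(16, 4, 1))$order   # exactly 2
#' @export
convergence_order <- function(h_values, errors) {
  if (length(h_values) < 3L || length(errors) != length(h_values))
    stop("need >= 3 matching (h, error) pairs", call. = FALSE)
  if (any(h_values <= 0) || any(errors <= 0))
    stop("h values and errors must be positive", call. = FALSE)
  fit <- stats::lm(log(errors) ~ log(h_values))
  # residual standard error computed directly: summary.lm warns on the
  # exact-power-law case (perfect fit), which is a legitimate input here
  sigma <- sqrt(sum(stats::residuals(fit)^2) / stats::df.residual(fit))
  list(order = unname(stats::coef(fit)[2]),
       fit_residual = sigma,
       intercept = unname(stats::coef(fit)[1]))
}

# restrict a fine-grid field (cell-centred) to a coarse grid with spacing
# ratio r = h_coarse / h_fine (integer).  For odd r the coarse cell centre
# coincides with a fine cell centre and is sampled; for even r it sits at a
# corner of four fine cells, whose average is taken.
restrict_field <- function(fine, r) {
  r <- as.integer(r)
  n <- nrow(fine) %/% r
  m <- ncol(fine) %/% r
  if (r == 1L) return(fine[seq_len(n), seq_len(m), drop = FALSE])
  if (r %% 2L == 1L) {
    idx <- r * (seq_len(n) - 1L) + (r + 1L) %/% 2L
    jdx <- r * (seq_len(m) - 1L) + (r + 1L) %/% 2L
    fine[idx, jdx, drop = FALSE]
  } else {
    i0 <- r * (seq_len(n) - 1L) + r %/% 2L
    j0 <- r * (seq_len(m) - 1L) + r %/% 2L
    (fine[i0, j0, drop = FALSE] + fine[i0 + 1L, j0, drop = FALSE] +
     fine[i0, j0 + 1L, drop = FALSE] + fine[i0 + 1L, j0 + 1L, drop = FALSE]) / 4
  }
}

#' Grid-convergence study of the stationary infected field
#'
#' Self-convergence study on a fixed physical domain: the system is
#' integrated to the same final time on a sequence of grid spacings, the
#' finest-grid infected field serves as the reference (restricted to each
#' coarser grid at cell centres), and the order of convergence is the
#' log-log slope of the L2 errors.
#'
#' All resolutions start from one continuum initial condition: the
#' homogeneous equilibrium plus a seeded random superposition of no-flux
#' cosine modes (resolvable on the coarsest grid), evaluated at each grid's
#' cell centres.  A smooth shared perturbation is essential — per-cell white
#' noise has no continuum limit and the runs would grow decorrelated
#' patterns.
#'
#' For the stochastic case the same noise path is used at every resolution
#' (common random numbers): per-step Gaussian increments are generated once
#' per step on the finest grid and block-averaged onto coarser grids.
#' Because the lattice noise intensity scales as `C_I = D_I/(dx dy)`,
#' block-averaging `r^2` fine cells reproduces the correctly scaled coarse
#' increment variance `2 C_I dt (h_fine/h)^2` exactly, with no ad hoc
#' rescaling.
#'
#' All runs share the time step dictated by the finest grid's stability
#' bound, so the measured order isolates the spatial discretisation.
#'
#' @param p an [epidemic_params()] object; `p$C_I > 0` gives the stochastic
#'   (common-random-numbers) study.
#' @param cfg_base a [sim_config()] for the coarsest grid of interest; its
#'   `nx * dx` fixes the physical domain, its `t_end` the common final time
#'   and its `seed` the perturbation/noise path.
#' @param h_list decreasing grid spacings; each must divide the domain and
#'   be an integer multiple of the smallest (reference) spacing.
#' @return An object of class `"convergence_report"`: list with `h_values`
#'   (the coarse spacings, excluding the reference), `l2_errors`,
#'   `fitted_order`, `fit_residual`, `stationary` flags per run and the
#'   reference spacing `h_ref`.
#' @export
convergence_study <- function(p, cfg_base, h_list = c(4, 2, 1, 0.5)) {
  h_list <- sort(h_list, decreasing = TRUE)
  L <- cfg_base$nx * cfg_base$dx
  h_ref <- h_list[length(h_list)]
  n_ref <- L / h_ref
  if (abs(n_ref - round(n_ref)) > 1e-9)
    stop("every h must divide the physical domain", call. = FALSE)
  ratios <- h_list / h_ref
  if (any(abs(ratios - round(ratios)) > 1e-9))
    stop("every h must be an integer multiple of the finest h", call. = FALSE)
  # common dt from the finest grid's stability bound (and cfg_base$dt cap)
  dmax <- max(p$D1, p$D2, p$D3)
  dt <- min(cfg_base$dt, if (dmax > 0) 0.9 * h_ref^2 / (4 * dmax) else Inf)
  seed <- if (is.null(cfg_base$seed)) 1L else cfg_base$seed
  mk_cfg <- function(h) sim_config(
    nx = round(L / h), ny = round(L / h), dx = h, dy = h, dt = dt,
    t_end = cfg_base$t_end, stationarity_tol = 0, seed = seed,
    init_amp = cfg_base$init_amp, record_every = cfg_base$record_every)
  cfg_ref <- mk_cfg(h_ref)

  # initial perturbation: a seeded random superposition of Neumann cosine
  # modes, evaluated analytically at each grid's cell centres.  Unlike
  # per-cell white noise this field is smooth and grid-independent, so the
  # runs share one continuum initial condition and self-convergence is
  # well defined.
  ss <- select_stable_equilibrium(p)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  M <- min(16L, round(L / h_list[1]))   # modes resolvable on the coarsest grid
  coef3 <- replicate(3, matrix(stats::runif((M + 1L)^2, -1, 1) / (M + 1L),
                               M + 1L, M + 1L), simplify = FALSE)
  pert_at <- function(h, coefs) {
    n <- round(L / h)
    xs <- (seq_len(n) - 0.5) * h
    Cm <- cos(outer(xs, (0:M) * pi / L))
    cfg_base$init_amp * (Cm %*% coefs %*% t(Cm))
  }
  n_fine <- cfg_ref$nx
  init_for <- function(h) {
    field_state(ss$S0 + pert_at(h, coef3[[1]]),
                ss$I0 + pert_at(h, coef3[[2]]),
                ss$R0 + pert_at(h, coef3[[3]]), t = 0)
  }
  noise_for <- function(r, cfg) {
    if (p$C_I == 0) return(NULL)
    sd_fine <- sqrt(2 * p$C_I * dt)
    force(r)
    function(cfg_, C_I_) {
      xi <- matrix(stats::rnorm(n_fine^2, sd = sd_fine), n_fine, n_fine)
      if (r == 1L) xi else block_average(xi, r)
    }
  }
  run_at <- function(h) {
    r <- as.integer(round(h / h_ref))
    cfg <- mk_cfg(h)
    # cfg carries the shared seed; the noise closure draws the fine-grid
    # sequence at every resolution, so the paths coincide step by step
    run_simulation(p, cfg, init = init_for(h), noise_fn = noise_for(r, cfg))
  }
  runs <- lapply(h_list, run_at)
  stationary <- vapply(runs, `[[`, logical(1), "stationary")
  I_ref <- runs[[length(runs)]]$state$I
  coarse <- seq_len(length(h_list) - 1L)
  errs <- vapply(coarse, function(i) {
    r <- as.integer(round(h_list[i] / h_ref))
    l2_error(runs[[i]]$state$I, restrict_field(I_ref, r), h_list[i])
  }, numeric(1))
  if (!all(stationary))
    warning("not all runs reached stationarity by t_end; ",
            "errors compare fields at the common final time", call. = FALSE)
  ord <- convergence_order(h_list[coarse], errs)
  structure(list(h_values = h_list[coarse], l2_errors = errs,
                 fitted_order = ord$order, fit_residual = ord$fit_residual,
                 stationary = stationary, h_ref = h_ref,
                 C_I = p$C_I, t_end = cfg_base$t_end),
            class = "convergence_report")
}

# mean over non-overlapping r x r blocks
block_average <- function(m, r) {
  n <- nrow(m) %/% r; k <- ncol(m) %/% r
  m <- m[seq_len(n * r), seq_len(k * r), drop = FALSE]
  # sum over rows within blocks, then columns
  rowg <- rep(seq_len(n), each = r)
  colg <- rep(seq_len(k), each = r)
  t(rowsum(t(rowsum(m, rowg)), colg)) / r^2
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence report (C_I=%g, t_end=%g, reference h=%g)\n",
              x$C_I, x$t_end, x$h_ref))
  for (i in seq_along(x$h_values))
    cat(sprintf("  h=%-6g L2 error = %.6g\n", x$h_values[i], x$l2_errors[i]))
  cat(sprintf("  fitted order = %.3f (log-log residual %.3g)\n",
              x$fitted_order, x$fit_residual))
  invisible(x)
}

#' Dominant wavenumber of a pattern
#'
#' Peak of the radially averaged power spectrum of the mean-subtracted
#' field, in the angular-wavenumber convention of a `cos(k x)` mode (a mode
#' `cos(0.6 x)` reports `k` near 0.6).  The field is mirrored in both
#' directions before the FFT so that the cosine modes compatible with
#' no-flux boundaries (`k = m pi / L`) are exact spectral lines; the radial
#' bin width is `pi / (n h)`.
#'
#' The estimate is flagged unreliable (rather than raising an error) when
#' the spectrum has no pronounced peak, as for a white-noise field: the
#' `reliable` flag requires the peak bin to carry at least five times the
#' median bin power.  A spatially flat field has no dominant mode and is an
#' error.
#'
#' @param field 2D numeric matrix.
#' @param h grid spacing.
#' @param var_floor spatial variance below which the field is considered
#'   flat.
#' @return List with `k_dominant`, `power_ratio` (peak / median bin power)
#'   and `reliable`.
#' @export
dominant_wavenumber <- function(field, h, var_floor = 1e-14) {
  v <- stats::var(as.vector(field))
  if (!is.finite(v) || v < var_floor)
    stop("no dominant mode: field is spatially flat", call. = FALSE)
  f <- field - mean(field)
  # even (mirror) extension -> Neumann cosine modes become periodic modes
  f <- rbind(f, f[rev(seq_len(nrow(f))), , drop = FALSE])
  f <- cbind(f, f[, rev(seq_len(ncol(f))), drop = FALSE])
  P <- Mod(stats::fft(f))^2
  n2 <- nrow(f); m2 <- ncol(f)
  kx <- 2 * pi * c(0:(n2 %/% 2), -((n2 - n2 %/% 2 - 1):1)) / (n2 * h)
  ky <- 2 * pi * c(0:(m2 %/% 2), -((m2 - m2 %/% 2 - 1):1)) / (m2 * h)
  kr <- sqrt(outer(kx^2, ky^2, `+`))
  dk <- pi / (nrow(field) * h)
  bin <- pmax(1L, as.integer(round(kr / dk)))
  pw <- tapply(as.vector(P), as.vector(bin), mean)
  ks <- as.numeric(names(pw)) * dk
  keep <- ks > 0 & ks <= pi / h   # up to the grid Nyquist
  pw <- pw[keep]; ks <- ks[keep]
  peak <- which.max(pw)
  ratio <- unname(pw[peak] / stats::median(pw))
  list(k_dominant = ks[peak], power_ratio = ratio, reliable = ratio >= 5)
}

#' Summary metrics of a pattern field
#'
#' Basic field statistics plus the dominant wavenumber (when defined).
#'
#' @param field 2D matrix (typically the stationary infected field).
#' @param h grid spacing.
#' @param var_floor variance below which the pattern is considered absent
#'   and `k_dominant` is `NA`.
#' @return List with `mean_I`, `var_I`, `min_I`, `max_I`, `k_dominant`,
#'   `k_reliable`.
#' @export
pattern_metrics <- function(field, h, var_floor = 1e-10) {
  v <- stats::var(as.vector(field))
  kd <- NA_real_; rel <- FALSE
  if (is.finite(v) && v >= var_floor) {
    dw <- dominant_wavenumber(field, h, var_floor = var_floor)
    kd <- dw$k_dominant; rel <- dw$reliable
  }
  list(mean_I = mean(field), var_I = v, min_I = min(field),
       max_I = max(field), k_dominant = kd, k_reliable = rel)
}
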