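#' Discrete Laplacian with no-flux boundaries
#'
#' Five-point stencil
#' `(f[i+1,j] + f[i-1,j] + f[i,j+1] + f[i,j-1] - 4 f[i,j]) / h^2`
#' with mirror ghost nodes at the boundary (the ghost cell duplicates the
#' boundary cell, the conservative zero-normal-flux closure).  The stencil
#' telescopes: the sum over all cells is exactly zero for any field, so pure
#' diffusion conserves mass to round-off.
#'
#' @param field 2D numeric matrix.
#' @param h grid spacing.
#' @return Matrix of the same shape.
#' @export
laplacian_no_flux <- function(field, h) {
  if (!is.matrix(field) || !all(is.finite(field)))
    stop("field must be a finite numeric matrix", call. = FALSE)
  n <- nrow(field); m <- ncol(field)
  (field[c(1L, seq_len(n - 1L)), , drop = FALSE] +
   field[c(seq_len(n - 1L) + 1L, n), , drop = FALSE] +
   field[, c(1L, seq_len(m - 1L)), drop = FALSE] +
   field[, c(seq_len(m - 1L) + 1L, m), drop = FALSE] -
   4 * field) / h^2
}

#' Gaussian noise increments for the infected field
#'
#' One Euler-Maruyama increment of the spatiotemporal white noise driving
#' the infected equation: independent Gaussians per lattice cell with mean 0
#' and variance `2 * C_I * dt`, the discrete counterpart of delta-correlated
#' noise of intensity `C_I`.  Draws from R's global RNG; seed beforehand
#' (or via `sim_config(seed = )` in [run_simulation()]) for reproducibility.
#'
#' @param cfg a [sim_config()] object (grid shape and `dt`).
#' @param C_I noise intensity (>= 0).
#' @return `nx` x `ny` matrix of increments (all zero when `C_I = 0`).
#' @export
noise_increments <- function(cfg, C_I) {
  if (C_I < 0) stop("C_I must be >= 0", call. = FALSE)
  if (C_I == 0) return(matrix(0, cfg$nx, cfg$ny))
  matrix(stats::rnorm(cfg$nx * cfg$ny, sd = sqrt(2 * C_I * cfg$dt)),
         cfg$nx, cfg$ny)
}

#' Construct a field state
#'
#' @param S,I,R 2D matrices of equal shape with non-negative entries.
#' @param t current time.
#' @param clipped running count of negative-density clip events.
#' @return Object of class `"field_state"`.
#' @export
field_state <- function(S, I, R, t = 0, clipped = 0L) {
  if (!all(dim(S) == dim(I)) || !all(dim(S) == dim(R)))
    stop("S, I, R must have identical shapes", call. = FALSE)
  if (!all(is.finite(S), is.finite(I), is.finite(R)))
    stop("fields must be finite", call. = FALSE)
  structure(list(S = S, I = I, R = R, t = t, clipped = as.integer(clipped)),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("Field state at t=%g on a %d x %d grid\n",
              x$t, nrow(x$I), ncol(x$I)))
  cat(sprintf("  I: mean %.5g, range [%.5g, %.5g], spatial var %.4g\n",
              mean(x$I), min(x$I), max(x$I), stats::var(as.vector(x$I))))
  if (x$clipped > 0) cat(sprintf("  %d negative-density clip events\n", x$clipped))
  invisible(x)
}

#' One explicit Euler / Euler-Maruyama step
#'
#' Advances the three fields by one time step: forward Euler for the
#' deterministic susceptible and recovered equations, Euler-Maruyama for the
#' infected equation (deterministic part times `dt` plus a
#' [noise_increments()] draw).  Negative densities, possible under noise,
#' are clipped to zero and counted.
#'
#' @param state a [field_state()].
#' @param p an [epidemic_params()] object.
#' @param cfg a [sim_config()] object; the explicit stability bound
#'   `dt <= dx^2/(4 max D)` is enforced.
#' @return The advanced `"field_state"`.
#' @export
em_step <- function(state, p, cfg) {
  check_cfl(p, cfg)
  rhs <- reaction_rhs(state$S, state$I, state$R, p)
  S <- state$S + cfg$dt * (rhs$F + p$D1 * laplacian_no_flux(state$S, cfg$dx))
  I <- state$I + cfg$dt * (rhs$G + p$D2 * laplacian_no_flux(state$I, cfg$dx)) +
    noise_increments(cfg, p$C_I)
  R <- state$R + cfg$dt * (rhs$H + p$D3 * laplacian_no_flux(state$R, cfg$dx))
  if (!all(is.finite(S), is.finite(I), is.finite(R))) {
    bad <- which(!is.finite(I), arr.ind = TRUE)
    if (!nrow(bad)) bad <- which(!is.finite(S) | !is.finite(R), arr.ind = TRUE)
    stop(sprintf("non-finite field value at t=%g (first bad cell: %d, %d)",
                 state$t + cfg$dt, bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  nclip <- sum(S < 0) + sum(I < 0) + sum(R < 0)
  if (nclip > 0) {
    S[S < 0] <- 0; I[I < 0] <- 0; R[R < 0] <- 0
  }
  field_state(S, I, R, t = state$t + cfg$dt,
              clipped = state$clipped + nclip)
}

#' Integrate the stochastic reaction-diffusion system to a stationary state
#'
#' Runs the explicit integrator from the homogeneous stable endemic
#' equilibrium perturbed by independent uniform noise in
#' `[-init_amp, init_amp]` per cell per field (seeded), until `t_end` or
#' until the relative L2 change of the infected field per unit time falls
#' below `cfg$stationarity_tol`.  With a positive growth band in the
#' dispersion relation the perturbation self-organises into a stationary
#' spatial pattern; otherwise it decays back to homogeneity.
#'
#' @param p an [epidemic_params()] object.
#' @param cfg a [sim_config()] object.
#' @param init optional `"field_state"` to start from instead of the
#'   perturbed equilibrium (used e.g. for manufactured-solution tests).
#' @param noise_fn optional function `(cfg, C_I)` replacing
#'   [noise_increments()] (used for common-random-number convergence
#'   studies); must return an `nx` x `ny` matrix.
#' @return A list of class `"sim_result"`: `state` (final
#'   [field_state()]), `summary` (data frame per snapshot: `t`, `mean_I`,
#'   `min_I`, `max_I`, `var_I`, `rel_change`), `stationary` (logical),
#'   `equilibrium`, `params`, `config`, and `clipped`.
#' @export
run_simulation <- function(p, cfg, init = NULL, noise_fn = NULL) {
  check_cfl(p, cfg)
  if (!is.null(cfg$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(cfg$seed)
  }
  ss <- NULL
  if (is.null(init)) {
    ss <- select_stable_equilibrium(p)
    n <- cfg$nx * cfg$ny
    pert <- function(v) matrix(v + stats::runif(n, -cfg$init_amp, cfg$init_amp),
                               cfg$nx, cfg$ny)
    state <- field_state(pert(ss$S0), pert(ss$I0), pert(ss$R0), t = 0)
  } else {
    state <- init
  }
  step_fn <- if (is.null(noise_fn)) {
    function(st) em_step(st, p, cfg)
  } else {
    # deterministic part via em_step at C_I = 0, noise supplied externally
    p0 <- update_params(p, C_I = 0)
    function(st) {
      st2 <- em_step(st, p0, cfg)
      I <- st2$I + noise_fn(cfg, p$C_I)
      nclip <- sum(I < 0)
      if (nclip > 0) I[I < 0] <- 0
      field_state(st2$S, I, st2$R, t = st2$t, clipped = st2$clipped + nclip)
    }
  }
  n_steps <- ceiling(cfg$t_end / cfg$dt)
  rec <- max(1L, cfg$record_every)
  snaps <- list()
  snap <- function(st, rel) data.frame(
    t = st$t, mean_I = mean(st$I), min_I = min(st$I), max_I = max(st$I),
    var_I = stats::var(as.vector(st$I)), rel_change = rel)
  snaps[[1]] <- snap(state, NA_real_)
  I_prev <- state$I; t_prev <- state$t
  stationary <- FALSE
  i <- 0L
  while (i < n_steps) {
    state <- tryCatch(step_fn(state), error = function(e) {
      stop(sprintf("integration aborted at t=%g: %s",
                   state$t, conditionMessage(e)), call. = FALSE)
    })
    i <- i + 1L
    if (i %% rec == 0L || i == n_steps) {
      dtspan <- state$t - t_prev
      rel <- sqrt(sum((state$I - I_prev)^2)) /
        max(sqrt(sum(I_prev^2)), .Machine$double.eps) / dtspan
      snaps[[length(snaps) + 1L]] <- snap(state, rel)
      if (cfg$stationarity_tol > 0 && rel < cfg$stationarity_tol) {
        stationary <- TRUE
        break
      }
      I_prev <- state$I; t_prev <- state$t
    }
  }
  structure(list(state = state, summary = do.call(rbind, snaps),
                 stationary = stationary, equilibrium = ss,
                 params = p, config = cfg, clipped = state$clipped),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Simulation result: t=%g (%s), %d x %d grid\n",
              x$state$t, if (x$stationary) "stationary" else "t_end reached",
              x$config$nx, x$config$ny))
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf("  I: mean %.5g, spatial var %.4g; %d clip events\n",
              last$mean_I, last$var_I, x$clipped))
  invisible(x)
}
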