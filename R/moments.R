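#' Second-order moment-evolution matrix
#'
#' Assembles the 9x9 matrix `A` governing the closed linear system
#' `dX/dt = A X` for the first and second moments of a spatial perturbation
#' of the homogeneous equilibrium at squared wavenumber `k2`, with state
#' ordering
#' \deqn{X = (\langle\delta S\rangle, \langle\delta I\rangle,
#'  \langle\delta R\rangle, \langle\delta S^2\rangle, \langle\delta I^2\rangle,
#'  \langle\delta R^2\rangle, \langle\delta S\delta I\rangle,
#'  \langle\delta S\delta R\rangle, \langle\delta I\delta R\rangle)^T.}
#' The system is obtained by expanding the reaction terms to second order
#' around the equilibrium, projecting onto a lattice mode with squared
#' wavenumber `k2`, statistically averaging, closing the moment hierarchy at
#' second order, and evaluating the noise-perturbation correlations (Novikov
#' identity for Gaussian noise), which places the noise intensity `C_I` at
#' exactly three positions: row 5 column 2 (`2 C_I`), row 7 column 1 and
#' row 9 column 3 (`C_I`).
#'
#' At `C_I = 0` the matrix is block triangular: the first-moment block
#' reduces to the classical linearisation `J - k2 * D` and the 6x6
#' second-moment block decouples, so the second-order spectrum contains the
#' linear Turing analysis as a special case.
#'
#' @param p an [epidemic_params()] object.
#' @param ss the steady state to perturb around (see
#'   [select_stable_equilibrium()]).
#' @param k2 squared wavenumber (>= 0).
#' @param C_I noise intensity; defaults to `p$C_I`.
#' @return An object of class `"moment_matrix"`: list with `entries`
#'   (9x9 matrix), `k2`, `C_I` and `coeffs` (the named coefficients,
#'   including the row sums `h1 = a1 + b2`, `h2 = a1 + c3`,
#'   `h3 = b2 + c3`).
#' @export
moment_matrix <- function(p, ss, k2, C_I = p$C_I) {
  if (k2 < 0) stop("k2 must be >= 0", call. = FALSE)
  if (C_I < 0) stop("C_I must be >= 0", call. = FALSE)
  cf <- reaction_coeffs(p, ss)
  a1 <- cf$a1 - k2 * p$D1
  a2 <- cf$a2; a3 <- cf$a3; a5 <- cf$a5; a7 <- cf$a7
  b1 <- cf$b1
  b2 <- cf$b2 - k2 * p$D2
  b5 <- -a5; b7 <- -a7
  c2 <- cf$c2
  c3 <- cf$c3 - k2 * p$D3
  h1 <- a1 + b2; h2 <- a1 + c3; h3 <- b2 + c3
  A <- matrix(c(
    a1,  a2,   a3, 0,    a5,   0,    a7,   0,  0,
    b1,  b2,   0,  0,    b5,   0,    b7,   0,  0,
    0,   c2,   c3, 0,    0,    0,    0,    0,  0,
    0,   0,    0,  2*a1, 0,    0,    2*a2, 2*a3, 0,
    0,   2*C_I, 0, 0,    2*b2, 0,    2*b1, 0,  0,
    0,   0,    0,  0,    0,    2*c3, 0,    0,  2*c2,
    C_I, 0,    0,  b1,   a2,   0,    h1,   0,  a3,
    0,   0,    0,  0,    0,    a3,   c2,   h2, a2,
    0,   0,    C_I, 0,   c2,   0,    0,    b1, h3),
    nrow = 9, byrow = TRUE)
  mom <- c("dS", "dI", "dR", "dS2", "dI2", "dR2", "dSdI", "dSdR", "dIdR")
  dimnames(A) <- list(mom, mom)
  structure(list(entries = A, k2 = k2, C_I = C_I,
                 coeffs = list(a1 = a1, a2 = a2, a3 = a3, a5 = a5, a7 = a7,
                               b1 = b1, b2 = b2, b5 = b5, b7 = b7,
                               c2 = c2, c3 = c3, h1 = h1, h2 = h2, h3 = h3)),
            class = "moment_matrix")
}

#' @export
print.moment_matrix <- function(x, ...) {
  cat(sprintf("9x9 moment-evolution matrix at k2=%g, C_I=%g\n", x$k2, x$C_I))
  print(signif(x$entries, 4))
  invisible(x)
}

# eigenvalue with maximal real part; ties on Re broken by smaller |Im|,
# then by smaller Im (so the member of a conjugate pair with negative
# imaginary part is reported deterministically)
max_eigenvalue <- function(A) {
  ev <- eigen(A, only.values = TRUE)$values
  ev[order(-Re(ev), abs(Im(ev)), Im(ev))[1]]
}

#' Eigenvalues of the linearised (first-order) spatial operator
#'
#' Spectrum of `J_D(k2) = J - k2 * D`, the classical linear Turing operator
#' with `J` the reaction Jacobian and `D = diag(D1, D2, D3)`.  Serves as the
#' independent linear-analysis reference for the second-order machinery: at
#' `C_I = 0` these eigenvalues form the first-moment part of the 9x9
#' spectrum.
#'
#' @param p an [epidemic_params()] object.
#' @param ss steady state.
#' @param k2 squared wavenumber (>= 0, scalar).
#' @return Complex vector of the three eigenvalues, sorted by decreasing
#'   real part.
#' @export
linear_dispersion <- function(p, ss, k2) {
  JD <- jacobian_matrix(p, ss) - k2 * diag(c(p$D1, p$D2, p$D3))
  ev <- eigen(JD, only.values = TRUE)$values
  ev[order(-Re(ev), abs(Im(ev)), Im(ev))]
}

#' Dispersion curve of the moment system
#'
#' Tracks the eigenvalue of the 9x9 moment matrix with maximal real part
#' over a grid of squared wavenumbers.  A band of `k2` where the real part
#' is positive signals instability of the homogeneous state; when the
#' crossing is non-oscillatory (zero imaginary part) it is a Turing-type
#' bifurcation producing stationary patterns.
#'
#' @param p an [epidemic_params()] object.
#' @param ss steady state; computed via [select_stable_equilibrium()] when
#'   `NULL`.
#' @param k2_grid increasing non-negative squared wavenumbers.
#' @param C_I noise intensity; defaults to `p$C_I`.
#' @return An object of class `"dispersion_curve"`: list with `k2_grid`,
#'   `re_lambda`, `im_lambda`, `unstable_band` (range of `k` — not `k2` —
#'   with positive real part from the grid scan, or `NULL`), and the
#'   parameters used.
#' @export
dispersion_curve <- function(p, ss = NULL, k2_grid = seq(0, 4, length.out = 401),
                             C_I = p$C_I) {
  if (is.unsorted(k2_grid) || any(k2_grid < 0))
    stop("k2_grid must be sorted and non-negative", call. = FALSE)
  if (is.null(ss)) ss <- select_stable_equilibrium(p)
  lam <- vapply(k2_grid, function(k2) {
    A <- moment_matrix(p, ss, k2, C_I)$entries
    lm <- tryCatch(max_eigenvalue(A), error = function(e)
      stop(sprintf("eigen decomposition failed at k2=%g: %s",
                   k2, conditionMessage(e)), call. = FALSE))
    c(Re(lm), Im(lm))
  }, numeric(2))
  re <- lam[1, ]; im <- lam[2, ]
  band <- NULL
  if (any(re > 0)) band <- sqrt(range(k2_grid[re > 0]))
  structure(list(k2_grid = k2_grid, re_lambda = re, im_lambda = im,
                 unstable_band = band, params = p, steady_state = ss,
                 C_I = C_I),
            class = "dispersion_curve")
}

#' @export
print.dispersion_curve <- function(x, ...) {
  cat(sprintf("Dispersion curve over %d k2 points (C_I=%g)\n",
              length(x$k2_grid), x$C_I))
  cat(sprintf("  max Re lambda = %.6g\n", max(x$re_lambda)))
  if (is.null(x$unstable_band)) cat("  no unstable band\n")
  else cat(sprintf("  unstable k band ~ [%.4f, %.4f]\n",
                   x$unstable_band[1], x$unstable_band[2]))
  invisible(x)
}

#' Turing threshold wavenumber
#'
#' Locates the smallest positive wavenumber at which the maximal eigenvalue
#' of the moment system crosses zero with vanishing imaginary part — the
#' onset of a stationary (Turing-type) instability.  The real part of the
#' maximal eigenvalue is scanned on a uniform k grid (step `dk` over
#' `(0, k_max]`) and the first sign change is refined by bisection to width
#' `1e-6` in k.  If the imaginary part at the crossing is non-zero the
#' crossing is oscillatory, not a Turing bifurcation, and is reported as
#' such.
#'
#' @param p an [epidemic_params()] object.
#' @param C_I noise intensity; defaults to `p$C_I`.
#' @param k_max upper end of the scanned k range.
#' @param dk coarse scan step in k.
#' @param ss steady state; computed when `NULL`.
#' @return An object of class `"turing_threshold"`: list with
#'   `k_threshold` (numeric, `NA` if no instability or oscillatory),
#'   `unstable_band` (length-2 `k` interval refined by bisection, or `NULL`),
#'   `oscillatory` (logical), and `max_re_lambda` over the scan.
#' @examples
#' \donttest{
#' th <- turing_threshold(epidemic_params())   # baseline: k ~ 0.574
#' }
#' @export
turing_threshold <- function(p, C_I = p$C_I, k_max = 2, dk = 1e-3, ss = NULL) {
  if (is.null(ss)) ss <- select_stable_equilibrium(p)
  f <- function(k) max_eigenvalue(moment_matrix(p, ss, k^2, C_I)$entries)
  ks <- seq(dk, k_max, by = dk)
  lam <- vapply(ks, f, complex(1))
  re <- Re(lam)
  pos <- which(re > 0)
  if (!length(pos))
    return(structure(list(k_threshold = NA_real_, unstable_band = NULL,
                          oscillatory = FALSE, max_re_lambda = max(re),
                          params = p, C_I = C_I),
                     class = "turing_threshold"))
  bisect <- function(lo, hi, rising) {
    # rising: Re lambda goes - to + across [lo, hi]
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      up <- Re(f(mid)) > 0
      if (up == rising) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  i_lo <- pos[1]
  k_lo <- if (i_lo == 1L) ks[1] else bisect(ks[i_lo - 1L], ks[i_lo], TRUE)
  i_hi <- pos[length(pos)]
  k_hi <- if (i_hi == length(ks)) ks[i_hi]
          else bisect(ks[i_hi], ks[i_hi + 1L], FALSE)
  lam_at <- f(k_lo)
  osc <- abs(Im(lam_at)) > 1e-6
  structure(list(k_threshold = if (osc) NA_real_ else k_lo,
                 unstable_band = c(k_lo, k_hi),
                 oscillatory = osc, max_re_lambda = max(re),
                 params = p, C_I = C_I),
            class = "turing_threshold")
}

#' @export
print.turing_threshold <- function(x, ...) {
  if (is.null(x$unstable_band)) {
    cat(sprintf("No instability for k in the scanned range (max Re lambda = %.4g)\n",
                x$max_re_lambda))
  } else if (x$oscillatory) {
    cat(sprintf("Oscillatory crossing at k ~ %.4f (not a Turing threshold)\n",
                x$unstable_band[1]))
  } else {
    cat(sprintf("Turing threshold k = %.4f; unstable band [%.4f, %.4f]\n",
                x$k_threshold, x$unstable_band[1], x$unstable_band[2]))
  }
  invisible(x)
}

#' Stability region in a parameter plane
#'
#' Maps the maximal real part of the moment-system eigenvalue over a 2D
#' parameter grid.  Two planes are supported:
#' \describe{
#'   \item{`"k2_D1"`}{the squared wavenumber against the susceptible
#'     diffusion coefficient: the equilibrium is independent of both axes,
#'     so each grid point is a single eigen problem.}
#'   \item{`"alpha_mu"`}{saturation against reinfection: the endemic
#'     equilibrium is re-solved at each grid point and the real part is
#'     maximised over an internal k scan.}
#' }
#' Grid points at which no stable endemic equilibrium exists are classified
#' `"undefined"`, distinct from `"stable"`/`"unstable"`.
#'
#' @param p_base baseline [epidemic_params()]; the plane axes override its
#'   fields.
#' @param plane `"k2_D1"` or `"alpha_mu"`.
#' @param x,y axis grids (increasing): `k2` and `D1` values, or `alpha` and
#'   `mu` values.
#' @param C_I noise intensity; defaults to `p_base$C_I`.
#' @param k_scan wavenumbers scanned internally per grid point for the
#'   `"alpha_mu"` plane (default 400 points over `(0, 2]`).
#' @return An object of class `"stability_diagram"`: list with `plane`,
#'   axis vectors `x`, `y`, matrix `max_re_lambda` (`length(x)` rows),
#'   logical `unstable_mask`, and character `status`
#'   (`"stable"`/`"unstable"`/`"undefined"`).
#' @export
stability_region <- function(p_base, plane = c("k2_D1", "alpha_mu"),
                             x, y, C_I = p_base$C_I,
                             k_scan = seq_len(400) / 400 * 2) {
  plane <- match.arg(plane)
  nx <- length(x); ny <- length(y)
  maxre <- matrix(NA_real_, nx, ny)
  if (plane == "k2_D1") {
    ss <- select_stable_equilibrium(p_base)
    for (j in seq_len(ny)) {
      pj <- update_params(p_base, D1 = y[j])
      for (i in seq_len(nx))
        maxre[i, j] <- Re(max_eigenvalue(moment_matrix(pj, ss, x[i], C_I)$entries))
    }
  } else {
    k2s <- k_scan^2
    for (j in seq_len(ny)) {
      for (i in seq_len(nx)) {
        pij <- update_params(p_base, alpha = x[i], mu = y[j])
        ss <- tryCatch(suppressWarnings(select_stable_equilibrium(pij)),
                       error = function(e) NULL)
        if (is.null(ss)) next   # stays NA -> undefined
        maxre[i, j] <- max(vapply(k2s, function(k2)
          Re(max_eigenvalue(moment_matrix(pij, ss, k2, C_I)$entries)),
          numeric(1)))
      }
    }
  }
  status <- matrix("undefined", nx, ny)
  status[!is.na(maxre) & maxre > 0] <- "unstable"
  status[!is.na(maxre) & maxre <= 0] <- "stable"
  structure(list(plane = plane, x = x, y = y, max_re_lambda = maxre,
                 unstable_mask = !is.na(maxre) & maxre > 0,
                 status = status, C_I = C_I, params = p_base),
            class = "stability_diagram")
}

#' @export
print.stability_diagram <- function(x, ...) {
  cat(sprintf("Stability diagram (%s plane, C_I=%g): %d x %d grid\n",
              x$plane, x$C_I, length(x$x), length(x$y)))
  tab <- table(factor(x$status, levels = c("stable", "unstable", "undefined")))
  cat(sprintf("  stable %d | unstable %d | undefined %d\n",
              tab["stable"], tab["unstable"], tab["undefined"]))
  invisible(x)
}
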