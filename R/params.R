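#' Model and noise parameters for the spatial SIRS model with reinfection
#'
#' Bundles the ten dimensionless parameters of the stochastic
#' reaction-diffusion SIRS system: demographic rates, the saturated-incidence
#' transmission law, reinfection, the three diffusion coefficients and the
#' lattice noise intensity.  Defaults are the baseline parameter set used
#' throughout the stability and pattern-formation analyses.
#'
#' The incidence force is \eqn{\beta_0 S I^2 / (1 + \alpha I^2)}: `beta0`
#' scales transmission and `alpha` the behavioural saturation that damps it
#' at high infected density.  `mu` is the rate at which recovered individuals
#' lose immunity and return to the susceptible pool, closing the
#' S -> I -> R -> S loop.  `C_I` is the per-lattice-cell intensity of the
#' spatiotemporal white noise driving the infected equation
#' (\eqn{C_I = D_I / (\Delta x \Delta y)} for continuum noise strength
#' \eqn{D_I}).
#'
#' @param b birth rate of susceptibles (> 0).
#' @param d death rate, common to all compartments (> 0).
#' @param beta0 transmission rate (> 0).
#' @param alpha saturation parameter (>= 0); `alpha = 0` recovers the
#'   unsaturated `S I^2` incidence.
#' @param mu reinfection (immunity-loss) rate, in `[0, 1]`.
#' @param gamma recovery rate (> 0).
#' @param D1,D2,D3 diffusion coefficients of S, I and R (>= 0).
#' @param C_I discrete noise intensity (>= 0).
#'
#' @return An object of class `"epidemic_params"`: a named list of the ten
#'   parameters.
#' @examples
#' p <- epidemic_params()            # baseline set
#' p2 <- epidemic_params(alpha = 2, mu = 0.1)
#' @export
epidemic_params <- function(b = 1, d = 1, beta0 = 35, alpha = 0, mu = 0,
                            gamma = 1.5, D1 = 10, D2 = 1, D3 = 0.2,
                            C_I = 0) {
  p <- list(b = b, d = d, beta0 = beta0, alpha = alpha, mu = mu,
            gamma = gamma, D1 = D1, D2 = D2, D3 = D3, C_I = C_I)
  validate_epidemic_params(p)
  structure(p, class = "epidemic_params")
}

validate_epidemic_params <- function(p) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("parameter '%s' must be a single finite number", nm),
           call. = FALSE)
  }
  for (nm in names(p)) num1(p[[nm]], nm)
  # b, d, beta0, gamma are positive rates in the epidemic model proper, but
  # zero is admitted here so that degenerate sub-models (e.g. pure diffusion
  # in scheme verification) can be expressed; operations whose mathematics
  # requires strict positivity (equilibria) check it themselves.
  nonneg <- c("b", "d", "beta0", "gamma", "alpha", "D1", "D2", "D3", "C_I")
  for (nm in nonneg) if (p[[nm]] < 0)
    stop(sprintf("parameter '%s' must be >= 0 (got %g)", nm, p[[nm]]),
         call. = FALSE)
  if (p$mu < 0 || p$mu > 1)
    stop(sprintf("parameter 'mu' must lie in [0, 1] (got %g)", p$mu),
         call. = FALSE)
  invisible(p)
}

#' @export
print.epidemic_params <- function(x, ...) {
  cat("Spatial SIRS model parameters\n")
  cat(sprintf("  kinetics : b=%g d=%g beta0=%g alpha=%g mu=%g gamma=%g\n",
              x$b, x$d, x$beta0, x$alpha, x$mu, x$gamma))
  cat(sprintf("  diffusion: D1=%g D2=%g D3=%g\n", x$D1, x$D2, x$D3))
  cat(sprintf("  noise    : C_I=%g\n", x$C_I))
  invisible(x)
}

#' Update a parameter set
#'
#' Returns a copy of `p` with the named fields replaced, re-validated.
#'
#' @param p an [epidemic_params()] object.
#' @param ... named scalar replacements, e.g. `alpha = 2, mu = 0.1`.
#' @return A new `"epidemic_params"` object.
#' @export
update_params <- function(p, ...) {
  repl <- list(...)
  bad <- setdiff(names(repl), names(p))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  p[names(repl)] <- repl
  validate_epidemic_params(p)
  structure(p, class = "epidemic_params")
}

#' Simulation configuration for the stochastic reaction-diffusion integrator
#'
#' Grid, time-stepping, stopping and reproducibility settings for
#' [run_simulation()].  Defaults mirror the reference numerical setup:
#' a 200 x 200 grid with unit spacing and time step 0.01.
#'
#' The explicit scheme is stable only for
#' `dt <= dx^2 / (4 * max(D1, D2, D3))`; this is enforced (with an error)
#' when a simulation is launched, since it depends on the diffusion
#' coefficients.
#'
#' @param nx,ny grid points per side (>= 3).
#' @param dx,dy grid spacing.
#' @param dt time step.
#' @param t_end final time; integration stops earlier if the stationarity
#'   criterion is met.
#' @param stationarity_tol relative L2 change of the infected field per unit
#'   time below which the run is declared stationary.  Set to 0 to always
#'   integrate to `t_end`.
#' @param seed RNG seed (integer) used for the initial perturbation and the
#'   noise path; `NULL` leaves the current RNG state untouched.
#' @param init_amp amplitude of the uniform initial perturbation applied to
#'   each field around the homogeneous equilibrium.
#' @param record_every number of steps between diagnostic snapshots
#'   (and stationarity checks).
#'
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(nx = 200, ny = 200, dx = 1, dy = 1, dt = 0.01,
                       t_end = 200, stationarity_tol = 1e-6, seed = NULL,
                       init_amp = 1e-2, record_every = 100L) {
  if (nx < 3 || ny < 3) stop("nx and ny must be >= 3", call. = FALSE)
  if (dx <= 0 || dy <= 0 || dt <= 0 || t_end <= 0)
    stop("dx, dy, dt and t_end must be > 0", call. = FALSE)
  if (dx != dy)
    stop("only square cells are supported (dx must equal dy)", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx, dy = dy,
                 dt = dt, t_end = t_end,
                 stationarity_tol = stationarity_tol, seed = seed,
                 init_amp = init_amp, record_every = as.integer(record_every)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d x %d grid, dx=%g, dt=%g, t_end=%g\n",
              x$nx, x$ny, x$dx, x$dt, x$t_end))
  cat(sprintf("  init_amp=%g, stationarity_tol=%g, record_every=%d, seed=%s\n",
              x$init_amp, x$stationarity_tol, x$record_every,
              if (is.null(x$seed)) "none" else as.character(x$seed)))
  invisible(x)
}

# explicit-scheme stability bound; error when violated
check_cfl <- function(p, cfg) {
  dmax <- max(p$D1, p$D2, p$D3)
  if (dmax > 0) {
    lim <- cfg$dx^2 / (4 * dmax)
    if (cfg$dt > lim)
      stop(sprintf(paste0("time step dt=%g violates the explicit stability ",
                          "bound dx^2/(4*max(D)) = %g"), cfg$dt, lim),
           call. = FALSE)
  }
  invisible(TRUE)
}
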