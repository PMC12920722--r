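#' Saturated incidence force
#'
#' The nonlinear force of infection acting on susceptibles,
#' \eqn{\beta_0 S I^2 / (1 + \alpha I^2)}.  For `alpha > 0` it saturates:
#' it is bounded above by `beta0 * S / alpha` however large the infected
#' density grows, modelling behavioural inhibition of spread.
#'
#' @param S,I susceptible and infected densities (>= 0, vectorised).
#' @param p an [epidemic_params()] object.
#' @return The incidence rate, same shape as `S`/`I`.
#' @examples
#' p <- epidemic_params(beta0 = 35, alpha = 2)
#' incidence_force(0.5, 1, p)   # 35 * 0.5 / 3
#' @export
incidence_force <- function(S, I, p) {
  if (any(S < 0) || any(I < 0))
    stop("densities S and I must be non-negative", call. = FALSE)
  p$beta0 * S * I^2 / (1 + p$alpha * I^2)
}

#' Reaction rates of the SIRS-with-reinfection kinetics
#'
#' Evaluates the three reaction terms (the right-hand sides with diffusion
#' and noise stripped off):
#' \deqn{F = b - dS - \beta_0 S I^2/(1+\alpha I^2) + \mu R}
#' \deqn{G = \beta_0 S I^2/(1+\alpha I^2) - (\gamma + d) I}
#' \deqn{H = \gamma I - (\mu + d) R}
#' The incidence, recovery and reinfection fluxes cancel in the sum, so
#' `F + G + H = b - d (S + I + R)` holds identically.
#'
#' @param S,I,R compartment densities (>= 0, vectorised; shapes must match).
#' @param p an [epidemic_params()] object.
#' @return A list with components `F`, `G`, `H`.
#' @export
reaction_rhs <- function(S, I, R, p) {
  if (any(S < 0) || any(I < 0) || any(R < 0))
    stop("densities must be non-negative", call. = FALSE)
  inc <- p$beta0 * S * I^2 / (1 + p$alpha * I^2)
  list(F = p$b - p$d * S - inc + p$mu * R,
       G = inc - (p$gamma + p$d) * I,
       H = p$gamma * I - (p$mu + p$d) * R)
}

new_steady_state <- function(S0, I0, R0, stable) {
  structure(list(S0 = S0, I0 = I0, R0 = R0, stable = stable),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Homogeneous steady state: S0=%.6g I0=%.6g R0=%.6g (%s)\n",
              x$S0, x$I0, x$R0, if (x$stable) "stable" else "unstable"))
  invisible(x)
}

#' Endemic equilibria of the homogeneous system
#'
#' All spatially homogeneous steady states with positive infected density.
#' Setting the reaction terms to zero and eliminating S and R (the infected
#' balance gives \eqn{S_0 = (\gamma+d)(1+\alpha I_0^2)/(\beta_0 I_0)}, the
#' recovered balance \eqn{R_0 = \gamma I_0/(\mu+d)}, and summing the three
#' equations forces \eqn{S_0 + I_0 + R_0 = b/d}) reduces the steady-state
#' problem exactly to a quadratic in \eqn{I_0}:
#' \deqn{\left[\alpha(\gamma+d) + \beta_0\frac{\mu+d+\gamma}{\mu+d}\right]
#'       I_0^2 - \frac{\beta_0 b}{d} I_0 + (\gamma + d) = 0,}
#' so the endemic roots are enumerated completely and exactly rather than by
#' generic root-finding.  There are two, one (a double root) or zero endemic
#' equilibria depending on the discriminant.
#'
#' Each returned state is tagged with its local (ODE, i.e. zero-wavenumber,
#' noise-free) stability: `stable` is `TRUE` when all eigenvalues of the
#' reaction Jacobian have negative real part.
#'
#' @param p an [epidemic_params()] object.
#' @return A list of `"steady_state"` objects, ordered by increasing `I0`;
#'   empty when no endemic equilibrium exists.
#' @examples
#' eq <- endemic_equilibria(epidemic_params())
#' length(eq)   # 2 for the baseline parameters
#' @export
endemic_equilibria <- function(p) {
  if (p$b <= 0 || p$d <= 0 || p$beta0 <= 0 || p$gamma <= 0)
    stop("endemic equilibria require strictly positive b, d, beta0, gamma",
         call. = FALSE)
  A <- p$alpha * (p$gamma + p$d) +
    p$beta0 * (p$mu + p$d + p$gamma) / (p$mu + p$d)
  B <- -p$beta0 * p$b / p$d
  C <- p$gamma + p$d
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(list())
  I_roots <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  I_roots <- unique(I_roots[I_roots > 0])
  lapply(I_roots, function(I0) {
    S0 <- (p$gamma + p$d) * (1 + p$alpha * I0^2) / (p$beta0 * I0)
    R0 <- p$gamma * I0 / (p$mu + p$d)
    ss <- new_steady_state(S0, I0, R0, stable = NA)
    res <- unlist(reaction_rhs(S0, I0, R0, p))
    if (max(abs(res)) > 1e-10 * max(1, p$b, p$beta0))
      stop("equilibrium residual exceeds tolerance; parameters ill-scaled",
           call. = FALSE)
    J <- jacobian_matrix(p, ss)
    ss$stable <- max(Re(eigen(J, only.values = TRUE)$values)) < 0
    ss
  })
}

#' Select the stable endemic equilibrium
#'
#' Returns the endemic root around which the stability and pattern analyses
#' are performed: the one whose reaction Jacobian (no diffusion, no noise)
#' has all eigenvalues in the left half plane.  If both endemic roots are
#' stable (bistability) the one with larger infected density is chosen, with
#' a warning.
#'
#' @param p an [epidemic_params()] object.
#' @return A `"steady_state"` object with `stable = TRUE`.
#' @export
select_stable_equilibrium <- function(p) {
  eq <- endemic_equilibria(p)
  if (length(eq) == 0L)
    stop("no endemic equilibrium for these parameters", call. = FALSE)
  stab <- vapply(eq, function(s) isTRUE(s$stable), logical(1))
  if (!any(stab))
    stop("no stable endemic equilibrium for these parameters", call. = FALSE)
  if (sum(stab) > 1L)
    warning("both endemic equilibria are stable; selecting the one with ",
            "larger I0", call. = FALSE)
  idx <- which(stab)
  eq[[idx[length(idx)]]]   # roots are sorted by I0
}

# named linearisation coefficients at a steady state; k2-independent parts.
# a1/b2/c3 returned WITHOUT their -k^2 D terms (added where needed).
reaction_coeffs <- function(p, ss) {
  q <- 1 + p$alpha * ss$I0^2
  a2 <- -2 * p$beta0 * ss$S0 * ss$I0 / q^2
  list(a1 = -(p$d + p$beta0 * ss$I0^2 / q),
       a2 = a2,
       a3 = p$mu,
       a5 = -p$beta0 * ss$S0 * (1 - 3 * p$alpha * ss$I0^2) / q^3,
       a7 = -2 * p$beta0 * ss$I0 / q^2,
       b1 = p$beta0 * ss$I0^2 / q,
       b2 = -(p$gamma + p$d + a2),
       c2 = p$gamma,
       c3 = -(p$mu + p$d))
}

#' Reaction Jacobian at a steady state
#'
#' The 3x3 Jacobian of the reaction terms (no diffusion) evaluated at
#' `ss`, rows ordered (S, I, R).  Its third row is `[0, gamma, -(mu + d)]`
#' for any parameters since the recovered equation is linear.
#'
#' @param p an [epidemic_params()] object.
#' @param ss a `"steady_state"` (or any list with `S0`, `I0`, `R0`).
#' @return A 3x3 numeric matrix.
#' @export
jacobian_matrix <- function(p, ss) {
  cf <- reaction_coeffs(p, ss)
  matrix(c(cf$a1, cf$a2, cf$a3,
           cf$b1, cf$b2, 0,
           0,     cf$c2, cf$c3),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("S", "I", "R"), c("S", "I", "R")))
}

#' Second-order expansion coefficients
#'
#' The non-vanishing second partial derivatives of the reaction terms at a
#' steady state, as they enter the second-order (moment-closure) analysis:
#' `a5 = (1/2) F_II`, `a7 = F_SI`, and their counterparts in the infected
#' equation `b5 = -a5`, `b7 = -a7` (the incidence term enters F and G with
#' opposite signs).  F and G are linear in S and H is fully linear, so
#' `F_SS`, `G_SS` and all other second derivatives vanish.
#'
#' @param p an [epidemic_params()] object.
#' @param ss a `"steady_state"`.
#' @return A list with components `a5`, `a7`, `b5`, `b7`.
#' @export
second_order_coeffs <- function(p, ss) {
  cf <- reaction_coeffs(p, ss)
  list(a5 = cf$a5, a7 = cf$a7, b5 = -cf$a5, b7 = -cf$a7)
}
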