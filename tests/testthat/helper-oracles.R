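# shared oracles and generators, independent of the implementation paths
# they check

# random admissible parameter draw (seed controlled by the caller)
draw_params <- function() {
  epidemic_params(b = runif(1, 0.5, 2), d = runif(1, 0.5, 2),
                  beta0 = runif(1, 5, 50), alpha = runif(1, 0, 3),
                  mu = runif(1, 0, 1), gamma = runif(1, 0.5, 3),
                  D1 = runif(1, 0, 15), D2 = runif(1, 0.1, 2),
                  D3 = runif(1, 0.05, 1), C_I = runif(1, 0, 0.2))
}

# random positive state (not necessarily an equilibrium)
draw_state <- function() {
  list(S0 = runif(1, 0.05, 2), I0 = runif(1, 0.05, 2),
       R0 = runif(1, 0.05, 2))
}

# central finite-difference Jacobian of the reaction terms at a state
fd_jacobian <- function(p, st, h = 1e-6) {
  x0 <- c(st$S0, st$I0, st$R0)
  f <- function(x) unlist(reaction_rhs(x[1], x[2], x[3], p))
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    hp <- h * max(1, abs(x0[j]))
    xp <- x0; xp[j] <- xp[j] + hp
    xm <- x0; xm[j] <- xm[j] - hp
    J[, j] <- (f(xp) - f(xm)) / (2 * hp)
  }
  J
}

# finite-difference second derivatives of F: (1/2) F_II and F_SI
fd_second_order <- function(p, st, h = 1e-4) {
  Ff <- function(S, I) reaction_rhs(S, I, st$R0, p)$F
  S0 <- st$S0; I0 <- st$I0
  hI <- h * max(1, abs(I0)); hS <- h * max(1, abs(S0))
  F_II <- (Ff(S0, I0 + hI) - 2 * Ff(S0, I0) + Ff(S0, I0 - hI)) / hI^2
  F_SI <- (Ff(S0 + hS, I0 + hI) - Ff(S0 + hS, I0 - hI) -
           Ff(S0 - hS, I0 + hI) + Ff(S0 - hS, I0 - hI)) / (4 * hS * hI)
  list(half_F_II = F_II / 2, F_SI = F_SI)
}

# quadratic-in-I0 oracle for the endemic equilibria, assembled from scratch
endemic_I_roots <- function(p) {
  A <- p$alpha * (p$gamma + p$d) + p$beta0 * (p$mu + p$d + p$gamma) / (p$mu + p$d)
  B <- -p$beta0 * p$b / p$d
  C <- p$gamma + p$d
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(numeric(0))
  sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
}

# brute-force single explicit step on a small grid: plain loops, mirror
# ghost cells duplicating the boundary cell
brute_step <- function(S, I, R, p, dt, h) {
  n <- nrow(S); m <- ncol(S)
  gi <- function(f, i, j) f[min(max(i, 1L), n), min(max(j, 1L), m)]
  lap <- function(f, i, j)
    (gi(f, i + 1L, j) + gi(f, i - 1L, j) + gi(f, i, j + 1L) +
     gi(f, i, j - 1L) - 4 * f[i, j]) / h^2
  Sn <- S; In <- I; Rn <- R
  for (i in seq_len(n)) for (j in seq_len(m)) {
    inc <- p$beta0 * S[i, j] * I[i, j]^2 / (1 + p$alpha * I[i, j]^2)
    Sn[i, j] <- S[i, j] + dt * (p$b - p$d * S[i, j] - inc + p$mu * R[i, j] +
                                p$D1 * lap(S, i, j))
    In[i, j] <- I[i, j] + dt * (inc - (p$gamma + p$d) * I[i, j] +
                                p$D2 * lap(I, i, j))
    Rn[i, j] <- R[i, j] + dt * (p$gamma * I[i, j] - (p$mu + p$d) * R[i, j] +
                                p$D3 * lap(R, i, j))
  }
  list(S = Sn, I = In, R = Rn)
}

base_params <- function(...) epidemic_params(...)
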