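test_that("no-flux Laplacian annihilates constants and conserves mass exactly", {
  expect_equal(laplacian_no_flux(matrix(3.7, 8, 5), h = 0.5),
               matrix(0, 8, 5))
  set.seed(5)
  for (i in 1:10) {
    f <- matrix(rnorm(12 * 9), 12, 9)
    expect_equal(sum(laplacian_no_flux(f, h = 1.3)), 0, tolerance = 1e-13)
  }
})

test_that("no-flux Laplacian has the cosine modes as discrete eigenfunctions", {
  n <- 40; h <- 0.7; L <- n * h
  xs <- (seq_len(n) - 0.5) * h
  for (mode in list(c(3, 0), c(1, 5), c(7, 2))) {
    kx <- mode[1] * pi / L; ky <- mode[2] * pi / L
    f <- outer(cos(kx * xs), cos(ky * xs))
    lam <- -(4 / h^2) * (sin(kx * h / 2)^2 + sin(ky * h / 2)^2)
    expect_equal(laplacian_no_flux(f, h), lam * f, tolerance = 1e-12)
  }
})

test_that("noise increments have the Euler-Maruyama variance and are seed-reproducible", {
  cfg <- sim_config(nx = 100, ny = 100, dt = 0.01)
  expect_identical(noise_increments(cfg, 0), matrix(0, 100, 100))
  C_I <- 8e-2
  set.seed(99)
  draws <- replicate(100, as.vector(noise_increments(cfg, C_I)))
  expect_equal(var(as.vector(draws)), 2 * C_I * cfg$dt, tolerance = 0.01)
  expect_equal(mean(draws), 0, tolerance = 1e-4)
  set.seed(123); a <- noise_increments(cfg, C_I)
  set.seed(123); b <- noise_increments(cfg, C_I)
  expect_identical(a, b)
})

test_that("a single step reproduces the brute-force update on a small grid", {
  set.seed(17)
  p <- epidemic_params(alpha = 0.8, mu = 0.3, D1 = 2, D2 = 0.5, D3 = 0.1,
                       C_I = 0)
  cfg <- sim_config(nx = 3, ny = 3, dx = 1, dt = 0.01)
  S <- matrix(runif(9, 0.5, 1.5), 3, 3)
  I <- matrix(runif(9, 0.1, 0.6), 3, 3)
  R <- matrix(runif(9, 0.1, 0.6), 3, 3)
  out <- em_step(field_state(S, I, R), p, cfg)
  ref <- brute_step(S, I, R, p, cfg$dt, cfg$dx)
  expect_equal(out$S, ref$S, tolerance = 1e-14)
  expect_equal(out$I, ref$I, tolerance = 1e-14)
  expect_equal(out$R, ref$R, tolerance = 1e-14)
  expect_equal(out$t, 0.01)
})

test_that("the homogeneous equilibrium is a fixed point of the deterministic step", {
  p <- epidemic_params()
  ss <- select_stable_equilibrium(p)
  st <- field_state(matrix(ss$S0, 6, 6), matrix(ss$I0, 6, 6),
                    matrix(ss$R0, 6, 6))
  out <- em_step(st, p, sim_config(nx = 6, ny = 6, dt = 0.01))
  expect_equal(out$I, st$I, tolerance = 1e-14)
  expect_equal(out$S, st$S, tolerance = 1e-14)
  expect_equal(out$R, st$R, tolerance = 1e-14)
})

test_that("pure diffusion conserves mass of every field per step", {
  p <- epidemic_params(b = 0, d = 0, beta0 = 0, gamma = 0, mu = 0,
                       D1 = 2, D2 = 1, D3 = 0.5, C_I = 0)
  cfg <- sim_config(nx = 16, ny = 16, dt = 0.01)
  set.seed(3)
  st <- field_state(matrix(runif(256, 0.5, 1.5), 16, 16),
                    matrix(runif(256, 0.5, 1.5), 16, 16),
                    matrix(runif(256, 0.5, 1.5), 16, 16))
  for (i in 1:20) {
    nxt <- em_step(st, p, cfg)
    expect_equal(sum(nxt$S), sum(st$S), tolerance = 1e-12)
    expect_equal(sum(nxt$I), sum(st$I), tolerance = 1e-12)
    expect_equal(sum(nxt$R), sum(st$R), tolerance = 1e-12)
    st <- nxt
  }
})

test_that("the explicit stability bound is enforced", {
  p <- epidemic_params(D1 = 10)
  expect_error(em_step(field_state(matrix(1, 4, 4), matrix(1, 4, 4),
                                   matrix(1, 4, 4)),
                       p, sim_config(nx = 4, ny = 4, dt = 0.5)),
               "stability bound")
})

test_that("negative densities are clipped and counted", {
  p <- epidemic_params(b = 0, d = 0, beta0 = 0, gamma = 0, mu = 0,
                       D1 = 0, D2 = 0, D3 = 0, C_I = 50)
  cfg <- sim_config(nx = 20, ny = 20, dt = 0.01, seed = 2)
  set.seed(2)
  st <- field_state(matrix(1, 20, 20), matrix(1e-4, 20, 20),
                    matrix(1, 20, 20))
  out <- em_step(st, p, cfg)
  expect_gt(out$clipped, 0)
  expect_true(all(out$I >= 0))
})

test_that("seeded stochastic runs are bit-reproducible", {
  p <- epidemic_params(C_I = 8e-2)
  cfg <- sim_config(nx = 24, ny = 24, t_end = 1, seed = 77,
                    record_every = 20)
  r1 <- run_simulation(p, cfg)
  r2 <- run_simulation(p, cfg)
  expect_identical(r1$state$S, r2$state$S)
  expect_identical(r1$state$I, r2$state$I)
  expect_identical(r1$state$R, r2$state$R)
  expect_identical(r1$summary, r2$summary)
})

test_that("pattern and no-pattern outcomes agree with the sign of the growth rate", {
  pts <- expand.grid(alpha = c(0, 0.5, 2), mu = c(0, 0.1, 0.3))
  pts <- pts[!(pts$alpha == 0 & pts$mu == 0), ]   # 8 remaining combinations
  # horizon: the smallest |growth rate| over the sample is ~0.04, so t = 150
  # provides > 10 e-foldings for every point
  cfg <- sim_config(nx = 64, ny = 64, t_end = 150, seed = 12,
                    record_every = 500)
  for (r in seq_len(nrow(pts))) {
    p <- epidemic_params(alpha = pts$alpha[r], mu = pts$mu[r])
    lam <- turing_threshold(p)$max_re_lambda
    res <- run_simulation(p, cfg)
    v0 <- res$summary$var_I[1]
    v1 <- res$summary$var_I[nrow(res$summary)]
    if (lam > 0) {
      expect_gt(v1, 10 * v0,
                label = sprintf("final var (alpha=%g mu=%g, growing)",
                                pts$alpha[r], pts$mu[r]))
    } else {
      expect_lt(v1, v0,
                label = sprintf("final var (alpha=%g mu=%g, damped)",
                                pts$alpha[r], pts$mu[r]))
    }
  }
})

test_that("an unperturbed equilibrium stays homogeneous over many steps", {
  p <- epidemic_params()
  ss <- select_stable_equilibrium(p)
  cfg <- sim_config(nx = 16, ny = 16, dt = 0.01, t_end = 100,
                    stationarity_tol = 0, record_every = 10000)
  init <- field_state(matrix(ss$S0, 16, 16), matrix(ss$I0, 16, 16),
                      matrix(ss$R0, 16, 16))
  res <- run_simulation(p, cfg, init = init)   # 10^4 deterministic steps
  expect_lt(max(abs(res$state$I - ss$I0)), 1e-10)
  expect_lt(max(abs(res$state$S - ss$S0)), 1e-10)
  expect_equal(res$summary$var_I[nrow(res$summary)], 0, tolerance = 1e-24)
})
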