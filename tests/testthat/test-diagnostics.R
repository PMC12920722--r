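test_that("L2 error matches closed forms and the cell-area scaling", {
  a <- matrix(rnorm(64), 8, 8)
  expect_identical(l2_error(a, a, 0.5), 0)
  b <- a + 0.3
  expect_equal(l2_error(a, b, 0.5), 0.3 * 0.5 * 8, tolerance = 1e-14)
  # same pointwise difference, half the spacing -> half the error
  expect_equal(l2_error(a, b, 0.25), l2_error(a, b, 0.5) / 2)
  expect_error(l2_error(a, matrix(0, 4, 4), 1), "shape")
})

test_that("convergence order recovers exact power laws and tolerates jitter", {
  h <- c(4, 2, 1, 0.5)
  expect_equal(convergence_order(h, 3 * h^2)$order, 2, tolerance = 1e-12)
  expect_equal(convergence_order(h, 0.7 * h)$order, 1, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    jit <- runif(length(h), 0.95, 1.05)
    expect_true(abs(convergence_order(h, 2 * h^2 * jit)$order - 2) < 0.1)
  }
  expect_error(convergence_order(c(1, 2), c(1, 2)), ">= 3")
  expect_error(convergence_order(h, c(-1, 1, 1, 1)), "positive")
})

test_that("restriction picks cell centres (odd ratio) and corner means (even ratio)", {
  fine <- matrix(seq_len(36), 6, 6)
  r3 <- sirsTuring:::restrict_field(fine, 3L)
  expect_equal(dim(r3), c(2L, 2L))
  expect_equal(r3[1, 1], fine[2, 2])
  expect_equal(r3[2, 2], fine[5, 5])
  r2 <- sirsTuring:::restrict_field(fine, 2L)
  expect_equal(r2[1, 1], mean(fine[1:2, 1:2]))
  ba <- sirsTuring:::block_average(fine, 2L)
  expect_equal(ba[1, 1], mean(fine[1:2, 1:2]))
  expect_equal(ba[3, 3], mean(fine[5:6, 5:6]))
})

test_that("dominant wavenumber recovers a pure cosine mode and flags noise", {
  n <- 100; h <- 1
  xs <- (seq_len(n) - 0.5) * h
  f <- outer(cos(0.6 * xs), rep(1, n))
  dw <- dominant_wavenumber(f, h)
  expect_equal(dw$k_dominant, 0.6, tolerance = pi / (n * h) + 1e-9)
  expect_true(dw$reliable)
  set.seed(14)
  wn <- matrix(rnorm(n * n), n, n)
  dwn <- dominant_wavenumber(wn, h)
  expect_false(dwn$reliable)
  expect_error(dominant_wavenumber(matrix(1, 10, 10), 1), "flat")
})

test_that("pattern metrics summarise a field and mark absent patterns", {
  n <- 50; xs <- (seq_len(n) - 0.5)
  f <- 0.3 + 0.1 * outer(cos(0.5 * xs), cos(0.5 * xs))
  pm <- pattern_metrics(f, 1)
  expect_equal(pm$mean_I, mean(f))
  expect_gt(pm$k_dominant, 0)
  flat <- pattern_metrics(matrix(0.3, n, n), 1)
  expect_true(is.na(flat$k_dominant))
})

test_that("a manufactured diffusion problem converges at second order", {
  # pure diffusion of a Neumann cosine mode; exact solution known
  D <- 1; L <- 64; m <- 6; k1 <- m * pi / L; T_end <- 10; dt <- 2e-3
  p <- epidemic_params(b = 0, d = 0, beta0 = 0, gamma = 0, mu = 0,
                       D1 = 0, D2 = D, D3 = 0, C_I = 0)
  err <- vapply(c(2, 1, 0.5), function(h) {
    n <- L / h
    xs <- (seq_len(n) - 0.5) * h
    I0 <- 1 + 0.5 * outer(cos(k1 * xs), cos(k1 * xs))
    cfg <- sim_config(nx = n, ny = n, dx = h, dy = h, dt = dt, t_end = T_end,
                      stationarity_tol = 0, record_every = 5000)
    res <- run_simulation(p, cfg,
                          init = field_state(matrix(1, n, n), I0,
                                             matrix(1, n, n)))
    exact <- 1 + 0.5 * exp(-2 * D * k1^2 * T_end) * outer(cos(k1 * xs),
                                                          cos(k1 * xs))
    l2_error(res$state$I, exact, h)
  }, numeric(1))
  ord <- convergence_order(c(2, 1, 0.5), err)$order
  expect_gt(ord, 1.8)
  expect_lt(ord, 2.2)
})

test_that("the deterministic self-convergence study is second order on a reduced problem", {
  p <- epidemic_params()
  cfg <- sim_config(nx = 20, ny = 20, dx = 2, dy = 2, t_end = 12, seed = 1,
                    stationarity_tol = 0, record_every = 1000)
  rep <- suppressWarnings(convergence_study(p, cfg,
                                            h_list = c(2, 1, 0.5, 0.25)))
  expect_true(all(rep$l2_errors > 0))
  expect_true(all(diff(rep$l2_errors) < 0))   # decreasing with h
  expect_gt(rep$fitted_order, 1.7)
  expect_lt(rep$fitted_order, 2.3)
})

test_that("the common-random-numbers stochastic study produces a well-defined order", {
  p <- epidemic_params(C_I = 8e-2)
  cfg <- sim_config(nx = 16, ny = 16, dx = 2, dy = 2, t_end = 8, seed = 1,
                    stationarity_tol = 0, record_every = 1000)
  rep <- suppressWarnings(convergence_study(p, cfg,
                                            h_list = c(2, 1, 0.5, 0.25)))
  expect_true(all(rep$l2_errors > 0))
  expect_true(all(diff(rep$l2_errors) < 0))
  # noise limits the attainable order below the deterministic rate
  expect_gt(rep$fitted_order, 0.5)
  expect_lt(rep$fitted_order, 2.3)
})

test_that("stationary pattern wavenumber falls inside the predicted unstable band", {
  for (a in c(0, 0.5)) {
    p <- epidemic_params(alpha = a)
    band <- turing_threshold(p)$unstable_band
    cfg <- sim_config(nx = 64, ny = 64, t_end = 80, seed = 4,
                      record_every = 500)
    res <- run_simulation(p, cfg)
    kd <- dominant_wavenumber(res$state$I, cfg$dx)
    expect_true(kd$reliable)
    expect_gt(kd$k_dominant, band[1])
    expect_lt(kd$k_dominant, band[2])
  }
})
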