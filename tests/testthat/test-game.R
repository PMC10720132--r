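oracle_game <- public_goods_game(B = 0.9, k = 0.05, h = 1, c = 0.2,
                                 s_A = 0.95, sigma0 = 0.1)

test_that("fitness functions encode the others-only benefit structure", {
  # no drug: producers pay the cost and are always disfavoured
  g0 <- public_goods_game(tau = 0, c = 0.2)
  w <- fitness_functions(g0, c(0.1, 0.5, 0.9))
  expect_true(all(w$W_A < w$W_D))
  expect_equal(unique(w$W_A), 0.8)
  # cost-free tolerant producers with weak benefit fix
  g1 <- public_goods_game(B = 0.5, c = 0, s_A = 1, sigma0 = 0)
  w1 <- fitness_functions(g1, seq(0, 1, by = 0.1))
  expect_true(all(w1$W_A > w1$W_D))
  eq1 <- find_equilibria(g1)
  expect_true(eq1$boundary$stable[2])   # producer fixation at x = 1
})

test_that("group-sampled fitness matches the binomial expectation and converges to mean field", {
  g2 <- public_goods_game(B = 0.9, k = 0.05, s_A = 0.95, sigma0 = 0.1, n = 2)
  x <- c(0.2, 0.5, 0.8)
  v1 <- hill_benefit(1, 0.9, 0.05)
  expected <- 0.1 + 0.9 * (x * v1 + (1 - x) * 0)
  expect_equal(fitness_functions(g2, x)$W_D, expected)
  # convergence to mean field away from the sharp-curvature corner x ~ k
  g200 <- public_goods_game(B = 0.9, k = 0.05, s_A = 0.95, sigma0 = 0.1, n = 200)
  gmf <- public_goods_game(B = 0.9, k = 0.05, s_A = 0.95, sigma0 = 0.1)
  xs <- seq(0.4, 0.95, by = 0.05)
  expect_lt(max(abs(fitness_functions(g200, xs)$W_D -
                      fitness_functions(gmf, xs)$W_D)), 1e-3)
  # and the discrepancy shrinks with group size everywhere
  xs_all <- seq(0.05, 0.95, by = 0.05)
  g20 <- public_goods_game(B = 0.9, k = 0.05, s_A = 0.95, sigma0 = 0.1, n = 20)
  d20 <- max(abs(fitness_functions(g20, xs_all)$W_D -
                   fitness_functions(gmf, xs_all)$W_D))
  d200 <- max(abs(fitness_functions(g200, xs_all)$W_D -
                    fitness_functions(gmf, xs_all)$W_D))
  expect_lt(d200, d20)
})

test_that("interior equilibrium matches both the grid-scan and algebraic oracles", {
  eq <- find_equilibria(oracle_game)
  expect_equal(nrow(eq$interior), 1)
  expect_true(eq$interior$stable)
  # brute-force grid scan oracle
  xs <- seq(1e-6, 1 - 1e-6, length.out = 1e6)
  g <- gain_function(oracle_game, xs)
  i <- which(diff(sign(g)) != 0)[1]
  x_scan <- (xs[i] + xs[i + 1]) / 2
  expect_lt(abs(eq$interior$x_star - x_scan), 1e-6)
  # algebraic oracle at h = 1: sigma0 + (1-sigma0) B x/(k+x) = s_A (1-c)
  target <- (0.95 * 0.8 - 0.1) / 0.9
  x_alg <- target * 0.05 / (0.9 - target)
  expect_equal(eq$interior$x_star, x_alg, tolerance = 1e-9)
  # minority equilibrium
  expect_lt(eq$interior$x_star, 0.5)
})

test_that("exactly one stable interior root exists in the coexistence regime", {
  set.seed(5)
  for (i in 1:20) {
    B <- runif(1, 0.5, 1); k <- runif(1, 0.02, 0.3); c <- runif(1, 0.05, 0.4)
    s_A <- runif(1, 0.7, 1); sigma0 <- runif(1, 0, 0.4)
    W_A <- s_A * (1 - c)
    V1 <- B / (k + 1)
    # coexistence regime: W_D(0) < W_A < W_D(1)
    if (!(sigma0 < W_A && W_A < sigma0 + (1 - sigma0) * V1)) next
    game <- public_goods_game(B = B, k = k, h = 1, c = c, s_A = s_A,
                              sigma0 = sigma0)
    eq <- find_equilibria(game)
    expect_equal(nrow(eq$interior), 1)
    expect_true(all(eq$interior$stable))
  }
})

test_that("replicator integration fixes boundaries and converges to the stable equilibrium", {
  expect_true(all(integrate_replicator(oracle_game, 0, t_end = 10)$x == 0))
  expect_true(all(integrate_replicator(oracle_game, 1, t_end = 10)$x == 1))
  eq <- find_equilibria(oracle_game)
  for (x0 in c(0.05, 0.5, 0.95)) {
    tr <- integrate_replicator(oracle_game, x0, t_end = 400, dt = 0.1)
    expect_lt(abs(tail(tr$x, 1) - eq$interior$x_star), 1e-4)
    expect_true(all(tr$x >= 0 & tr$x <= 1))
  }
  expect_error(integrate_replicator(oracle_game, 0.5, dt = -1),
               class = "coopcell_error_param")
})

test_that("a calibrated linear benefit that never pays drives producers extinct", {
  # contrast case: replace V by the linear function with the same V(1) and
  # choose the cost so W_A < W_D(x) for every x; the replicator then drives
  # producers extinct, while the concave benefit at moderate cost coexists
  v1 <- hill_benefit(1, 0.9, 0.05)
  sigma0 <- 0.1; s_A <- 0.95; c_big <- 0.92
  W_A <- s_A * (1 - c_big)
  W_D_lin <- function(x) sigma0 + (1 - sigma0) * v1 * x
  xs <- seq(0, 1, by = 0.01)
  expect_true(all(W_A < W_D_lin(xs)))
  f <- function(x) x * (1 - x) * (W_A - W_D_lin(x))
  x <- 0.5
  for (i in 1:5000) x <- min(max(x + 0.1 * f(x), 0), 1)
  expect_lt(x, 1e-4)
  # the concave benefit with moderate cost instead supports a stable
  # interior minority (established above with the same B, k)
  eqc <- find_equilibria(oracle_game)
  expect_true(eqc$interior$stable[1])
  expect_lt(eqc$interior$x_star[1], 0.5)
})

test_that("therapy sweep is nondecreasing and validated", {
  sw <- therapy_sweep(seq(0, 1, length.out = 50))
  expect_equal(sw$x_star[sw$tau == 0], 0)
  expect_true(all(diff(sw$x_star) >= -1e-9))
  expect_true(any(sw$interior))
  # spot-check a sweep point against the per-point equilibrium finder
  tau_i <- sw$tau[30]
  eq_mid <- find_equilibria(public_goods_game(tau = tau_i))
  expect_equal(sw$x_star[30],
               eq_mid$interior$x_star[eq_mid$interior$stable][1],
               tolerance = 1e-6)
  expect_error(therapy_sweep(sigma0_fun = function(tau) rep(0.5, length(tau))),
               class = "coopcell_error_param")
  expect_error(therapy_sweep(s_A_fun = function(tau) 1 - tau,
                             sigma0_fun = function(tau) 1 - 0.5 * tau),
               class = "coopcell_error_param")
})
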