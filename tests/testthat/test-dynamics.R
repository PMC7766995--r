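test_that("orientational ACFs handle frozen and planar-rotator limits", {
  ## frozen vector: P1 = P2 = 1 at every lag
  n <- 50
  u <- array(rep(c(0, 0, 1), each = n), dim = c(n, 3, 1))
  vs <- vector_series(0:(n - 1), u)
  expect_true(all(abs(orientational_acf(vs, 1, max_lag_frac = 0.5)$values - 1) < 1e-12))
  expect_true(all(abs(orientational_acf(vs, 2, max_lag_frac = 0.5)$values - 1) < 1e-12))
  ## vector rotating 90 deg per frame in a plane: lag 1 has cos = 0,
  ## so P1 = 0 and P2 = -1/2
  ang <- (0:(n - 1)) * pi / 2
  up <- array(c(cos(ang), sin(ang), rep(0, n)), dim = c(n, 3, 1))
  vsp <- vector_series(0:(n - 1), up)
  p1 <- orientational_acf(vsp, 1, max_lag_frac = 0.2)
  p2 <- orientational_acf(vsp, 2, max_lag_frac = 0.2)
  expect_equal(p1$values[2], 0, tolerance = 1e-12)
  expect_equal(p2$values[2], -0.5, tolerance = 1e-12)
  expect_equal(p1$values[1], 1); expect_equal(p2$values[1], 1)
  ## P2 bounds
  expect_true(all(p2$values >= -0.5 - 1e-12 & p2$values <= 1 + 1e-12))
  ## the identity check flags this anisotropic motion loudly
  chk <- p1_cubed_check(p1, p2, p1_min = -2, tol = 1e-3)
  expect_false(chk$pass)
  expect_gt(chk$max_deviation, 0.4)
})

test_that("rotational diffusion recovers its closed-form time constants", {
  vs <- gen_rotational_diffusion(dr = 0.01, n_steps = 1e6, dt = 0.5,
                                 n_vectors = 8, seed = 61)
  truth <- attr(vs, "truth")
  t2 <- characteristic_time(orientational_acf(vs, 2, lags = 0:200))$tau
  t1 <- characteristic_time(orientational_acf(vs, 1, lags = 0:400))$tau
  expect_equal(t2, truth$tau2, tolerance = 0.03)
  expect_equal(t1 / t2, 3, tolerance = 0.05)
  ## FFT full-lag path and direct lag path agree exactly
  vss <- gen_rotational_diffusion(0.005, 4000, dt = 1, n_vectors = 3,
                                  seed = 62)
  full <- orientational_acf(vss, 2)
  sub <- orientational_acf(vss, 2, lags = c(0, 10, 100, 300))
  expect_equal(sub$values, full$values[c(1, 11, 101, 301)],
               tolerance = 1e-10)
})

test_that("characteristic time is exact on exponentials and censors", {
  t <- seq(0, 50, by = 0.1)
  cf <- correlation_function(t, exp(-t / 5), 2)
  expect_equal(characteristic_time(cf)$tau, 5, tolerance = 1e-4)
  ## estimator identity at a nanosecond-scale constant
  t2 <- seq(0, 6e4, by = 10)
  cf2 <- correlation_function(t2, exp(-t2 / 11900), 1)
  expect_equal(characteristic_time(cf2)$tau, 11900, tolerance = 1e-4)
  ## bi-exponential vs brute-force bisection on the analytic curve
  f <- function(x) 0.6 * exp(-x / 2) + 0.4 * exp(-x / 20)
  cfb <- correlation_function(t, f(t), 2)
  lo <- 0; hi <- 50
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > exp(-1)) lo <- mid else hi <- mid
  }
  expect_equal(characteristic_time(cfb)$tau, (lo + hi) / 2, tolerance = 1e-3)
  ## no crossing in window: censored with lower bound
  cfc <- correlation_function(t, exp(-t / 1e4), 2)
  ct <- characteristic_time(cfc)
  expect_true(ct$censored)
  expect_equal(ct$lower_bound, 50)
})

test_that("size-pulsation ACF recovers the mean-reverting time constant", {
  x <- gen_ou_scalar(n_steps = 2e5, dt = 1, theta = 100, seed = 63)
  cf <- scalar_acf(x, dt = 1)
  expect_equal(cf$values[1], 1)
  expect_equal(characteristic_time(cf)$tau, 100, tolerance = 0.05)
  expect_error(scalar_acf(rep(4, 100)), "zero-variance")
})

test_that("spectral density matches the Lorentzian closed form", {
  tau <- 1
  t <- seq(0, 20, by = 0.001)
  cf <- correlation_function(t, exp(-t / tau), 2)
  om <- exp(seq(log(0.01), log(100), length.out = 50)) / tau
  J <- spectral_density(cf, om)
  ref <- 2 * tau / (1 + om^2 * tau^2)
  expect_lt(max(abs(J$J - ref) / ref), 0.01)
  ## white-spectrum limit: fast decay gives flat J ~ 2 tau at low frequency
  tauf <- 0.05
  tf <- seq(0, 2, by = 0.001)
  cff <- correlation_function(tf, exp(-tf / tauf), 2)
  Jf <- spectral_density(cff, c(0.001, 0.01, 0.1))
  expect_equal(Jf$J, rep(2 * tauf, 3), tolerance = 0.01)
  ## bi-exponential vs fine-grid numerical quadrature oracle
  g <- function(x) 0.7 * exp(-x / 0.5) + 0.3 * exp(-x / 5)
  tb <- seq(0, 60, by = 0.002)
  cfb <- correlation_function(tb, g(tb), 2)
  omb <- c(0.05, 0.2, 1, 5)
  Jb <- spectral_density(cfb, omb)
  oracle <- vapply(omb, function(w) {
    tt <- seq(0, 400, by = 5e-4)
    2 * sum(g(tt) * cos(w * tt)) * 5e-4
  }, numeric(1))
  expect_equal(Jb$J, oracle, tolerance = 0.01)
})

test_that("transform consistency: inverse cosine transform returns P2", {
  tau <- 2
  t <- seq(0, 30, by = 0.01)
  cf <- correlation_function(t, exp(-t / tau), 2)
  om <- seq(1e-4, 60, by = 2e-3)
  J <- spectral_density(cf, om)$J
  ## P2(t) = (1/pi) * integral J(w) cos(wt) dw
  tt <- seq(0, 6, by = 0.5)
  back <- vapply(tt, function(ti)
    sum(J * cos(om * ti)) * (om[2] - om[1]) / pi, numeric(1))
  expect_equal(back, exp(-tt / tau), tolerance = 0.02)
})

test_that("reduced and susceptibility relaxation rates follow the algebra", {
  tau <- 1
  t <- seq(0, 25, by = 0.001)
  cf <- correlation_function(t, exp(-t / tau), 2)
  om <- exp(seq(log(0.02), log(20), length.out = 40))
  red <- t1_reduced(cf, om)
  ref <- om * (2 * tau / (1 + om^2 * tau^2) + 8 * tau / (1 + 4 * om^2 * tau^2))
  expect_lt(max(abs(red$rate - ref) / ref), 0.01)
  ## low-frequency limit: rate -> 0
  red0 <- t1_reduced(cf, 1e-6)
  expect_lt(red0$rate, 1e-4)
  ## maximum position equals a brute-force scan of the closed form
  oms <- seq(0.05, 5, by = 0.001)
  refs <- oms * (2 * tau / (1 + oms^2 * tau^2) +
                   8 * tau / (1 + 4 * oms^2 * tau^2))
  om_peak_ref <- oms[which.max(refs)]
  redS <- t1_reduced(cf, oms[seq(1, length(oms), by = 10)])
  om_peak <- redS$omega[which.max(redS$rate)]
  expect_equal(om_peak, om_peak_ref, tolerance = 0.05)
  ## susceptibility conversion: arithmetic, linearity, zero
  expect_equal(t1_susceptibility(1.0, 0.56e10, 2 * pi * 4e8),
               0.56e10 / (2 * pi * 4e8), tolerance = 1e-12)
  expect_equal(t1_susceptibility(1.0, 1.12e10), 2 * t1_susceptibility(1.0, 0.56e10))
  expect_equal(t1_susceptibility(0), 0)
})

test_that("mobility classes with prescribed time constants are recovered", {
  taus <- c(side_3 = 70, side_4 = 100, side_5 = 165)
  series <- lapply(names(taus), function(cl)
    gen_rotational_diffusion(dr = 1 / (6 * taus[[cl]]), n_steps = 1e5,
                             dt = 1, n_vectors = 8,
                             seed = 64 + match(cl, names(taus))))
  names(series) <- names(taus)
  gm <- group_mobility_by_topology(series, lags = 0:600)
  got <- setNames(gm$table$tau_ps, gm$table$class)
  for (cl in names(taus))
    expect_equal(got[[cl]], taus[[cl]], tolerance = 0.05)
  ## ordering by topological distance is preserved
  expect_true(got[["side_3"]] < got[["side_4"]] &&
                got[["side_4"]] < got[["side_5"]])
})

test_that("CH2 classes extracted from a toy trajectory produce NMR tables", {
  run <- gen_toy_dendrimer_trajectory(1, "2Lys", n_steps = 1500,
                                      save_every = 5, seed = 66)
  cls <- ch2_vector_series(run$traj, run$system)
  expect_setequal(names(cls),
                  c("side_1", "side_2", "side_3", "side_4", "inner",
                    "terminal"))
  nm <- nmr_relaxation_summary(run$traj, run$system, temperature = 310)
  expect_true(all(c("class", "tau_ps", "reduced_rate", "t1h_rate") %in%
                    names(nm$table)))
  expect_true(all(nm$table$t1h_rate >= 0, na.rm = TRUE))
  ## core-to-end vectors: one instance per terminal group
  ce <- core_to_end_series(run$traj, run$system)
  expect_equal(dim(ce$u)[3], run$system$counts$Nend)
})
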