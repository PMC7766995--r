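test_that("geometric criteria accept and reject canonical triples", {
  sys <- make_hbond_system(1, 1)
  p <- hbond_participants(sys)
  ## D-A at 0.30 nm with H on the D->A axis: bond
  x <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.3, 0, 0))
  expect_equal(nrow(detect_hbonds(x, p$donors, p$acceptors)), 1)
  ## D-A at 0.40 nm, any geometry: no bond
  x2 <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.4, 0, 0))
  expect_equal(nrow(detect_hbonds(x2, p$donors, p$acceptors)), 0)
  ## angle slightly over the cutoff: no bond
  th <- 31 * pi / 180
  x3 <- rbind(c(0, 0, 0), 0.1 * c(cos(th), sin(th), 0), c(0.3, 0, 0))
  expect_equal(nrow(detect_hbonds(x3, p$donors, p$acceptors)), 0)
  ## donors without hydrogens are a configuration error
  expect_error(hbond_participants(sys, donors = 3L), "configuration error")
})

test_that("detector agrees with a brute-force oracle on random geometries", {
  set.seed(51)
  n <- 1e4
  sys <- make_hbond_system(n, 0)
  ## give every donor its own acceptor O placed randomly nearby
  at <- sys$atoms
  acc <- data.frame(atom_id = nrow(at) + seq_len(n),
                    name = paste0("O", seq_len(n)), element = "O",
                    mass = 16, charge = 0, role = "water_oxygen",
                    residue_kind = "hb", segment_id = nrow(at) + seq_len(n),
                    stringsAsFactors = FALSE)
  sys <- molecular_system(rbind(at, acc), sys$bonds, sys$selections)
  don <- seq(1, 2 * n, by = 2); hyd <- don + 1; accid <- 2 * n + seq_len(n)
  x <- matrix(0, 3 * n, 3)
  x[don, ] <- matrix(runif(3 * n, -1, 1), ncol = 3)
  x[hyd, ] <- x[don, ] + matrix(rnorm(3 * n, sd = 0.1), ncol = 3)
  x[accid, ] <- x[don, ] + matrix(rnorm(3 * n, sd = 0.25), ncol = 3)
  got <- detect_hbonds(x, data.frame(donor = don, hydrogen = hyd), accid)
  ## restrict to the matched (per-donor) triples for exact set equality
  got_own <- got[got$acceptor == accid[(got$donor + 1) / 2], ]
  want <- hbond_oracle(x, don, hyd, accid, 0.35, 30)
  expect_identical(sort(got_own$donor), sort(don[want]))
  ## and the full cross set agrees with the oracle on a subsample
  sub <- sample(nrow(got), min(500, nrow(got)))
  ok <- hbond_oracle(x, got$donor[sub], got$hydrogen[sub],
                     got$acceptor[sub], 0.35, 30)
  expect_true(all(ok))
})

test_that("per-class statistics partition the detected bonds", {
  ## 2 dendrimer donors + 2 water acceptors; geometry fixes the classes
  sys <- make_hbond_system(2, 2)
  ## donor 1 bonded to water O (id 5), donor 2 to nothing
  x <- rbind(c(0, 0, 0), c(0.1, 0, 0),        # N1, H1
             c(5, 5, 5), c(5.1, 5, 5),        # N2, H2
             c(0.3, 0, 0), c(9, 9, 9))        # O1 near N1, O2 far
  tr <- make_static_traj(x, n_frames = 2)
  hs <- hbond_statistics(tr, sys)
  expect_equal(hs$mean_dw, 1)
  expect_equal(hs$mean_dw_side, 1)       # donors are side-segment atoms
  expect_equal(hs$mean_id, 0)
  expect_lte(hs$mean_dw_side, hs$mean_dw)
  ## empty frame: histogram mass at zero
  x0 <- x; x0[5, ] <- c(20, 20, 20)
  hs0 <- hbond_statistics(make_static_traj(x0), sys)
  expect_equal(hs0$mean_dw, 0)
  expect_equal(names(hs0$hist_dw), "0")
  ## printed-table normalization: side counts per inserted residue
  expect_equal(round(hbond_per_spacer(165.9, 28), 1), 5.9)
  expect_equal(round(hbond_per_spacer(123.9, 28), 1), 4.4)
})

test_that("continuous lifetimes follow the frame-count convention", {
  nf <- 50
  ind <- rep(FALSE, nf)
  ind[11:30] <- TRUE                 # 20 frames on
  lt <- continuous_lifetimes(ind, dt = 0.1)
  expect_equal(lt$durations, 2.0)
  ## single-frame event: lifetime = dt
  ind1 <- rep(FALSE, nf); ind1[25] <- TRUE
  expect_equal(continuous_lifetimes(ind1, dt = 0.1)$durations, 0.1)
  ## events touching the boundary are censored
  indc <- rep(FALSE, nf); indc[1:5] <- TRUE; indc[48:50] <- TRUE
  ltc <- continuous_lifetimes(indc, dt = 0.1)
  expect_equal(ltc$n_censored, 2)
  expect_length(ltc$durations, 0)
})

test_that("spline refinement recovers sub-frame crossing times", {
  ## linear margin crossing zero at t = 10.25 and t = 30.75 (dt = 1)
  nf <- 50; t <- 0:(nf - 1)
  margin <- pmin((t - 10.25) * 0.2, (30.75 - t) * 0.2)
  ind <- margin > 0
  lt <- continuous_lifetimes(ind, dt = 1, margins = margin)
  expect_equal(lt$durations, 30.75 - 10.25, tolerance = 1e-6)
  ## refined duration stays within +-2 frames of the raw interval
  raw <- continuous_lifetimes(ind, dt = 1)$durations
  expect_lt(abs(lt$durations - raw), 2)
})

test_that("lifetime estimator is unbiased on telegraph processes", {
  tg <- gen_telegraph_bonds(mean_on = 110, mean_off = 110, dt = 0.1,
                            n_events = 5000, seed = 52)
  lt <- continuous_lifetimes(tg$indicator, tg$dt)
  expect_equal(lt$mean, mean(tg$truth_durations), tolerance = 0.05)
  ## heavy discretization: mean on-time equal to dt biases the estimator;
  ## the gap is reported (short events vanish below the sampling comb)
  tgc <- gen_telegraph_bonds(mean_on = 0.1, mean_off = 0.5, dt = 0.1,
                             n_events = 4000, seed = 53)
  ltc <- continuous_lifetimes(tgc$indicator, tgc$dt)
  gap <- ltc$mean - mean(tgc$truth_durations)
  expect_gt(abs(gap) / mean(tgc$truth_durations), 0.1)
})

test_that("event tracking over a trajectory feeds the lifetime estimator", {
  ## donor-acceptor pair oscillating through the distance cutoff
  sys <- make_hbond_system(1, 1)
  nf <- 60
  d <- 0.3 + 0.1 * sin(2 * pi * (0:(nf - 1)) / 20)   # crosses 0.35
  frames <- lapply(seq_len(nf), function(f)
    rbind(c(0, 0, 0), c(0.1, 0, 0), c(d[f], 0, 0)))
  tr <- make_traj(frames, dt = 1)
  ev <- hbond_event_series(tr, sys)
  expect_equal(nrow(ev$triples), 1)
  lt_raw <- continuous_lifetimes(ev$indicator, ev$dt)
  lt_ref <- continuous_lifetimes(ev$indicator, ev$dt, margins = ev$margins)
  expect_gt(length(lt_ref$durations), 0)
  ## refinement shifts each duration by less than 2 frames
  expect_true(all(abs(lt_ref$durations - lt_raw$durations) < 2))
})
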