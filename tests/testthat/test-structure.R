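test_that("radius of gyration matches closed-form point configurations", {
  ## single atom: Rg = 0
  s1 <- make_point_system(1)
  g1 <- radius_of_gyration(make_static_traj(matrix(c(2, 1, -1), 1)), s1)
  expect_equal(g1$rg_mean, 0)
  ## two unit masses at (+-1, 0, 0): Rg = 1
  s2 <- make_point_system(2)
  g2 <- radius_of_gyration(make_static_traj(rbind(c(1, 0, 0), c(-1, 0, 0))), s2)
  expect_equal(g2$rg_mean, 1)
  ## 8 unit masses at cube corners: Rg = sqrt(3), perfectly spherical
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  s8 <- make_point_system(8)
  g8 <- radius_of_gyration(make_static_traj(cube), s8)
  expect_equal(g8$rg_mean, sqrt(3))
  expect_equal(asphericity(g8), 0, tolerance = 1e-12)
  ## per-frame identity Rg^2 = Ix + Iy + Iz
  expect_equal(g8$rg^2, rowSums(g8$eig))
  ## zero total mass rejected
  expect_error(radius_of_gyration(make_static_traj(cube),
                                  make_point_system(8, mass = 1e-300)),
               NA, info = "tiny masses are fine")
})

test_that("asphericity attains its limiting values and matches a direct oracle", {
  ## ideal rod: Ix > 0, Iy = Iz = 0 -> alpha = 1
  s2 <- make_point_system(2)
  rod <- radius_of_gyration(make_static_traj(rbind(c(3, 0, 0), c(-3, 0, 0))), s2)
  expect_equal(asphericity(rod), 1)
  ## 500-point cloud filling a 2:1:1 ellipsoid vs direct eigen evaluation
  set.seed(31)
  n <- 500
  pts <- matrix(rnorm(3 * n), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * runif(n)^(1 / 3)
  pts <- sweep(pts, 2, c(2, 1, 1), "*")
  sysn <- make_point_system(n)
  gr <- radius_of_gyration(make_static_traj(pts), sysn)
  ## oracle: diagonalize the covariance of centred coordinates directly
  d <- sweep(pts, 2, colMeans(pts))
  ev <- eigen(crossprod(d) / n, symmetric = TRUE)$values
  alpha_oracle <- 1 - 3 * (ev[1] * ev[2] + ev[1] * ev[3] + ev[2] * ev[3]) /
    sum(ev)^2
  expect_equal(asphericity(gr), alpha_oracle, tolerance = 1e-12)
  expect_length(asphericity(gr, per_frame = TRUE), 1)
})

test_that("Kirkwood radius matches exact and Monte-Carlo references", {
  ## two points at distance d: Rh = d
  s2 <- make_point_system(2)
  tr <- make_static_traj(rbind(c(0, 0, 0), c(0.7, 0, 0)))
  expect_equal(kirkwood_hydrodynamic_radius(tr, s2, 1:2), 0.7)
  ## regular tetrahedron, all pairs at d: Rh = d
  d <- 1.2
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    (d / (2 * sqrt(2)))
  s4 <- make_point_system(4)
  expect_equal(kirkwood_hydrodynamic_radius(make_static_traj(tet), s4, 1:4), d)
  ## 2000 points uniform on a sphere of radius R: mean inverse chord = 1/R
  set.seed(32)
  n <- 2000; R <- 1.5
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * R
  sn <- make_point_system(n)
  rh <- kirkwood_hydrodynamic_radius(make_static_traj(u), sn, 1:n)
  expect_equal(rh, R, tolerance = 0.02)
  ## Rh never exceeds the maximal pairwise distance
  expect_lt(rh, 2 * R)
  expect_error(kirkwood_hydrodynamic_radius(tr, s2, 1), "size < 2")
})

test_that("terminal-group radius matches shell configurations", {
  ## all terminal N on a shell of radius R around a massive centre
  n <- 16; R <- 2.5
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * R
  x <- rbind(c(0, 0, 0), u)
  atoms <- data.frame(atom_id = 1:(n + 1), name = "X",
                      element = c("C", rep("N", n)),
                      mass = c(1e9, rep(1, n)), charge = 0,
                      role = c("core", rep("terminal_group", n)),
                      residue_kind = "t", segment_id = 1:(n + 1),
                      stringsAsFactors = FALSE)
  sys <- molecular_system(atoms, matrix(integer(), ncol = 2),
                          selections = list(dendrimer = 1:(n + 1),
                                            terminal_N = 2:(n + 1),
                                            ions = integer()))
  tr <- make_static_traj(x)
  expect_equal(terminal_group_radius(tr, sys), R, tolerance = 1e-6)
  ## half at radius 1, half at 3: Re = sqrt(5)
  x2 <- rbind(c(0, 0, 0), u / R * rep(c(1, 3), each = n / 2))
  expect_equal(terminal_group_radius(make_static_traj(x2), sys), sqrt(5),
               tolerance = 1e-6)
  ## rigid-sphere estimate
  expect_equal(rigid_sphere_radius(2.0), sqrt(5 / 3) * 2)
})

test_that("radial density conserves mass and is flat for a uniform ball", {
  ## single atom: all mass in its shell, total mass conserved
  sys1 <- make_point_system(2, mass = c(1e9, 3))
  x <- rbind(c(0, 0, 0), c(1.23, 0, 0))
  pr <- radial_density_profile(make_static_traj(x), sys1, 2, dr = 0.05)
  mass_back <- sum(4 * pi * pr$r^2 * pr$values * pr$dr)
  expect_equal(mass_back, 3, tolerance = 1e-10)
  expect_equal(pr$r[which.max(pr$values)], 1.225, tolerance = 0.051)
  ## uniform ball: flat profile within binning/Monte-Carlo error
  set.seed(33)
  n <- 40000; R <- 2
  pts <- matrix(rnorm(3 * n), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * R * runif(n)^(1 / 3)
  pts <- rbind(c(0, 0, 0), pts)
  sysb <- make_point_system(n + 1, mass = c(1e12, rep(1, n)))
  prb <- radial_density_profile(make_static_traj(pts), sysb, 2:(n + 1),
                                dr = 0.1)
  rho0 <- n / ((4 / 3) * pi * R^3)
  mid <- prb$r > 0.4 & prb$r < 1.6
  expect_lt(max(abs(prb$values[mid] - rho0)) / rho0, 0.1)
  ## mass closure within 1 % at dr = 0.05
  prc <- radial_density_profile(make_static_traj(pts), sysb, 2:(n + 1),
                                dr = 0.05)
  expect_equal(sum(4 * pi * prc$r^2 * prc$values * prc$dr) / n, 1,
               tolerance = 0.01)
  ## terminal-count mode peaks at the shell radius
  shell <- pts[-1, ] / sqrt(rowSums(pts[-1, ]^2)) * 1.5
  prn <- radial_density_profile(make_static_traj(rbind(c(0, 0, 0), shell)),
                                sysb, 2:(n + 1), dr = 0.05, mode = "count")
  expect_equal(prn$r[which.max(prn$values)], 1.475, tolerance = 0.051)
  expect_error(radial_density_profile(make_static_traj(pts), sysb,
                                      2:(n + 1), dr = 10), "binning error")
})

test_that("congregation coefficient hits both stated limits", {
  ## all members along one ray -> k45 = 1
  n <- 16
  ray <- matrix(rep(c(1, 0, 0), each = n), ncol = 3) *
    seq(0.5, 2, length.out = n)
  x <- rbind(c(0, 0, 0), ray)
  atoms <- data.frame(atom_id = 1:(n + 1), name = "X",
                      element = c("C", rep("N", n)),
                      mass = c(1e9, rep(1, n)), charge = 0,
                      role = c("core", rep("terminal_group", n)),
                      residue_kind = "t", segment_id = 1:(n + 1),
                      stringsAsFactors = FALSE)
  sys <- molecular_system(atoms, matrix(integer(), ncol = 2),
                          selections = list(dendrimer = 1:(n + 1),
                                            terminal_N = 2:(n + 1),
                                            ions = integer()))
  expect_equal(congregation_coefficient(make_static_traj(x), sys), 1)
  ## uniform scattering -> k45 ~ 0 (small-sample check; the full
  ## 1e4-resample bound is exercised by the acceptance suite)
  set.seed(34)
  frames <- lapply(1:500, function(f) {
    u <- matrix(rnorm(3 * n), ncol = 3)
    rbind(c(0, 0, 0), u / sqrt(rowSums(u^2)))
  })
  k <- congregation_coefficient(make_traj(frames), sys)
  expect_lt(abs(k), 0.1)
})

test_that("structural descriptors are invariant under rotation + translation", {
  set.seed(35)
  run <- gen_toy_dendrimer_trajectory(1, "2Arg", n_steps = 400,
                                      save_every = 100, seed = 35)
  tr <- run$traj; sys <- run$system
  Q <- random_rotation(); shift <- c(1.3, -0.7, 2.1)
  coords2 <- tr$coords
  for (f in seq_len(dim(coords2)[1]))
    coords2[f, , ] <- sweep(matrix(tr$coords[f, , ], ncol = 3) %*% t(Q),
                            2, -shift)
  tr2 <- md_trajectory(tr$times, coords2)
  expect_equal(radius_of_gyration(tr2, sys)$rg,
               radius_of_gyration(tr, sys)$rg, tolerance = 1e-10)
  expect_equal(asphericity(radius_of_gyration(tr2, sys)),
               asphericity(radius_of_gyration(tr, sys)), tolerance = 1e-8)
  expect_equal(kirkwood_hydrodynamic_radius(tr2, sys),
               kirkwood_hydrodynamic_radius(tr, sys), tolerance = 1e-10)
  expect_equal(terminal_group_radius(tr2, sys),
               terminal_group_radius(tr, sys), tolerance = 1e-10)
  expect_equal(congregation_coefficient(tr2, sys),
               congregation_coefficient(tr, sys), tolerance = 1e-10)
  p1 <- radial_density_profile(tr, sys, dr = 0.1)
  p2 <- radial_density_profile(tr2, sys, dr = 0.1)
  nb <- min(length(p1$values), length(p2$values))
  expect_equal(p1$values[1:nb], p2$values[1:nb], tolerance = 1e-8)
})
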