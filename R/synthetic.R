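## Synthetic inputs with analytically known ground truth. These stand in
## for long atomistic trajectories in all tests: every generator records
## its spec and exposes a closed-form truth accessor.

gen_spec <- function(kind, ...) {
  list(kind = kind, parameters = list(...))
}

#' Isotropic rotational diffusion of unit vectors
#'
#' Evolves unit vectors by exact small rotations about random transverse
#' axes with Gaussian transverse increments (variance `2*Dr*dt` per
#' component, i.e. total angular variance `4*Dr*dt` per step). The exact
#' orientational ACFs are \eqn{P_1(t) = e^{-2 D_r t}} and
#' \eqn{P_2(t) = e^{-6 D_r t}}, so the characteristic times are
#' \eqn{\tau_1 = 1/(2 D_r)} and \eqn{\tau_2 = 1/(6 D_r)} and the
#' \eqn{P_2 = P_1^3} identity holds. The small-angle regime requires
#' `Dr*dt <= 0.01`.
#'
#' @param dr rotational diffusion coefficient (1/ps).
#' @param n_steps number of steps.
#' @param dt time step (ps).
#' @param n_vectors independent vector instances.
#' @param seed RNG seed (set only when non-NULL).
#' @return a [vector_series] with attribute `truth` (list of `tau1`,
#'   `tau2`, `p1`, `p2` closed forms) and `spec`.
#' @export
gen_rotational_diffusion <- function(dr, n_steps, dt = 1, n_vectors = 1,
                                     seed = NULL) {
  stopifnot(dr > 0, n_steps >= 2)
  if (dr * dt > 0.01)
    stop("step-size error: Dr*dt = ", dr * dt,
         " violates the small-angle regime (require <= 0.01)")
  if (!is.null(seed)) set.seed(seed)
  u0 <- random_unit_vectors(n_vectors)
  u <- cpp_rotdiff(n_steps, dr, dt, u0)
  vs <- vector_series((0:(n_steps - 1)) * dt, u, "rotational_diffusion")
  attr(vs, "truth") <- list(
    tau1 = 1 / (2 * dr), tau2 = 1 / (6 * dr),
    p1 = function(t) exp(-2 * dr * t), p2 = function(t) exp(-6 * dr * t))
  attr(vs, "spec") <- gen_spec("rotational_diffusion", dr = dr, dt = dt,
                               n_steps = n_steps, n_vectors = n_vectors,
                               seed = seed)
  vs
}

random_unit_vectors <- function(n) {
  v <- matrix(rnorm(3 * n), nrow = 3)
  v / rep(sqrt(colSums(v^2)), each = 3)
}

#' Streaming Legendre ACFs of rotational diffusion
#'
#' Simulates isotropic rotational diffusion and accumulates the P1 and P2
#' ACFs at a sparse lag set on the fly (ring-buffer accumulation), so that
#' sample sizes far beyond what fits in memory as a stored series can be
#' used for precision checks of the \eqn{P_2 = P_1^3} identity.
#'
#' @inheritParams gen_rotational_diffusion
#' @param lags integer frame lags (0 allowed).
#' @return list with `p1` and `p2` [correlation_function]s.
#' @export
rotdiff_legendre_acf <- function(dr, dt, n_steps, n_vectors, lags,
                                 seed = NULL) {
  stopifnot(dr > 0)
  if (dr * dt > 0.01)
    stop("step-size error: Dr*dt violates the small-angle regime")
  if (!is.null(seed)) set.seed(seed)
  lags <- sort(unique(as.integer(lags)))
  stopifnot(all(lags >= 0), all(lags < n_steps))
  u0 <- random_unit_vectors(n_vectors)
  s <- cpp_rotdiff_stream(n_steps, dr, dt, u0, lags)
  p1 <- s$s1 / s$counts
  p2 <- 1.5 * s$s2 / s$counts - 0.5
  list(p1 = correlation_function(lags * dt, p1, 1, n_vectors, s$counts / n_vectors),
       p2 = correlation_function(lags * dt, p2, 2, n_vectors, s$counts / n_vectors))
}

#' Mean-reverting scalar series (Ornstein-Uhlenbeck)
#'
#' Gaussian mean-reverting process with exact autocorrelation
#' \eqn{e^{-t/\theta}}, emulating the pulsation of the squared dendrimer
#' size \eqn{R_g^2(t)}. Defaults place a 3-sigma band of about 2.8-5.2
#' nm^2 around a mean of 4 nm^2, i.e. an Rg band of roughly 1.7-2.3 nm.
#'
#' @param n_steps series length.
#' @param dt time step (ps).
#' @param mean stationary mean (nm^2 when emulating Rg^2).
#' @param sd stationary standard deviation.
#' @param theta correlation time (ps).
#' @param seed RNG seed.
#' @return numeric series with attributes `truth` (`acf` closed form) and
#'   `times`.
#' @export
gen_ou_scalar <- function(n_steps, dt = 1, mean = 4, sd = 0.4, theta = 100,
                          seed = NULL) {
  stopifnot(theta > 0, n_steps >= 2)
  if (!is.null(seed)) set.seed(seed)
  phi <- exp(-dt / theta)
  z0 <- rnorm(1)
  eps <- rnorm(n_steps) * sqrt(1 - phi^2)
  z <- as.numeric(stats::filter(eps, phi, method = "recursive", init = z0))
  x <- mean + sd * z
  attr(x, "truth") <- list(acf = function(t) exp(-t / theta),
                           mean = mean, sd = sd, theta = theta)
  attr(x, "times") <- (0:(n_steps - 1)) * dt
  x
}

#' Radially structured charge cloud with a counterion double layer
#'
#' Builds a synthetic macroion: positive unit charges whose radial
#' positions are Gaussian around a shell radius, negative counterions whose
#' radial positions decay exponentially beyond a shift radius, directions
#' uniform on the sphere, and an uncharged heavy anchor bead at the origin
#' pinning the centre of mass. The cumulative charge has the closed form
#' \eqn{Q(r) = N_+ \Phi((r-\mu)/\sigma) - N_- (1 - e^{-(r-r_0)/\ell})_+},
#' exposed through the `truth` attribute together with the analytic
#' location of its maximum.
#'
#' @param n_plus number of positive charges.
#' @param shell_mu,shell_sigma Gaussian shell radius and width (nm).
#' @param n_minus number of counterions.
#' @param decay counterion decay length (nm).
#' @param ion_shift radius beyond which the exponential cloud starts (nm);
#'   defaults to `shell_mu`.
#' @param n_frames number of independently redrawn frames.
#' @param seed RNG seed.
#' @return list with `system` ([molecular_system]), `traj`
#'   ([md_trajectory]) and `truth` (list `Q`, `Rmax`, `Q_star`).
#' @export
gen_double_layer_cloud <- function(n_plus = 44, shell_mu = 2.6,
                                   shell_sigma = 0.3, n_minus = 44,
                                   decay = 1.0, ion_shift = shell_mu,
                                   n_frames = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_plus != n_minus)
    warning("non-neutral charge cloud: cumulative charge will not close")
  n <- 1L + n_plus + n_minus
  atoms <- data.frame(
    atom_id = seq_len(n),
    name = c("CEN", rep("QP", n_plus), rep("CL", n_minus)),
    element = c("C", rep("N", n_plus), rep("Cl", n_minus)),
    mass = c(1e6, rep(10, n_plus + n_minus)),
    charge = c(0, rep(1, n_plus), rep(-1, n_minus)),
    role = c("core", rep("terminal_group", n_plus), rep("counterion", n_minus)),
    residue_kind = c("anchor", rep("shell", n_plus), rep("ion", n_minus)),
    segment_id = seq_len(n), stringsAsFactors = FALSE)
  sys <- molecular_system(atoms, matrix(integer(), ncol = 2),
                          selections = list(
                            dendrimer = 1:(1 + n_plus),
                            ions = if (n_minus) (1 + n_plus + 1):n else integer(),
                            terminal_N = 2:(1 + n_plus),
                            terminal_charged_groups = 2:(1 + n_plus),
                            charged_side_groups = 2:(1 + n_plus),
                            core_branch_point = 1L))
  coords <- array(0, dim = c(n_frames, n, 3))
  for (f in seq_len(n_frames)) {
    rp <- abs(rnorm(n_plus, shell_mu, shell_sigma))
    rm <- if (n_minus) ion_shift + rexp(n_minus, 1 / decay) else numeric(0)
    dirs <- t(random_unit_vectors(n_plus + n_minus))
    coords[f, 2:n, ] <- dirs * c(rp, rm)
  }
  traj <- md_trajectory(seq_len(n_frames) - 1, coords)
  Qfun <- function(r)
    n_plus * stats::pnorm((r - shell_mu) / shell_sigma) -
      n_minus * pmax(1 - exp(-(r - ion_shift) / decay), 0)
  opt <- optimize(Qfun, c(ion_shift, ion_shift + 5 * decay), maximum = TRUE)
  list(system = sys, traj = traj,
       truth = list(Q = Qfun, Rmax = opt$maximum, Q_star = opt$objective))
}

#' Two-state telegraph bond process
#'
#' Alternating exponential on/off durations discretized at `dt`, emulating
#' the continuous presence/absence of a hydrogen bond. The continuous
#' ground-truth on-durations are retained for oracle comparison with the
#' lifetime estimator.
#'
#' @param mean_on,mean_off mean on/off durations (ps).
#' @param dt sampling interval (ps).
#' @param n_events number of on-periods generated.
#' @param seed RNG seed.
#' @return list with `indicator` (logical vector sampled at `dt`), `dt`,
#'   `truth_durations` (continuous on-durations, ps), `times`.
#' @export
gen_telegraph_bonds <- function(mean_on = 110, mean_off = 110, dt = 0.1,
                                n_events = 1000, seed = NULL) {
  stopifnot(mean_on > 0, mean_off > 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  on <- rexp(n_events, 1 / mean_on)
  off <- rexp(n_events + 1, 1 / mean_off)
  ## timeline: off_1, on_1, off_2, on_2, ..., on_n, off_{n+1}
  dur <- as.vector(rbind(off[seq_len(n_events)], on))
  dur <- c(dur, off[n_events + 1])
  bounds <- cumsum(dur)
  total <- bounds[length(bounds)]
  times <- seq(0, total, by = dt)
  seg <- findInterval(times, c(0, bounds), rightmost.closed = TRUE)
  indicator <- seg %% 2 == 0          # even segments are 'on'
  list(indicator = indicator, dt = dt, times = times,
       truth_durations = on)
}

#' Brownian-dynamics trajectory of the toy dendrimer
#'
#' Integrates the coarse-grained toy dendrimer plus counterions with an
#' overdamped (Brownian) integrator: harmonic bonds, soft pair repulsion,
#' screened Coulomb interactions between charges, and a soft spherical
#' container wall that keeps the counterion cloud around the macroion. The
#' resulting frames have dendrimer-like radial structure and are used for
#' end-to-end pipeline tests; no attempt is made to reproduce atomistic
#' force-field physics. The dendrimer centre of mass is removed from every
#' saved frame. At `kT = 0` the structure is frozen (frames replicate the
#' initial configuration), giving the zero-temperature limit in which all
#' ACFs stay at 1.
#'
#' @param generation,spacer_kind passed to [build_toy_dendrimer].
#' @param n_steps integration steps.
#' @param dt time step (reduced units, interpreted as ps in outputs).
#' @param save_every save a frame every this many steps.
#' @param kT thermal energy (reduced); 0 freezes the structure.
#' @param bond_r0,bond_k harmonic bond rest length (nm) and constant.
#' @param rep_rcut,rep_k soft repulsion range (nm) and constant.
#' @param coul_lambda,coul_kappa screened-Coulomb strength (nm, the Bjerrum
#'   length in reduced units) and screening length (nm).
#' @param wall_r,wall_k container radius (nm; default scales with
#'   generation) and wall constant.
#' @param seed RNG seed.
#' @return list with `system` and `traj`.
#' @export
gen_toy_dendrimer_trajectory <- function(generation = 2, spacer_kind = "2Arg",
                                         n_steps = 20000, dt = 0.002,
                                         save_every = 20, kT = 1,
                                         bond_r0 = 0.25, bond_k = 200,
                                         rep_rcut = 0.3, rep_k = 100,
                                         coul_lambda = 0.7, coul_kappa = 1.0,
                                         wall_r = NULL, wall_k = 20,
                                         seed = NULL) {
  sys <- build_toy_dendrimer(generation, spacer_kind)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(wall_r)) wall_r <- 2.0 + 0.8 * generation
  n <- nrow(sys$atoms)
  dend <- resolve_selection(sys, "dendrimer")
  ions <- resolve_selection(sys, "ions")
  ## initial placement: walk the bond tree; ions uniform in the container
  x0 <- matrix(0, n, 3)
  g <- bond_graph(sys)
  bf <- igraph::bfs(g, root = 1, unreachable = FALSE, father = TRUE)
  ordv <- suppressWarnings(as.integer(bf$order))
  fa <- suppressWarnings(as.integer(bf$father))
  ord <- ordv[!is.na(ordv)]
  for (i in ord) {
    p <- fa[i]
    if (!is.na(p) && p >= 1)
      x0[i, ] <- x0[p, ] + t(random_unit_vectors(1)) * bond_r0
  }
  if (length(ions)) {
    rr <- wall_r * 0.9 * runif(length(ions))^(1 / 3)
    x0[ions, ] <- t(random_unit_vectors(length(ions))) * rr
  }
  if (kT == 0) {
    nf <- max(1L, floor(n_steps / save_every))
    coords <- array(rep(x0, each = nf), dim = c(nf, n, 3))
    traj <- md_trajectory((seq_len(nf) - 1) * dt * save_every, coords)
  } else {
    res <- cpp_brownian(x0, sys$bonds, sys$atoms$charge, n_steps, dt,
                        save_every, kT, bond_r0, bond_k, rep_rcut, rep_k,
                        coul_lambda, coul_kappa, wall_r, wall_k)
    traj <- md_trajectory((seq_len(dim(res)[1]) - 1) * dt * save_every, res)
  }
  traj <- unwrap_or_center(traj, sys, "center")
  list(system = sys, traj = traj)
}
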