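## Electric double layer: charge profiles, Poisson potential, zeta,
## ion pairing and osmotic-ion balance.

#' Bjerrum length
#'
#' \eqn{\lambda_B = e^2 / (4 \pi \epsilon \epsilon_0 k_B T)}: the distance at
#' which the Coulomb energy of two elementary charges equals the thermal
#' energy. About 0.70 nm in water at 300 K.
#'
#' @param temperature absolute temperature (K).
#' @param epsilon relative dielectric permittivity (default 80, water).
#' @return lambda_B in nm.
#' @export
bjerrum_length <- function(temperature, epsilon = 80) {
  stopifnot(temperature > 0, epsilon > 0)
  lb_m <- .const$e_C^2 /
    (4 * pi * epsilon * .const$eps0_F_m * .const$kB_J * temperature)
  lb_m * 1e9
}

## thermal voltage kB*T/e in mV
thermal_voltage_mV <- function(temperature) {
  .const$kB_J * temperature / .const$e_C * 1e3
}

#' Construct charge profiles from binned charges
#'
#' Low-level constructor used by [charge_profiles] and by synthetic /
#' analytic inputs: takes net charge per radial bin and derives the
#' cumulative charge \eqn{Q(r)}, the radius `Rmax` of its maximum, the
#' effective (uncompensated) charge `Q_star = Q(Rmax)`, the surface charge
#' density `sigma = Q_star / (4 pi Rmax^2)` and the charge renormalization
#' degree `Q_star / Q_bare`.
#'
#' @param dr bin width (nm); bin k covers `[(k-1) dr, k dr)`.
#' @param q net charge per bin (e).
#' @param q_bare bare charge of the macroion (e).
#' @return object of class `charge_profiles` with fields `r` (bin upper
#'   edges, nm), `q`, `Q`, `Rmax`, `Q_star`, `sigma`, `renorm`, `dr`,
#'   `q_bare`.
#' @export
new_charge_profiles <- function(dr, q, q_bare) {
  stopifnot(dr > 0, length(q) >= 1)
  Q <- cumsum(q)
  edges <- dr * seq_along(q)
  if (abs(Q[length(Q)]) > 0.5)
    warning("charge does not close at the outer boundary (|Q| = ",
            round(abs(Q[length(Q)]), 2), " e)")
  i_max <- which.max(Q)
  r_max <- edges[i_max]
  q_star <- Q[i_max]
  structure(list(r = edges, q = q, Q = Q, dr = dr,
                 Rmax = r_max, Q_star = q_star,
                 sigma = surface_charge_density(q_star, r_max),
                 renorm = if (!is.na(q_bare) && q_bare != 0) q_star / q_bare else NA_real_,
                 q_bare = q_bare),
            class = "charge_profiles")
}

#' Surface charge density at the effective radius
#'
#' \eqn{\sigma = Q^* / (4 \pi R_{max}^2)}.
#'
#' @param q_star effective charge (e).
#' @param r_max effective macroion radius (nm).
#' @return sigma in e/nm^2.
#' @export
surface_charge_density <- function(q_star, r_max) q_star / (4 * pi * r_max^2)

#' Radial charge profiles of dendrimer + counterions
#'
#' Bins all charges (dendrimer and counterions; water excluded by default)
#' by distance to the dendrimer centre of mass, averaged over frames, and
#' derives the cumulative charge, effective charge Q*, Rmax, surface charge
#' density and renormalization degree (see [new_charge_profiles]).
#'
#' @inheritParams radius_of_gyration
#' @param dr bin width (nm), default 0.05.
#' @param include_water also bin water partial charges (default FALSE).
#' @return a `charge_profiles` object.
#' @export
charge_profiles <- function(traj, system, dr = 0.05, include_water = FALSE) {
  at <- system$atoms
  keep <- at$role %in% c("core", "backbone", "side_segment", "terminal_group",
                         "counterion")
  if (include_water) keep <- keep | at$role == "water_oxygen"
  ids <- at$atom_id[keep & at$charge != 0]
  if (!any(at$role[keep] == "counterion"))
    warning("no counterions present: cumulative charge will not return to 0")
  prof <- radial_density_profile(traj, system, ids, dr = dr, mode = "charge")
  new_charge_profiles(dr, prof$values, system$bare_charge)
}

#' Solve the spherically symmetric Poisson equation
#'
#' Computes the dimensionless electrostatic potential \eqn{\psi(r)} created
#' by the sampled radial charge distribution, i.e. the solution of
#' \eqn{\psi'' + (2/r)\psi' = -4\pi\lambda_B \rho(r)} with regularity at the
#' origin, where \eqn{\rho} is the charge number density (e/nm^3) implied by
#' the binned profile. The equation is integrated through its first
#' integral (Gauss's law), \eqn{\psi'(r) = -\lambda_B Q_{enc}(r)/r^2}, with
#' exact per-bin quadrature for the piecewise-constant shell density; the
#' outer boundary value is the point-charge continuation
#' \eqn{\psi(R_{out}) = \lambda_B Q(R_{out})/R_{out}} (zero for a
#' neutralized system). The zeta potential is read at `Rmax`, the effective
#' macroion radius identified with the slip plane, as
#' \eqn{\zeta = \psi(R_{max}) k_B T / e}.
#'
#' @param cp a `charge_profiles` object.
#' @param temperature temperature (K).
#' @param epsilon relative permittivity (default 80).
#' @return object of class `potential_profile`: `r` (grid = bin edges incl.
#'   0), `psi` (dimensionless), `Psi_mV`, `zeta_mV`, `bjerrum` (nm),
#'   `temperature`, `epsilon`.
#' @export
solve_poisson_spherical <- function(cp, temperature = 310, epsilon = 80) {
  stopifnot(inherits(cp, "charge_profiles"))
  lb <- bjerrum_length(temperature, epsilon)
  dr <- cp$dr
  K <- length(cp$q)
  a <- c(0, cp$r[-K])            # bin lower edges
  bnd <- cp$r                    # bin upper edges
  if (abs(cp$Q[K]) > 0.5)
    warning("charge profile does not close at the boundary; potential tail uses point-charge continuation")
  cvol <- (4 * pi / 3) * (bnd^3 - a^3)
  rho <- cp$q / cvol             # charge density per shell [e/nm^3]
  Qlow <- c(0, cp$Q[-K])         # enclosed charge at lower edge
  ck <- rho * 4 * pi / 3
  Ak <- Qlow - ck * a^3          # Q_enc(s) = Ak + ck s^3 within bin k
  ## contribution of bin k to psi drop across [a_k, b_k]:
  ## integral of Q_enc(s)/s^2 ds = A (1/a - 1/b) + c (b^2 - a^2)/2
  inv_a <- ifelse(a > 0, 1 / a, 0)   # A_1 = 0 when a = 0, term vanishes
  contrib <- lb * (Ak * (inv_a - 1 / bnd) + ck * (bnd^2 - a^2) / 2)
  ## psi at the bin edges (grid r = 0, dr, ..., K dr), integrating inward
  psi_edges <- rev(cumsum(rev(contrib)))     # drop from edge j-1 to outer
  psi <- c(psi_edges, 0) + lb * cp$Q[K] / bnd[K]   # outer BC continuation
  grid <- c(0, bnd)
  ## zeta at Rmax (a grid point by construction)
  zeta <- psi[match(cp$Rmax, grid)] * thermal_voltage_mV(temperature)
  structure(list(r = grid, psi = psi,
                 Psi_mV = psi * thermal_voltage_mV(temperature),
                 zeta_mV = zeta, bjerrum = lb,
                 temperature = temperature, epsilon = epsilon),
            class = "potential_profile")
}

#' Ion-pair and osmotic-ion accounting
#'
#' Computes the pair correlation function g(r) between counterions and each
#' charged-group selection, locates the first minimum after the first peak
#' on a 5-point moving-average smoothed curve, counts ion pairs as the
#' time-averaged number of (group, ion) contacts within that cutoff, and
#' closes the balance \eqn{\langle n^{osm}\rangle = Q_{bare} - Q^* -
#' \langle n^{pairs}\rangle} with the effective charge from the charge
#' profiles.
#'
#' @inheritParams radius_of_gyration
#' @param dr g(r) bin width (nm), default 0.01.
#' @param r_max g(r) range (nm), default 1.5.
#' @param groups named selections of charged groups to pair with the ions.
#' @param q_star effective charge Q* (e); if `NULL`, computed from
#'   [charge_profiles] on the same trajectory.
#' @return object of class `ion_pair_result`: per-selection `g` profiles and
#'   `cutoffs`, `n_pairs_mean` (total and per selection), `n_osmotic_mean`.
#' @export
ion_pair_analysis <- function(traj, system, dr = 0.01, r_max = 1.5,
                              groups = c("charged_side_groups",
                                         "terminal_charged_groups"),
                              q_star = NULL) {
  ions <- resolve_selection(system, "ions")
  if (!length(ions)) stop("selection error: no ions")
  nf <- n_frames(traj)
  nb <- ceiling(r_max / dr)
  centres <- (seq_len(nb) - 0.5) * dr
  out_g <- list(); cutoffs <- c(); n_pairs <- c()
  for (gname in groups) {
    gids <- resolve_selection(system, gname)
    if (!length(gids)) stop("selection error: empty selection '", gname, "'")
    counts <- numeric(nb)
    all_d <- vector("list", nf)
    for (f in seq_len(nf)) {
      xg <- matrix(traj$coords[f, gids, ], ncol = 3)
      xi <- matrix(traj$coords[f, ions, ], ncol = 3)
      d2 <- outer(rowSums(xg^2), rowSums(xi^2), "+") - 2 * tcrossprod(xg, xi)
      d <- sqrt(pmax(d2, 0))
      all_d[[f]] <- d[d < r_max]
      idx <- ceiling(all_d[[f]] / dr); idx[idx < 1] <- 1L
      tb <- tabulate(idx, nbins = nb)
      counts <- counts + tb
    }
    mean_counts <- counts / nf                       # pairs per frame per bin
    ## ideal-gas normalization within the analysis sphere of radius r_max
    pair_density <- length(gids) * length(ions) / ((4 / 3) * pi * r_max^3)
    g <- mean_counts / (4 * pi * centres^2 * dr * pair_density)
    ## first minimum after the first peak, on 5-point moving average
    sm <- stats::filter(g, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- g[is.na(sm)]
    cut <- NA_real_
    ipk <- which.max(sm)
    if (ipk < nb - 1) {
      after <- sm[(ipk + 1):nb]
      imin <- which(diff(after) > 0)[1]   # first upturn = local minimum
      if (!is.na(imin)) cut <- centres[ipk + imin]
    }
    if (is.na(cut) || sm[ipk] <= 1) {
      warning("no detectable first peak for '", gname,
              "'; falling back to 0.5 nm cutoff")
      cut <- 0.5
    }
    npair <- mean(vapply(all_d, function(d) sum(d < cut), numeric(1)))
    out_g[[gname]] <- data.frame(r = centres, g = as.numeric(sm), g_raw = g)
    cutoffs[gname] <- cut
    n_pairs[gname] <- npair
  }
  if (is.null(q_star)) q_star <- charge_profiles(traj, system)$Q_star
  n_tot <- sum(n_pairs)
  structure(list(g = out_g, cutoffs = cutoffs,
                 n_pairs = n_pairs, n_pairs_mean = n_tot,
                 q_star = q_star, q_bare = system$bare_charge,
                 n_osmotic_mean = osmotic_ion_count(system$bare_charge,
                                                    q_star, n_tot)),
            class = "ion_pair_result")
}

#' Osmotic-ion balance
#'
#' Counterions inside the macroion that are not in contact ion pairs:
#' \eqn{\langle n^{osm} \rangle = Q_{bare} - Q^* - \langle n^{pairs}
#' \rangle}.
#'
#' @param q_bare bare charge (e).
#' @param q_star effective charge (e).
#' @param n_pairs mean number of ion pairs.
#' @return mean number of osmotic ions.
#' @export
osmotic_ion_count <- function(q_bare, q_star, n_pairs) q_bare - q_star - n_pairs

#' Electrostatics summary table
#'
#' Assembles the double-layer summary (Q*, Q*/Qbare, sigma, zeta, ion pairs,
#' osmotic ions) for one trajectory at one temperature.
#'
#' @inheritParams charge_profiles
#' @param temperature temperature (K) for the Poisson solve and the label.
#' @param epsilon relative permittivity.
#' @return one-row data.frame.
#' @export
electrostatics_summary <- function(traj, system, temperature = 310,
                                   epsilon = 80, dr = 0.05) {
  cp <- charge_profiles(traj, system, dr = dr)
  pp <- solve_poisson_spherical(cp, temperature, epsilon)
  ip <- ion_pair_analysis(traj, system, q_star = cp$Q_star)
  data.frame(temperature = temperature,
             Q_star = cp$Q_star, renorm = cp$renorm, sigma = cp$sigma,
             Rmax = cp$Rmax, zeta_mV = pp$zeta_mV,
             n_ion_pairs = ip$n_pairs_mean,
             n_ion_osmotic = ip$n_osmotic_mean)
}
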