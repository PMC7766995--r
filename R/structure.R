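## Global and local structural descriptors of the dendrimer.

#' Radius of gyration and gyration tensor
#'
#' Computes, per frame, the mass-weighted radius of gyration
#' \eqn{R_g^2 = (1/M) \sum_i m_i r_i^2} (with \eqn{r_i} the distance of atom
#' i to the selection's centre of mass) together with the eigenvalues
#' \eqn{I_x \ge I_y \ge I_z} of the mass-weighted gyration tensor. The
#' per-frame identity \eqn{R_g^2 = I_x + I_y + I_z} holds by construction.
#'
#' @param traj an [md_trajectory].
#' @param system a [molecular_system].
#' @param selection selection name or integer atom ids (default: the whole
#'   dendrimer).
#' @return object of class `gyration_result`: list with `times`, per-frame
#'   `rg` (nm), eigenvalue matrix `eig` (nm^2, columns Ix >= Iy >= Iz),
#'   `rg_mean`, `rg_sd`, and `asphericity` computed from the time-averaged
#'   eigenvalues.
#' @export
radius_of_gyration <- function(traj, system, selection = "dendrimer") {
  ids <- if (is.character(selection)) resolve_selection(system, selection)
         else as.integer(selection)
  if (!length(ids)) stop("selection error: empty selection")
  m <- system$atoms$mass[ids]
  M <- sum(m)
  if (M <= 0) stop("computation error: zero total mass")
  nf <- n_frames(traj)
  rg <- numeric(nf)
  eig <- matrix(0, nf, 3, dimnames = list(NULL, c("Ix", "Iy", "Iz")))
  for (f in seq_len(nf)) {
    x <- matrix(traj$coords[f, ids, ], ncol = 3)
    d <- sweep(x, 2, colSums(x * m) / M)
    S <- crossprod(d * m, d) / M          # mass-weighted gyration tensor
    ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    eig[f, ] <- ev
    rg[f] <- sqrt(sum(ev))
  }
  structure(list(times = traj$times, rg = rg, eig = eig,
                 rg_mean = mean(rg), rg_sd = sd(rg),
                 asphericity = tryCatch(
                   asphericity_from_eigenvalues(colMeans(eig)),
                   error = function(e) NA_real_)),
            class = "gyration_result")
}

asphericity_from_eigenvalues <- function(ev) {
  s <- sum(ev)
  if (s <= 0) stop("computation error: all gyration eigenvalues are zero")
  unname(1 - 3 * (ev[1] * ev[2] + ev[1] * ev[3] + ev[2] * ev[3]) / s^2)
}

#' Asphericity parameter
#'
#' Shape measure \eqn{\alpha = 1 - 3 (I_x I_y + I_x I_z + I_y I_z) /
#' (I_x+I_y+I_z)^2}: 0 for a sphere, approaching 1 for a rod. By default the
#' time-averaged eigenvalues are combined into a single value (the quoted
#' summary statistic); `per_frame = TRUE` returns the frame series instead.
#'
#' @param gr a `gyration_result` from [radius_of_gyration].
#' @param per_frame return the per-frame series instead of the
#'   averaged-eigenvalue scalar.
#' @return numeric scalar in `[0, 1]`, or a vector if `per_frame`.
#' @export
asphericity <- function(gr, per_frame = FALSE) {
  stopifnot(inherits(gr, "gyration_result"))
  if (per_frame)
    return(apply(gr$eig, 1, asphericity_from_eigenvalues))
  asphericity_from_eigenvalues(colMeans(gr$eig))
}

#' Kirkwood hydrodynamic radius
#'
#' Estimates the hydrodynamic radius from the Kirkwood approximation
#' \eqn{R_h^{-1} = \langle r_{ij}^{-1} \rangle_{i \ne j}}: the inverse of
#' the time-averaged mean inverse pairwise distance within an atom subset.
#' Subsets mirror the common usage ladder: backbone atoms only, all heavy
#' dendrimer atoms, dendrimer + ions, and dendrimer + ions + water oxygens
#' close to the dendrimer.
#'
#' @param traj an [md_trajectory].
#' @param system a [molecular_system].
#' @param subset_mode one of `"backbone_CA"`, `"dendrimer_heavy"`,
#'   `"dendrimer_heavy_plus_ions"`, `"plus_near_water_O"`, or an explicit
#'   integer id vector.
#' @param near_cutoff distance threshold (nm) defining "close" water oxygens
#'   for the last mode; default 0.35 nm.
#' @return Rh in nm.
#' @export
kirkwood_hydrodynamic_radius <- function(traj, system,
                                         subset_mode = "dendrimer_heavy",
                                         near_cutoff = 0.35) {
  at <- system$atoms
  heavy <- at$atom_id[at$element != "H"]
  dend <- at$atom_id[at$role %in% c("core", "backbone", "side_segment", "terminal_group")]
  fixed_ids <- NULL
  if (is.numeric(subset_mode)) {
    fixed_ids <- as.integer(subset_mode)
  } else {
    fixed_ids <- switch(subset_mode,
      backbone_CA = intersect(heavy, at$atom_id[at$role %in% c("core", "backbone")]),
      dendrimer_heavy = intersect(heavy, dend),
      dendrimer_heavy_plus_ions = intersect(heavy, c(dend, at$atom_id[at$role == "counterion"])),
      plus_near_water_O = NULL,
      stop("unknown subset_mode '", subset_mode, "'"))
  }
  nf <- n_frames(traj)
  inv_means <- numeric(nf)
  for (f in seq_len(nf)) {
    ids <- fixed_ids
    if (is.null(ids)) {  # plus_near_water_O: frame-dependent subset
      base <- intersect(heavy, c(dend, at$atom_id[at$role == "counterion"]))
      wo <- at$atom_id[at$role == "water_oxygen"]
      if (length(wo)) {
        xd <- matrix(traj$coords[f, intersect(heavy, dend), ], ncol = 3)
        xw <- matrix(traj$coords[f, wo, ], ncol = 3)
        dmin <- apply(xw, 1, function(p)
          min(sqrt(colSums((t(xd) - p)^2))))
        base <- c(base, wo[dmin < near_cutoff])
      }
      ids <- base
    }
    if (length(ids) < 2) stop("computation error: subset of size < 2")
    x <- matrix(traj$coords[f, ids, ], ncol = 3)
    inv_means[f] <- mean(1 / stats::dist(x))
  }
  1 / mean(inv_means)
}

#' Terminal-group radius
#'
#' Root-mean-square radial distance of the terminal amine nitrogens from the
#' dendrimer centre of mass, \eqn{R_e = (\frac{1}{N_t}\sum_i r_i^2)^{1/2}},
#' averaged over frames. Estimates the position of the outer boundary of the
#' dendrimer; for a spherical molecule it is expected near the rigid-sphere
#' radius \eqn{\sqrt{5/3} R_g} (see [rigid_sphere_radius]).
#'
#' @inheritParams radius_of_gyration
#' @param selection terminal nitrogen selection name (default `terminal_N`).
#' @return Re in nm.
#' @export
terminal_group_radius <- function(traj, system, selection = "terminal_N") {
  ids <- if (is.character(selection)) resolve_selection(system, selection)
         else as.integer(selection)
  if (!length(ids)) stop("selection error: empty terminal selection")
  dend <- resolve_selection(system, "dendrimer")
  m <- system$atoms$mass[dend]
  nf <- n_frames(traj)
  ms <- numeric(nf)
  for (f in seq_len(nf)) {
    x <- matrix(traj$coords[f, , ], ncol = 3)
    com <- centre_of_mass(x[dend, , drop = FALSE], m)
    ms[f] <- mean(rowSums(sweep(x[ids, , drop = FALSE], 2, com)^2))
  }
  sqrt(mean(ms))
}

#' Rigid-sphere outer radius from the radius of gyration
#'
#' For a homogeneous rigid sphere \eqn{R = \sqrt{5/3}\, R_g}; used as the
#' theoretical outer-boundary estimate to compare with the terminal-group
#' radius Re.
#'
#' @param rg radius of gyration (nm).
#' @return radius in nm.
#' @export
rigid_sphere_radius <- function(rg) sqrt(5 / 3) * rg

#' Radial profile from the dendrimer centre of mass
#'
#' Bins atoms of a selection by their distance to the dendrimer centre of
#' mass, averaged over frames. `mode = "mass"` gives the mass density
#' \eqn{\rho(r)} (g/mol/nm^3, shell-volume normalised by \eqn{4\pi r^2 dr});
#' `"count"` the number density analogue \eqn{n_t(r)} used for terminal
#' groups; `"charge"` the charge per bin (e, *not* volume-normalised; see
#' [charge_profiles]).
#'
#' @inheritParams radius_of_gyration
#' @param dr bin width in nm (default 0.05).
#' @param mode `"mass"`, `"count"` or `"charge"`.
#' @param r_max outer radius (nm); defaults to the largest sampled distance.
#' @return object of class `radial_profile`: list with bin centres `r`,
#'   `values`, `dr`, `mode`, and `total` (mean binned weight per frame).
#' @export
radial_density_profile <- function(traj, system, selection = "dendrimer",
                                   dr = 0.05, mode = c("mass", "count", "charge"),
                                   r_max = NULL) {
  mode <- match.arg(mode)
  if (dr <= 0) stop("binning error: dr must be > 0")
  ids <- if (is.character(selection)) resolve_selection(system, selection)
         else as.integer(selection)
  if (!length(ids)) stop("selection error: empty selection")
  dend <- resolve_selection(system, "dendrimer")
  m <- system$atoms$mass[dend]
  w <- switch(mode, mass = system$atoms$mass[ids],
              count = rep(1, length(ids)),
              charge = system$atoms$charge[ids])
  nf <- n_frames(traj)
  ## first pass: radial distances
  rads <- matrix(0, nf, length(ids))
  for (f in seq_len(nf)) {
    x <- matrix(traj$coords[f, , ], ncol = 3)
    com <- centre_of_mass(x[dend, , drop = FALSE], m)
    rads[f, ] <- row_norms(sweep(x[ids, , drop = FALSE], 2, com))
  }
  extent <- max(rads)
  if (is.null(r_max)) r_max <- extent + dr
  if (dr > extent || dr > r_max)
    stop("binning error: dr exceeds the profile extent")
  nb <- ceiling(r_max / dr)
  edges <- seq(0, by = dr, length.out = nb + 1)
  centres <- edges[-1] - dr / 2
  hist_w <- numeric(nb)
  idx <- pmin(pmax(ceiling(rads / dr), 1L), nb)
  for (f in seq_len(nf)) {
    acc <- tapply(w, idx[f, ], sum)
    hist_w[as.integer(names(acc))] <- hist_w[as.integer(names(acc))] + acc
  }
  hist_w <- hist_w / nf
  values <- if (mode == "charge") hist_w else hist_w / (4 * pi * centres^2 * dr)
  structure(list(r = centres, values = values, dr = dr, mode = mode,
                 total = sum(hist_w), edges = edges),
            class = "radial_profile")
}

#' Congregation coefficient of terminal groups
#'
#' Angular clustering score of a selection about the dendrimer centre of
#' mass: for each member, the fraction of the other members lying within a
#' cone of the given half-angle about its radial direction is computed and
#' rescaled so that the fraction expected under a uniform angular
#' distribution maps to 0 and total coincidence maps to 1. Values near 1
#' indicate groups congregated in one spherical sector; values near 0 an
#' even angular spread.
#'
#' @inheritParams radius_of_gyration
#' @param selection member selection (default `terminal_N`).
#' @param cone_half_angle cone half-angle in degrees (default 45).
#' @return mean coefficient over frames (numeric scalar).
#' @export
congregation_coefficient <- function(traj, system, selection = "terminal_N",
                                     cone_half_angle = 45) {
  ids <- if (is.character(selection)) resolve_selection(system, selection)
         else as.integer(selection)
  if (length(ids) < 2) stop("selection error: need >= 2 members")
  dend <- resolve_selection(system, "dendrimer")
  m <- system$atoms$mass[dend]
  cmin <- cos(cone_half_angle * pi / 180)
  p0 <- (1 - cmin) / 2                     # uniform-null cone fraction
  nf <- n_frames(traj)
  ks <- numeric(nf)
  for (f in seq_len(nf)) {
    x <- matrix(traj$coords[f, , ], ncol = 3)
    com <- centre_of_mass(x[dend, , drop = FALSE], m)
    v <- sweep(x[ids, , drop = FALSE], 2, com)
    nv <- row_norms(v)
    if (any(nv < 1e-12)) {
      warning("selection member at the centre of mass skipped")
      v <- v[nv >= 1e-12, , drop = FALSE]
      nv <- nv[nv >= 1e-12]
    }
    u <- v / nv
    cc <- tcrossprod(u)
    diag(cc) <- NA
    f_i <- rowMeans(cc > cmin, na.rm = TRUE)
    ks[f] <- (mean(f_i) - p0) / (1 - p0)
  }
  mean(ks)
}

#' Structure summary table
#'
#' Assembles the per-temperature structural summary (asphericity, Rg, Rh,
#' Rh/Rg, rigid-sphere radius sqrt(5/3) Rg, Re, k45) for one trajectory.
#'
#' @inheritParams radius_of_gyration
#' @param temperature label (K) recorded in the table.
#' @param rh_mode subset mode for [kirkwood_hydrodynamic_radius].
#' @return one-row data.frame.
#' @export
structure_summary <- function(traj, system, temperature = NA,
                              rh_mode = "dendrimer_heavy") {
  gr <- radius_of_gyration(traj, system)
  rh <- kirkwood_hydrodynamic_radius(traj, system, rh_mode)
  re <- terminal_group_radius(traj, system)
  k45 <- congregation_coefficient(traj, system)
  data.frame(temperature = temperature,
             alpha = asphericity(gr),
             Rg = gr$rg_mean, Rg_sd = gr$rg_sd,
             Rh = rh, Rh_over_Rg = rh / gr$rg_mean,
             R_sphere = rigid_sphere_radius(gr$rg_mean),
             Re = re, k45 = k45)
}
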