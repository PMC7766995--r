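## Geometric hydrogen-bond detection, per-class statistics and continuous
## lifetimes with sub-frame spline refinement.

#' Identify hydrogen-bond donors and acceptors
#'
#' Donors are N/O atoms with at least one bonded hydrogen (one donor-H row
#' per hydrogen); acceptors are all N/O atoms. If an explicit donor id list
#' is supplied, every donor must carry a bonded hydrogen.
#'
#' @param system a [molecular_system].
#' @param donors optional integer ids to restrict the donor set.
#' @return list with `donors` (data.frame `donor`, `hydrogen`) and
#'   `acceptors` (integer ids).
#' @export
hbond_participants <- function(system, donors = NULL) {
  at <- system$atoms
  b <- system$bonds
  no <- at$atom_id[at$element %in% c("N", "O")]
  ## bonded hydrogens per heavy atom
  h1 <- b[at$element[b[, 2]] == "H", , drop = FALSE]
  h2 <- b[at$element[b[, 1]] == "H", c(2, 1), drop = FALSE]
  dh <- rbind(h1, h2)            # column 1 heavy, column 2 hydrogen
  dh <- dh[dh[, 1] %in% no, , drop = FALSE]
  if (!is.null(donors)) {
    missing_h <- setdiff(donors, dh[, 1])
    if (length(missing_h))
      stop("configuration error: donors without bonded hydrogens: ",
           paste(missing_h, collapse = ", "))
    dh <- dh[dh[, 1] %in% donors, , drop = FALSE]
  }
  list(donors = data.frame(donor = dh[, 1], hydrogen = dh[, 2]),
       acceptors = no)
}

#' Detect hydrogen bonds in one frame
#'
#' Geometric criteria: donor-acceptor distance < `d_cut` and the
#' H-donor-acceptor deviation-from-linearity angle (between the D->H and
#' D->A directions) < `angle_cut`.
#'
#' @param x `n x 3` coordinate matrix (nm).
#' @param donors data.frame with columns `donor`, `hydrogen`.
#' @param acceptors integer atom ids.
#' @param d_cut distance cutoff in nm (default 0.35).
#' @param angle_cut angle cutoff in degrees (default 30).
#' @return data.frame of satisfied triples with columns `donor`, `hydrogen`,
#'   `acceptor`, `distance`, `angle`.
#' @export
detect_hbonds <- function(x, donors, acceptors, d_cut = 0.35, angle_cut = 30) {
  nd <- nrow(donors); na <- length(acceptors)
  xd <- x[donors$donor, , drop = FALSE]
  ## chunk the acceptor axis so the pair matrices stay bounded
  chunk <- max(1L, floor(5e6 / max(nd, 1L)))
  out <- list()
  for (s in seq(1, na, by = chunk)) {
    ai <- acceptors[s:min(na, s + chunk - 1L)]
    xa <- x[ai, , drop = FALSE]
    d2 <- outer(rowSums(xd^2), rowSums(xa^2), "+") - 2 * tcrossprod(xd, xa)
    hit <- which(d2 < d_cut^2, arr.ind = TRUE)
    if (!nrow(hit)) next
    D <- donors$donor[hit[, 1]]; H <- donors$hydrogen[hit[, 1]]
    A <- ai[hit[, 2]]
    keep <- D != A & H != A
    D <- D[keep]; H <- H[keep]; A <- A[keep]
    if (!length(D)) next
    vda <- x[A, , drop = FALSE] - x[D, , drop = FALSE]
    vdh <- x[H, , drop = FALSE] - x[D, , drop = FALSE]
    dda <- row_norms(vda)
    cosang <- rowSums(vda * vdh) / (dda * row_norms(vdh))
    ang <- acos(clamp(cosang, -1, 1)) * 180 / pi
    ok <- ang < angle_cut
    if (any(ok))
      out[[length(out) + 1L]] <- data.frame(
        donor = D[ok], hydrogen = H[ok], acceptor = A[ok],
        distance = dda[ok], angle = ang[ok])
  }
  if (!length(out))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric()))
  do.call(rbind, out)
}

## partner-class label from the donor/acceptor roles
hbond_class <- function(system, donor, acceptor) {
  r <- system$atoms$role
  dend_roles <- c("core", "backbone", "side_segment", "terminal_group")
  dw <- (r[donor] == "water_oxygen") != (r[acceptor] == "water_oxygen")
  id <- r[donor] %in% dend_roles & r[acceptor] %in% dend_roles
  side_involved <- r[donor] == "side_segment" | r[acceptor] == "side_segment"
  cls <- rep("other", length(donor))
  cls[dw] <- "dendrimer_water"
  cls[id] <- "intra_dendrimer"
  attr(cls, "side") <- side_involved
  cls
}

#' Hydrogen-bond statistics over a trajectory
#'
#' Per-frame hydrogen-bond counts by partner class (dendrimer-water,
#' intra-dendrimer, side-segment-water, side-side), count histograms, time
#' means, and the per-spacer normalization of the side-segment-water count
#' (divided by the number of inserted residues `Nins`).
#'
#' @param traj an [md_trajectory].
#' @param system a [molecular_system].
#' @param d_cut,angle_cut geometric criteria (nm, degrees).
#' @return object of class `hbond_summary`: `counts` (data.frame per frame),
#'   `mean_dw`, `mean_id`, `mean_dw_side`, `per_spacer`, `hist_dw`.
#' @export
hbond_statistics <- function(traj, system, d_cut = 0.35, angle_cut = 30) {
  p <- hbond_participants(system)
  if (!nrow(p$donors)) stop("selection error: no hydrogen-bond donors")
  nf <- n_frames(traj)
  r <- system$atoms$role
  cnt <- data.frame(frame = seq_len(nf), dendrimer_water = 0,
                    intra_dendrimer = 0, side_water = 0, side_side = 0)
  for (f in seq_len(nf)) {
    hb <- detect_hbonds(frame_coords(traj, f), p$donors, p$acceptors,
                        d_cut, angle_cut)
    if (!nrow(hb)) next
    cls <- hbond_class(system, hb$donor, hb$acceptor)
    side <- attr(cls, "side")
    cnt$dendrimer_water[f] <- sum(cls == "dendrimer_water")
    cnt$intra_dendrimer[f] <- sum(cls == "intra_dendrimer")
    cnt$side_water[f] <- sum(cls == "dendrimer_water" & side)
    cnt$side_side[f] <- sum(cls == "intra_dendrimer" &
                              r[hb$donor] == "side_segment" &
                              r[hb$acceptor] == "side_segment")
  }
  nins <- system$counts$Nins %||% NA_integer_
  structure(list(counts = cnt,
                 mean_dw = mean(cnt$dendrimer_water),
                 mean_id = mean(cnt$intra_dendrimer),
                 mean_dw_side = mean(cnt$side_water),
                 per_spacer = hbond_per_spacer(mean(cnt$side_water), nins),
                 hist_dw = table(cnt$dendrimer_water)),
            class = "hbond_summary")
}

#' Per-spacer hydrogen-bond normalization
#'
#' Mean side-segment-water hydrogen-bond count divided by the number of
#' inserted spacer residues.
#'
#' @param mean_side mean side-segment-water HB count.
#' @param nins number of inserted residues.
#' @return bonds per spacer residue.
#' @export
hbond_per_spacer <- function(mean_side, nins) mean_side / nins

#' Track hydrogen-bond events along a trajectory
#'
#' Detects every (donor, hydrogen, acceptor) triple that is bonded in at
#' least one frame, then evaluates its geometry in every frame, returning
#' the on/off indicator and the signed, dimensionless criterion margin
#' `min((d_cut - d)/d_cut, (angle_cut - theta)/angle_cut)` used for
#' sub-frame refinement of bond formation/breaking instants.
#'
#' @inheritParams hbond_statistics
#' @return list with `triples` (data.frame), `indicator` (frames x triples
#'   logical matrix), `margins` (frames x triples numeric matrix), `dt`.
#' @export
hbond_event_series <- function(traj, system, d_cut = 0.35, angle_cut = 30) {
  p <- hbond_participants(system)
  nf <- n_frames(traj)
  keys <- character(0); trip <- list()
  for (f in seq_len(nf)) {
    hb <- detect_hbonds(frame_coords(traj, f), p$donors, p$acceptors,
                        d_cut, angle_cut)
    if (!nrow(hb)) next
    k <- paste(hb$donor, hb$hydrogen, hb$acceptor)
    new <- !(k %in% keys)
    if (any(new)) {
      keys <- c(keys, k[new])
      trip <- c(trip, split(hb[new, 1:3], seq_len(sum(new))))
    }
  }
  if (!length(keys))
    return(list(triples = data.frame(), indicator = NULL, margins = NULL,
                dt = timestep(traj)))
  triples <- do.call(rbind, trip)
  nt <- nrow(triples)
  ind <- matrix(FALSE, nf, nt)
  mar <- matrix(0, nf, nt)
  for (f in seq_len(nf)) {
    x <- frame_coords(traj, f)
    vda <- x[triples$acceptor, , drop = FALSE] - x[triples$donor, , drop = FALSE]
    vdh <- x[triples$hydrogen, , drop = FALSE] - x[triples$donor, , drop = FALSE]
    d <- row_norms(vda)
    ang <- acos(clamp(rowSums(vda * vdh) / (d * row_norms(vdh)), -1, 1)) * 180 / pi
    mar[f, ] <- pmin((d_cut - d) / d_cut, (angle_cut - ang) / angle_cut)
    ind[f, ] <- d < d_cut & ang < angle_cut
  }
  list(triples = triples, indicator = ind, margins = mar, dt = timestep(traj))
}

#' Continuous hydrogen-bond lifetimes
#'
#' Computes per-event continuous durations from on/off indicator series: a
#' bond's lifetime is the time it satisfies the geometric criteria without
#' interruption (transient breaks are not bridged). Without refinement an
#' event spanning k frames lasts `k * dt`. With `margins` supplied, the
#' formation and breaking instants are refined by interpolating the signed
#' criterion margin with a cubic spline through the 4 frames bracketing each
#' transition and taking its zero crossing. Events touching the trajectory
#' boundary are censored and excluded from the mean.
#'
#' @param indicator logical matrix (frames x bonds) or vector.
#' @param dt frame spacing (ps).
#' @param margins optional numeric matrix of criterion margins (same shape)
#'   enabling spline refinement.
#' @return list with `durations` (ps), `n_censored`, `mean` (ps).
#' @export
continuous_lifetimes <- function(indicator, dt, margins = NULL) {
  if (is.vector(indicator)) indicator <- matrix(indicator, ncol = 1)
  if (!is.null(margins) && is.vector(margins)) margins <- matrix(margins, ncol = 1)
  nf <- nrow(indicator)
  times <- (seq_len(nf) - 1) * dt
  durations <- numeric(0); n_cens <- 0L
  for (j in seq_len(ncol(indicator))) {
    r <- rle(as.logical(indicator[, j]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      s <- starts[k]; e <- ends[k]
      if (s == 1L || e == nf) { n_cens <- n_cens + 1L; next }
      if (is.null(margins)) {
        durations <- c(durations, (e - s + 1L) * dt)
      } else {
        t_on <- refine_crossing(times, margins[, j], s - 1L, rising = TRUE)
        t_off <- refine_crossing(times, margins[, j], e, rising = FALSE)
        durations <- c(durations, t_off - t_on)
      }
    }
  }
  list(durations = durations, n_censored = n_cens,
       mean = if (length(durations)) mean(durations) else NA_real_)
}

## zero crossing of the margin between frames i and i+1 (1-based), cubic
## spline through up to 4 bracketing frames, clamped into the bracket
refine_crossing <- function(times, margin, i, rising) {
  idx <- max(1L, i - 1L):min(length(times), i + 2L)
  f <- splinefun(times[idx], margin[idx], method = "natural")
  lo <- times[i]; hi <- times[i + 1L]
  root <- tryCatch(uniroot(f, c(lo, hi))$root, error = function(e) {
    ## margin may not change sign exactly at this pair (numerical ties):
    ## fall back to the linear crossing
    m0 <- margin[i]; m1 <- margin[i + 1L]
    if (m1 != m0) lo + (hi - lo) * (0 - m0) / (m1 - m0) else (lo + hi) / 2
  })
  clamp(root, lo, hi)
}
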