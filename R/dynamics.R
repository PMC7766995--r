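## Orientational autocorrelation functions and characteristic times.

#' Construct a unit-vector time series
#'
#' @param times frame times (ps), uniformly spaced.
#' @param u array `[n_frames, 3, n_instances]` of unit vectors.
#' @param label class label (e.g. `inner`, `side_3`, `core_to_end`).
#' @param normalize renormalize vectors instead of validating.
#' @return object of class `vector_series`.
#' @export
vector_series <- function(times, u, label = "", normalize = FALSE) {
  if (length(dim(u)) == 2) u <- array(u, dim = c(dim(u), 1))
  stopifnot(length(dim(u)) == 3, dim(u)[2] == 3, dim(u)[1] == length(times))
  if (!is_uniform_times(times))
    stop("vector series requires uniform time spacing")
  nrm <- sqrt(u[, 1, , drop = FALSE]^2 + u[, 2, , drop = FALSE]^2 +
                u[, 3, , drop = FALSE]^2)
  if (normalize) {
    u <- sweep_norm(u)
  } else if (any(abs(nrm - 1) > 1e-6)) {
    stop("vectors are not normalized (max deviation ",
         format(max(abs(nrm - 1))), ")")
  }
  structure(list(times = as.numeric(times), u = u, label = label),
            class = "vector_series")
}

sweep_norm <- function(u) {
  for (i in seq_len(dim(u)[3])) {
    m <- matrix(u[, , i], ncol = 3)
    u[, , i] <- m / row_norms(m)
  }
  u
}

#' Construct a correlation function object
#'
#' @param lags lag times (ps), starting at 0.
#' @param values ACF values (value 1 at lag 0).
#' @param order Legendre order 1 or 2, or `"scalar"` for the size-pulsation
#'   ACF.
#' @param n_instances number of vector instances averaged.
#' @param n_origins number of time origins per lag.
#' @return object of class `correlation_function`.
#' @export
correlation_function <- function(lags, values, order, n_instances = 1,
                                 n_origins = NULL) {
  stopifnot(length(lags) == length(values))
  structure(list(lags = lags, values = values, order = order,
                 n_instances = n_instances,
                 n_origins = n_origins %||% rep(NA_integer_, length(lags))),
            class = "correlation_function")
}

#' @export
print.correlation_function <- function(x, ...) {
  cat("correlation_function: order", x$order, "-", length(x$lags), "lags,",
      x$n_instances, "instance(s)\n")
  invisible(x)
}

#' Orientational autocorrelation function P1 / P2
#'
#' Multi-origin, multi-instance averaged orientational ACF of a unit-vector
#' series: order 1 is the mean direction cosine
#' \eqn{P_1(t) = \langle u(\tau) \cdot u(\tau+t) \rangle}, order 2 the
#' second Legendre polynomial
#' \eqn{P_2(t) = \langle \frac{3}{2} (u(\tau)\cdot u(\tau+t))^2 -
#' \frac{1}{2} \rangle}. All time origins are used; the lag window is
#' capped at a fraction of the series length for variance control. A sparse
#' lag subset can be requested for long series (computed by a direct
#' accumulation kernel rather than FFT).
#'
#' @param vs a [vector_series].
#' @param order 1 or 2.
#' @param max_lag_frac lag window as fraction of the series length
#'   (default 0.1).
#' @param lags optional integer frame-lag subset (0 allowed).
#' @return a [correlation_function].
#' @export
orientational_acf <- function(vs, order = 2, max_lag_frac = 0.1, lags = NULL) {
  stopifnot(inherits(vs, "vector_series"), order %in% c(1, 2))
  n <- dim(vs$u)[1]; m <- dim(vs$u)[3]
  if (n < 2) stop("need at least 2 frames")
  dt <- if (n > 1) vs$times[2] - vs$times[1] else 1
  if (!is.null(lags)) {
    lags <- sort(unique(as.integer(lags)))
    stopifnot(all(lags >= 0), all(lags < n))
    s <- cpp_vector_acf_lags(vs$u, lags)
    vals <- if (order == 1) s$s1 / s$counts
            else 1.5 * s$s2 / s$counts - 0.5
    return(correlation_function(lags * dt, vals, order, m, s$counts / m))
  }
  max_lag <- max(1L, floor(n * max_lag_frac))
  counts <- (n - 0:(n - 1))
  if (order == 1) {
    s <- numeric(n)
    for (i in seq_len(m))
      for (c in 1:3) s <- s + acf_sums_fft(vs$u[, c, i])
    vals <- (s / (counts * m))[1:(max_lag + 1)]
  } else {
    s <- numeric(n)
    w <- c(1, 1, 1, 2, 2, 2)
    combs <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
    for (i in seq_len(m))
      for (k in seq_along(combs)) {
        q <- vs$u[, combs[[k]][1], i] * vs$u[, combs[[k]][2], i]
        s <- s + w[k] * acf_sums_fft(q)
      }
    vals <- (1.5 * s / (counts * m) - 0.5)[1:(max_lag + 1)]
  }
  correlation_function((0:max_lag) * dt, vals, order, m, counts[1:(max_lag + 1)])
}

#' Size-pulsation autocorrelation function
#'
#' Normalized autocovariance of a scalar series such as \eqn{R_g^2(t)}:
#' \eqn{C(t) = (\langle x(\tau) x(\tau+t)\rangle - \langle x \rangle^2) /
#' (\langle x^2 \rangle - \langle x \rangle^2)}.
#'
#' @param x scalar series.
#' @param dt frame spacing (ps).
#' @param max_lag_frac lag window fraction (default 0.1).
#' @return a [correlation_function] with order `"scalar"`.
#' @export
scalar_acf <- function(x, dt = 1, max_lag_frac = 0.1) {
  n <- length(x)
  if (n < 2) stop("need at least 2 points")
  v <- var(x) * (n - 1) / n
  if (v < .Machine$double.eps * max(1, mean(x)^2))
    stop("zero-variance error: the series is constant")
  xc <- x - mean(x)
  s <- acf_sums_fft(xc)
  counts <- n - 0:(n - 1)
  max_lag <- max(1L, floor(n * max_lag_frac))
  vals <- (s / counts)[1:(max_lag + 1)] / v
  correlation_function((0:max_lag) * dt, vals, "scalar", 1,
                       counts[1:(max_lag + 1)])
}

#' Characteristic (1/e) correlation time
#'
#' Locates the first crossing of the ACF below `1/e` by log-linear
#' interpolation between the bracketing lags. If the ACF does not decay
#' below the level within the lag window the result is censored and the
#' window end is reported as a lower bound.
#'
#' @param cf a [correlation_function].
#' @param level crossing level (default `exp(-1)`).
#' @return list with `tau` (ps; `NA` if censored), `censored`, `lower_bound`
#'   (ps).
#' @export
characteristic_time <- function(cf, level = exp(-1)) {
  v <- cf$values; tt <- cf$lags
  below <- which(v < level)
  if (!length(below))
    return(list(tau = NA_real_, censored = TRUE, lower_bound = max(tt)))
  k <- below[1]
  if (k == 1) return(list(tau = tt[1], censored = FALSE, lower_bound = NA))
  v0 <- v[k - 1]; v1 <- v[k]
  tau <- if (v1 > 0)
    tt[k - 1] + (tt[k] - tt[k - 1]) * (log(v0) - log(level)) / (log(v0) - log(v1))
  else
    tt[k - 1] + (tt[k] - tt[k - 1]) * (v0 - level) / (v0 - v1)
  list(tau = tau, censored = FALSE, lower_bound = NA)
}

#' Check the P2 = P1^3 relation
#'
#' For isotropic rotational diffusion the first- and second-order
#' orientational ACFs obey \eqn{P_2(t) = P_1(t)^3} exactly
#' (\eqn{e^{-6 D_r t} = (e^{-2 D_r t})^3}); deviations signal anisotropic
#' or multi-process reorientation. Reports the maximum absolute deviation
#' over lags where `P1 > p1_min`.
#'
#' @param p1cf,p2cf [correlation_function]s of order 1 and 2 on a common
#'   lag grid.
#' @param p1_min smallest P1 value included (default 0.1).
#' @param tol pass/fail tolerance on the max deviation (default 1e-3).
#' @return list with `max_deviation`, `pass`, `n_lags`, `deviation` series.
#' @export
p1_cubed_check <- function(p1cf, p2cf, p1_min = 0.1, tol = 1e-3) {
  stopifnot(identical(p1cf$lags, p2cf$lags))
  keep <- p1cf$values > p1_min
  dev <- p2cf$values[keep] - p1cf$values[keep]^3
  list(max_deviation = max(abs(dev)), pass = max(abs(dev)) < tol,
       n_lags = sum(keep),
       deviation = data.frame(lag = p1cf$lags[keep], deviation = dev))
}

## ------------------------------------------- vector extraction helpers ----

## canonicalize instantaneous vector signs by temporal continuity
canonicalize_sign <- function(u) {
  for (i in seq_len(dim(u)[3])) {
    m <- matrix(u[, , i], ncol = 3)
    d <- rowSums(m[-1, , drop = FALSE] * m[-nrow(m), , drop = FALSE])
    flip <- cumprod(c(1, sign(ifelse(d == 0, 1, d))))
    u[, , i] <- m * flip
  }
  u
}

#' Core-to-end unit-vector series
#'
#' Unit vectors connecting the first branching point in the dendrimer core
#' to the carbon atoms of the terminal amine groups (one instance per
#' terminal group), used for the whole-molecule rotational ACFs.
#'
#' @param traj an [md_trajectory].
#' @param system a [molecular_system] with `core_branch_point` and
#'   `terminal_C` selections.
#' @return a [vector_series].
#' @export
core_to_end_series <- function(traj, system) {
  core <- resolve_selection(system, "core_branch_point")[1]
  term <- resolve_selection(system, "terminal_C")
  nf <- n_frames(traj)
  u <- array(0, dim = c(nf, 3, length(term)))
  for (f in seq_len(nf)) {
    x <- frame_coords(traj, f)
    v <- sweep(x[term, , drop = FALSE], 2, x[core, ])
    u[f, , ] <- t(v / row_norms(v))
  }
  vector_series(traj$times, u, "core_to_end")
}

#' CH2-group orientation series by class
#'
#' Extracts one unit-vector series per CH2 mobility class: side-segment
#' groups pooled by topological distance to the segment end (classes
#' `side_1` ... `side_5`), plus `inner` and `terminal` CH2 groups. For
#' atomistic systems the vector is the H-H difference of the group's two
#' bonded hydrogens; for coarse-grained (one bead per CH2 group) systems
#' the direction between the two flanking bonded heavy atoms is used as the
#' group's orientation proxy. Signs are canonicalized by temporal
#' continuity so that P1 is well defined (only P2 feeds the NMR
#' observables, which are sign-blind).
#'
#' @param traj an [md_trajectory].
#' @param system a [molecular_system] with CH2 annotation.
#' @return named list of [vector_series].
#' @export
ch2_vector_series <- function(traj, system) {
  at <- system$atoms
  labs <- label_topological_distance(system)
  groups <- split(labs$group_id, paste0("side_", labs$n_bonds_to_segment_end))
  for (cl in c("inner", "terminal")) {
    ids <- at$atom_id[!is.na(at$ch2_class) & at$ch2_class == cl]
    if (length(ids)) groups[[cl]] <- ids
  }
  nbrs <- split(c(system$bonds[, 2], system$bonds[, 1]),
                c(system$bonds[, 1], system$bonds[, 2]))
  nf <- n_frames(traj)
  out <- list()
  for (cl in names(groups)) {
    ids <- groups[[cl]]
    ends <- lapply(ids, function(i) {
      nb <- nbrs[[as.character(i)]]
      h <- nb[at$element[nb] == "H"]
      if (length(h) >= 2) h[1:2] else {
        heavy <- nb[at$element[nb] != "H"]
        if (length(heavy) < 2)
          stop("topology error: CH2 atom ", i, " lacks two neighbours")
        heavy[1:2]
      }
    })
    u <- array(0, dim = c(nf, 3, length(ids)))
    for (f in seq_len(nf)) {
      x <- frame_coords(traj, f)
      for (k in seq_along(ends)) {
        v <- x[ends[[k]][2], ] - x[ends[[k]][1], ]
        u[f, , k] <- v / sqrt(sum(v * v))
      }
    }
    out[[cl]] <- vector_series(traj$times, canonicalize_sign(u), cl)
  }
  out
}

#' Orientational mobility by topological distance class
#'
#' Pools CH2-group orientation vectors by their topological distance to the
#' side-segment end, computes the P2 ACF per class and the 1/e
#' characteristic time, and returns a per-class mobility table. Accepts
#' either a named list of [vector_series] (one per class) or a trajectory +
#' system pair (classes extracted via [ch2_vector_series]).
#'
#' @param x named list of [vector_series], or an [md_trajectory].
#' @param system required when `x` is a trajectory.
#' @param lags optional integer frame-lag subset passed to
#'   [orientational_acf].
#' @param max_lag_frac lag window fraction for the full-lag path.
#' @return list with `table` (data.frame: class, tau_ps, censored,
#'   n_instances) and `acfs` (named list of [correlation_function]).
#' @export
group_mobility_by_topology <- function(x, system = NULL, lags = NULL,
                                       max_lag_frac = 0.1) {
  if (inherits(x, "md_trajectory")) {
    stopifnot(!is.null(system))
    x <- ch2_vector_series(x, system)
  }
  stopifnot(is.list(x), length(x) >= 1)
  acfs <- lapply(x, orientational_acf, order = 2,
                 max_lag_frac = max_lag_frac, lags = lags)
  taus <- lapply(acfs, characteristic_time)
  tab <- data.frame(
    class = names(x),
    tau_ps = vapply(taus, function(t) t$tau %||% NA_real_, numeric(1)),
    censored = vapply(taus, `[[`, logical(1), "censored"),
    n_instances = vapply(x, function(v) dim(v$u)[3], numeric(1)),
    row.names = NULL)
  list(table = tab, acfs = acfs)
}
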