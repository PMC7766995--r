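## Spectral densities and spin-lattice relaxation observables.

#' Default angular-frequency grid
#'
#' Log-spaced grid in rad/ps covering the dispersion range of the reduced
#' relaxation rate curves.
#'
#' @param n number of points.
#' @param range frequency range in rad/ps.
#' @return numeric vector (rad/ps).
#' @export
omega_grid <- function(n = 120, range = c(1e-5, 1e2)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

## fit sum of n_exp decaying exponentials to (t, v); returns coef list or NULL
fit_exp_sum <- function(t, v, n_exp, tau0) {
  taus <- tau0 * 3^(seq_len(n_exp) - (n_exp + 1) / 2)
  a0 <- rep(max(v[1], 0.5) / n_exp, n_exp)
  an <- paste0("a", seq_len(n_exp)); tn <- paste0("tau", seq_len(n_exp))
  rhs <- paste(sprintf("%s*exp(-t/%s)", an, tn), collapse = " + ")
  start <- as.list(c(setNames(a0, an), setNames(taus, tn)))
  dat <- data.frame(t = t, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(stats::as.formula(paste("v ~", rhs)), data = dat,
                      start = start,
                      lower = rep(c(-0.2, min(diff(t)[1] / 10, tau0 * 1e-3)),
                                  each = n_exp),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  fit
}

## pick 1..n_max exponential fit by BIC; returns data.frame(a, tau) or NULL
select_exp_fit <- function(t, v, n_max = 3) {
  ct <- characteristic_time(correlation_function(t, v, 2))
  tau0 <- if (!is.na(ct$tau)) ct$tau else max(t) / 3
  best <- NULL; best_bic <- Inf
  for (n in seq_len(n_max)) {
    fit <- fit_exp_sum(t, v, n, tau0)
    if (is.null(fit)) next
    bic <- tryCatch(stats::BIC(fit), error = function(e) Inf)
    if (bic < best_bic - 2) { best <- fit; best_bic <- bic }
  }
  if (is.null(best)) return(NULL)
  cf <- coef(best)
  n <- length(cf) / 2
  data.frame(a = cf[seq_len(n)], tau = cf[n + seq_len(n)])
}

#' Spectral density J(omega) of an orientational ACF
#'
#' Cosine Fourier transform \eqn{J(\omega) = 2 \int_0^\infty P_2(t)
#' \cos(\omega t)\, dt}, computed by trapezoidal quadrature over the
#' sampled lag window plus an analytic tail contribution from a fitted
#' 1-3-exponential extension of the ACF beyond the window (`exp_fit`, the
#' default; order chosen by BIC) or no tail at all (`truncate`).
#'
#' For an exponential ACF \eqn{e^{-t/\tau}} this reproduces the Lorentzian
#' \eqn{J(\omega) = 2\tau / (1 + \omega^2 \tau^2)}.
#'
#' @param cf a [correlation_function] (order 2).
#' @param omega angular frequencies (rad/ps).
#' @param tail_mode `"exp_fit"` or `"truncate"`.
#' @param n_exp_max maximum number of exponentials in the tail fit.
#' @return object of class `relaxation_spectrum`: `omega` (rad/ps), `J`
#'   (ps), `tail_mode`, `tail_fit` (data.frame a/tau or NULL).
#' @export
spectral_density <- function(cf, omega = omega_grid(),
                             tail_mode = c("exp_fit", "truncate"),
                             n_exp_max = 3) {
  tail_mode <- match.arg(tail_mode)
  t <- cf$lags; v <- cf$values
  stopifnot(length(t) >= 3)
  Tend <- t[length(t)]
  fit <- NULL
  if (tail_mode == "exp_fit") {
    fit <- select_exp_fit(t, v, n_exp_max)
    if (is.null(fit)) {
      warning("exponential tail fit failed; truncating the transform")
      tail_mode <- "truncate"
    }
  }
  if (tail_mode == "truncate" && abs(v[length(v)]) > 0.05)
    warning("ACF has not decayed at the window end; J(omega) is biased at low frequency")
  ## window part: 2 * trapz( v(t) cos(wt) )
  wts <- diff(t)
  J <- vapply(omega, function(w) {
    integ <- v * cos(w * t)
    sum(wts * (integ[-1] + integ[-length(integ)]))  # 2 * trapz / 2 * 2
  }, numeric(1))
  if (!is.null(fit) && tail_mode == "exp_fit") {
    for (k in seq_len(nrow(fit))) {
      s <- 1 / fit$tau[k]
      J <- J + 2 * fit$a[k] * exp(-s * Tend) *
        (s * cos(omega * Tend) - omega * sin(omega * Tend)) / (s^2 + omega^2)
    }
  }
  structure(list(omega = omega, J = J, tail_mode = tail_mode, tail_fit = fit),
            class = "relaxation_spectrum")
}

#' Reduced spin-lattice relaxation rate
#'
#' Susceptibility-representation reduced rate
#' \eqn{(1/T_1)^{red}(\omega) = \omega [J(\omega) + 4 J(2\omega)]},
#' dimensionless, computed from the P2 ACF via [spectral_density] at
#' \eqn{\omega} and \eqn{2\omega}.
#'
#' @param cf a [correlation_function] of order 2.
#' @param omega angular frequencies (rad/ps).
#' @param ... passed to [spectral_density].
#' @return list with `omega`, `rate` (dimensionless), `J`, `J2`.
#' @export
t1_reduced <- function(cf, omega = omega_grid(), ...) {
  sd1 <- spectral_density(cf, omega, ...)
  sd2 <- spectral_density(cf, 2 * omega, ...)
  list(omega = omega, rate = omega * (sd1$J + 4 * sd2$J),
       J = sd1$J, J2 = sd2$J)
}

#' Physical 1/T1 in the susceptibility representation
#'
#' Converts the dimensionless reduced rate at the spectrometer frequency to
#' the measured spin-lattice relaxation rate:
#' \eqn{1/T_{1H} = (A_0 / \omega_H) (1/T_1)^{red}}, with \eqn{A_0} the
#' quantum-chemical dipolar constant (theory value 0.56e10 s^-2 for CH2
#' groups) and \eqn{\omega_H} the spectrometer angular frequency.
#'
#' @param reduced dimensionless reduced rate (scalar or vector).
#' @param A0 dipolar constant (s^-2), default 0.56e10.
#' @param omega_H spectrometer angular frequency (rad/s), default
#'   `2*pi*400e6` (a 400 MHz proton spectrometer).
#' @return 1/T1 in s^-1.
#' @export
t1_susceptibility <- function(reduced, A0 = 0.56e10, omega_H = 2 * pi * 400e6) {
  stopifnot(A0 > 0, omega_H > 0)
  A0 / omega_H * reduced
}

#' Per-class NMR relaxation table
#'
#' Computes, for each CH2 mobility class of a trajectory, the P2 ACF, the
#' 1/e correlation time, and the reduced and physical 1/T1 at the
#' spectrometer frequency. A0 defaults to the theoretical CH2 value with an
#' optional per-class override table.
#'
#' @inheritParams group_mobility_by_topology
#' @param temperature temperature label (K).
#' @param freq_mhz spectrometer frequency in MHz (default 400).
#' @param A0 default dipolar constant (s^-2).
#' @param A0_override named numeric vector of per-class A0 values.
#' @param ... passed to [spectral_density].
#' @return list with `table` (class, tau_ps, reduced_rate, t1h_rate) and
#'   `acfs`.
#' @export
nmr_relaxation_summary <- function(x, system = NULL, temperature = NA,
                                   freq_mhz = 400, A0 = 0.56e10,
                                   A0_override = c(), lags = NULL,
                                   max_lag_frac = 0.1, ...) {
  gm <- group_mobility_by_topology(x, system, lags = lags,
                                   max_lag_frac = max_lag_frac)
  ## spectrometer frequency in rad/ps: 2*pi*f[MHz]*1e6 / 1e12
  w_ps <- 2 * pi * freq_mhz * 1e-6
  red <- vapply(gm$acfs, function(cf)
    t1_reduced(cf, omega = w_ps, ...)$rate, numeric(1))
  a0s <- setNames(rep(A0, length(red)), names(red))
  a0s[names(A0_override)] <- A0_override
  tab <- gm$table
  tab$temperature <- temperature
  tab$reduced_rate <- unname(red)
  tab$t1h_rate <- unname(t1_susceptibility(red, a0s, 2 * pi * freq_mhz * 1e6))
  list(table = tab, acfs = gm$acfs)
}
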