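#' @title Frequency trajectories, the FFCF and Kubo fits
#'
#' @description
#' The instantaneous probe frequency sampled on a uniform grid,
#' `omega(t)` in cm^-1, yields the three observables used to fingerprint a
#' molecular environment:
#'
#' 1. the **central frequency** `<omega>` (solvatochromism),
#' 2. the **frequency-fluctuation correlation function**
#'    `C(t) = <delta_omega(t) delta_omega(0)>` with
#'    `delta_omega(t) = omega(t) - <omega>`, fitted by the Kubo model
#'    `c(t) = sum_i Delta_i^2 exp(-t/tau_ci)` to give correlation times, and
#' 3. the **fluctuation amplitude** `Delta`, the Gaussian width of the
#'    frequency distribution.
#'
#' The FFCF estimator is gap-aware: snapshots whose frequency assignment
#' failed appear as explicit `NA` gaps; a (j, j+k) pair contributes to lag k
#' only when both endpoints are valid, and each lag is normalized by its own
#' pair count. `delta_omega` is always taken against the single global sample
#' mean.
#'
#' @name ffcf-analysis
NULL

#' Construct a frequency trajectory
#'
#' @param omega numeric vector of instantaneous frequencies in cm^-1; `NA`
#'   marks a gap (failed snapshot).
#' @param dt_fs sampling interval in fs (> 0).
#' @param t0_fs time of the first sample (default 0).
#' @return an object of class `"vib_freq_traj"` with fields `omega`,
#'   `times_fs`, `dt_fs`, `mean_omega` and `n_valid`.
#' @export
new_frequency_trajectory <- function(omega, dt_fs, t0_fs = 0) {
  if (dt_fs <= 0)
    vib_stop("dt_fs must be positive", "vib_invalid_trajectory")
  omega <- as.numeric(omega)
  n_valid <- sum(is.finite(omega))
  if (n_valid < 2)
    vib_stop("a frequency trajectory needs at least 2 valid samples",
             "vib_invalid_trajectory")
  omega[!is.finite(omega)] <- NA_real_
  structure(list(
    omega = omega,
    times_fs = t0_fs + dt_fs * (seq_along(omega) - 1),
    dt_fs = as.numeric(dt_fs),
    mean_omega = mean(omega, na.rm = TRUE),
    n_valid = n_valid),
    class = "vib_freq_traj")
}

#' @export
print.vib_freq_traj <- function(x, ...) {
  cat(sprintf(
    "<vib_freq_traj: %d samples (%d valid), dt = %g fs, <omega> = %.2f cm^-1>\n",
    length(x$omega), x$n_valid, x$dt_fs, x$mean_omega))
  invisible(x)
}

#' Assemble a frequency trajectory from a snapshot manifest
#'
#' The manifest (see [read_manifest()]) carries one row per snapshot with
#' `time_fs`, `omega_cm1` and `status`. Rows whose status is not `"ok"` (or
#' whose frequency is missing) become explicit gaps. Snapshot times must lie
#' on a uniform grid.
#'
#' @param manifest a data frame with columns `time_fs`, `omega_cm1`, `status`.
#' @param max_gap_fraction error threshold on the fraction of gaps
#'   (default 0.2).
#' @return a `vib_freq_traj`.
#' @export
build_frequency_trajectory <- function(manifest, max_gap_fraction = 0.2) {
  need <- c("time_fs", "omega_cm1", "status")
  if (!all(need %in% names(manifest)))
    vib_stop(sprintf("manifest must have columns: %s",
                     paste(need, collapse = ", ")), "vib_invalid_manifest")
  ord <- order(manifest$time_fs)
  manifest <- manifest[ord, ]
  dts <- diff(manifest$time_fs)
  if (length(dts) == 0)
    vib_stop("manifest must contain at least 2 snapshots",
             "vib_invalid_manifest")
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-6 * dt))
    vib_stop("snapshot times are not uniformly spaced",
             "vib_invalid_manifest")
  omega <- ifelse(manifest$status == "ok", manifest$omega_cm1, NA_real_)
  gap_frac <- mean(!is.finite(omega))
  if (gap_frac > max_gap_fraction)
    vib_stop(sprintf(
      "%.0f%% of snapshots failed assignment, above the %.0f%% threshold: trajectory unusable",
      100 * gap_frac, 100 * max_gap_fraction), "vib_too_many_gaps")
  traj <- new_frequency_trajectory(omega, dt_fs = dt,
                                   t0_fs = manifest$time_fs[1])
  attr(traj, "gap_fraction") <- gap_frac
  traj
}

#' Compute the frequency-fluctuation correlation function
#'
#' `C(k dt) = (1/N_k) * sum over valid pairs (j, j+k) of
#' delta_omega_j * delta_omega_(j+k)` with `delta_omega` taken against the
#' global sample mean and `N_k` the number of pairs whose two endpoints are
#' both valid. `C(0)` therefore equals the population variance of the valid
#' samples. If some lag has zero valid pairs the curve is truncated there.
#'
#' @param traj a `vib_freq_traj` with at least 10 valid samples.
#' @param max_lag_ps maximum lag in ps; must not exceed half the trajectory
#'   span.
#' @return an object of class `"vib_ffcf"`: a data frame with columns
#'   `lag_ps`, `C_cm2`, `n_pairs`, with the sampling interval in
#'   `attr(, "dt_ps")`.
#' @export
compute_ffcf <- function(traj, max_lag_ps) {
  if (traj$n_valid < 10)
    vib_stop("FFCF needs at least 10 valid samples", "vib_invalid_trajectory")
  dt_ps <- fs_to_ps(traj$dt_fs)
  n <- length(traj$omega)
  span_ps <- (n - 1) * dt_ps
  if (max_lag_ps > span_ps / 2 + 1e-12)
    vib_stop(sprintf(
      "max lag %g ps exceeds half the trajectory span (%g ps)",
      max_lag_ps, span_ps / 2), "vib_invalid_lag")
  kmax <- as.integer(floor(max_lag_ps / dt_ps + 1e-9))
  valid <- is.finite(traj$omega)
  dw <- traj$omega - traj$mean_omega
  dw[!valid] <- 0
  v <- as.numeric(valid)
  C <- numeric(kmax + 1L)
  np <- numeric(kmax + 1L)
  for (k in 0:kmax) {
    i <- seq_len(n - k)
    np[k + 1L] <- sum(v[i] * v[i + k])
    if (np[k + 1L] == 0) {
      # zero valid pairs: truncate the curve here
      C <- C[seq_len(k)]
      np <- np[seq_len(k)]
      break
    }
    C[k + 1L] <- sum(dw[i] * dw[i + k]) / np[k + 1L]
  }
  out <- data.frame(lag_ps = dt_ps * (seq_along(C) - 1),
                    C_cm2 = C, n_pairs = np)
  attr(out, "dt_ps") <- dt_ps
  attr(out, "span_ps") <- span_ps
  class(out) <- c("vib_ffcf", "data.frame")
  out
}

# Kubo model: sum_i a_i * exp(-t/tau_i) (+ offset); a_i = Delta_i^2 in cm^-2
kubo_model <- function(t, a, tau, offset = 0) {
  y <- rep(offset, length(t))
  for (i in seq_along(a)) y <- y + a[i] * exp(-t / tau[i])
  y
}

#' Fit the Kubo multi-exponential model to an FFCF
#'
#' Nonlinear least squares of `C(t) = sum_i Delta_i^2 exp(-t/tau_i)` (plus an
#' optional static offset `Delta_0^2`) over the requested lag range, by
#' Levenberg-Marquardt with multi-start initialization: starting `tau` values
#' are log-spaced over (0.05, 10) ps (all ordered pairs for two components)
#' and the starting amplitudes split `C(0)` evenly. Bounds: `tau` in
#' [dt/2, span], amplitudes and offset >= 0. The best converged start by
#' residual sum of squares wins.
#'
#' @param curve a `vib_ffcf`.
#' @param n_components 1 or 2 exponential components.
#' @param fit_range_ps length-2 lag range in ps, default `c(0, 10)`.
#' @param offset include a static `Delta_0^2` term (default FALSE).
#' @return an object of class `"vib_kubo_fit"`: `components` (data frame of
#'   `delta_cm1`, `tau_ps`, sorted by tau ascending), `delta0_sq`, `rmse`,
#'   `fit_range_ps` and `diagnostics` (per-start convergence, bound hits,
#'   degeneracy flag, total-amplitude consistency with C(0)).
#' @export
fit_kubo <- function(curve, n_components = 2, fit_range_ps = c(0, 10),
                     offset = FALSE) {
  if (!n_components %in% c(1, 2))
    vib_stop("n_components must be 1 or 2", "vib_invalid_fit")
  sel <- curve$lag_ps >= fit_range_ps[1] & curve$lag_ps <= fit_range_ps[2] &
    is.finite(curve$C_cm2)
  t <- curve$lag_ps[sel]
  y <- curve$C_cm2[sel]
  if (length(t) < 5)
    vib_stop("need at least 5 finite lags inside the fit range",
             "vib_invalid_fit")
  dt_ps <- attr(curve, "dt_ps")
  if (is.null(dt_ps)) dt_ps <- diff(curve$lag_ps[1:2])
  span <- attr(curve, "span_ps")
  if (is.null(span)) span <- max(curve$lag_ps) * 2
  C0 <- y[which.min(t)]
  if (C0 <= 0) C0 <- max(y, 1e-12)

  tau_lo <- dt_ps / 2
  tau_hi <- span
  tau_grid <- exp(seq(log(0.05), log(10), length.out = 4))
  tau_grid <- pmin(pmax(tau_grid, tau_lo * 1.01), tau_hi * 0.99)
  starts <- if (n_components == 1) {
    lapply(exp(seq(log(0.05), log(10), length.out = 6)), function(tt)
      list(a = C0, tau = pmin(pmax(tt, tau_lo * 1.01), tau_hi * 0.99)))
  } else {
    combs <- utils::combn(seq_along(tau_grid), 2)
    lapply(seq_len(ncol(combs)), function(j)
      list(a = rep(C0 / 2, 2), tau = tau_grid[combs[, j]]))
  }

  fit_one <- function(st) {
    par0 <- c(st$a, st$tau, if (offset) 0.05 * C0)
    lower <- c(rep(0, n_components), rep(tau_lo, n_components),
               if (offset) 0)
    upper <- c(rep(Inf, n_components), rep(tau_hi, n_components),
               if (offset) Inf)
    resid_fn <- function(p) {
      a <- p[seq_len(n_components)]
      tau <- p[n_components + seq_len(n_components)]
      off <- if (offset) p[2 * n_components + 1] else 0
      kubo_model(t, a, tau, off) - y
    }
    tryCatch({
      fit <- minpack.lm::nls.lm(
        par = par0, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-14, ptol = 1e-14))
      list(ok = fit$info %in% 1:4, par = fit$par,
           ssr = sum(fit$fvec^2), info = fit$info)
    }, error = function(e) list(ok = FALSE, par = par0, ssr = Inf,
                                info = NA_integer_))
  }

  results <- lapply(starts, fit_one)
  ssrs <- vapply(results, function(r) r$ssr, numeric(1))
  oks <- vapply(results, function(r) isTRUE(r$ok), logical(1))
  if (!any(oks))
    vib_stop(sprintf(
      "Kubo fit failed to converge from all %d starts (best residual SSR %.4g)",
      length(starts), min(ssrs)), "vib_fit_nonconvergence")
  best <- results[[which(oks)[which.min(ssrs[oks])]]]
  p <- best$par
  a <- p[seq_len(n_components)]
  tau <- p[n_components + seq_len(n_components)]
  d0 <- if (offset) p[2 * n_components + 1] else 0

  ord <- order(tau)
  a <- a[ord]; tau <- tau[ord]
  rmse <- sqrt(best$ssr / length(t))
  at_bounds <- any(tau <= tau_lo * 1.0001 | tau >= tau_hi * 0.9999)
  degenerate <- n_components == 2 &&
    (tau[2] / tau[1] < 1.5 || min(a) / max(sum(a), 1e-300) < 1e-3)
  total_amp_sq <- sum(a) + d0
  structure(list(
    components = data.frame(delta_cm1 = sqrt(pmax(a, 0)), tau_ps = tau),
    delta0_sq = d0,
    rmse = rmse,
    fit_range_ps = fit_range_ps,
    diagnostics = list(
      n_starts = length(starts), n_converged = sum(oks),
      tau_at_bounds = at_bounds, degenerate = degenerate,
      total_amplitude_sq = total_amp_sq, C0 = C0,
      amp_consistency = abs(total_amp_sq - C0) <= max(3 * rmse, 1e-8 * C0))),
    class = "vib_kubo_fit")
}

#' @export
print.vib_kubo_fit <- function(x, ...) {
  cat("<vib_kubo_fit>\n")
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  component %d: Delta = %.3f cm^-1, tau = %.4f ps\n",
                i, x$components$delta_cm1[i], x$components$tau_ps[i]))
  if (x$delta0_sq > 0)
    cat(sprintf("  static offset Delta0^2 = %.3f cm^-2\n", x$delta0_sq))
  cat(sprintf("  RMSE = %.4g cm^-2%s%s\n", x$rmse,
              if (x$diagnostics$degenerate) " [degenerate components]" else "",
              if (x$diagnostics$tau_at_bounds) " [tau at bounds]" else ""))
  invisible(x)
}

#' Reduce a Kubo fit to a single correlation time
#'
#' The multi-exponential fit yields one correlation time per component; a
#' single reported number requires a reduction convention. All three
#' conventions are always computed and returned in `$all`:
#'
#' * `slowest` (default): the largest `tau_i`;
#' * `amplitude_weighted`: `sum(Delta_i^2 tau_i) / sum(Delta_i^2)`;
#' * `integral`: `sum(Delta_i^2 tau_i) / C(0)` with
#'   `C(0) = sum(Delta_i^2) + Delta_0^2` (the normalized FFCF integral; a
#'   static offset lowers it).
#'
#' @param fit a `vib_kubo_fit`.
#' @param convention one of `"slowest"`, `"amplitude_weighted"`, `"integral"`.
#' @return a list with `tau_c_ps` (the selected value), `convention` and
#'   `all` (named vector of the three conventions).
#' @export
correlation_time <- function(fit,
                             convention = c("slowest", "amplitude_weighted",
                                            "integral")) {
  convention <- match.arg(convention)
  a <- fit$components$delta_cm1^2
  tau <- fit$components$tau_ps
  c0 <- sum(a) + fit$delta0_sq
  all <- c(slowest = max(tau),
           amplitude_weighted = sum(a * tau) / sum(a),
           integral = sum(a * tau) / c0)
  list(tau_c_ps = unname(all[convention]), convention = convention, all = all)
}

# Freedman-Diaconis bin width with fallbacks for pathological IQRs
fd_bin_width <- function(x) {
  iqr <- stats::IQR(x)
  if (iqr <= 0) iqr <- stats::sd(x)
  2 * iqr / length(x)^(1 / 3)
}

#' Fluctuation amplitude from the frequency distribution
#'
#' Fits a Gaussian profile `A exp(-(x - mu)^2 / (2 sigma^2))` to the
#' density-normalized histogram of the valid frequencies by least squares
#' (Freedman-Diaconis binning by default) and reports `Delta = sigma`. The
#' direct sample standard deviation is reported alongside; for strictly
#' Gaussian statistics the two estimates agree.
#'
#' @param traj a `vib_freq_traj` with at least 50 valid samples.
#' @param bin_width histogram bin width in cm^-1, or `NULL` for
#'   Freedman-Diaconis.
#' @return an object of class `"vib_amplitude_fit"`: `mu` and `sigma`
#'   (= `Delta`) in cm^-1, `sample_sd`, `bin_width`, `r_squared` of the
#'   Gaussian fit.
#' @export
amplitude_from_distribution <- function(traj, bin_width = NULL) {
  x <- traj$omega[is.finite(traj$omega)]
  if (length(x) < 50)
    vib_stop("histogram amplitude fit needs at least 50 valid samples",
             "vib_invalid_trajectory")
  s <- stats::sd(x)
  if (s == 0)
    vib_stop("zero-width distribution: trajectory is constant",
             "vib_degenerate_distribution")
  if (is.null(bin_width)) bin_width <- fd_bin_width(x)
  breaks <- seq(min(x) - bin_width, max(x) + bin_width, by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  xc <- h$mids
  dens <- h$density
  mu0 <- mean(x)
  start <- c(A = max(dens), mu = mu0, sigma = s)
  fit <- minpack.lm::nlsLM(
    dens ~ A * exp(-(xc - mu)^2 / (2 * sigma^2)),
    start = as.list(start),
    lower = c(A = 0, mu = min(x), sigma = bin_width / 10),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  resid <- stats::resid(fit)
  ss_tot <- sum((dens - mean(dens))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  structure(list(mu = unname(cf["mu"]), sigma = unname(abs(cf["sigma"])),
                 sample_sd = s, bin_width = bin_width, r_squared = r2),
            class = "vib_amplitude_fit")
}

#' @export
print.vib_amplitude_fit <- function(x, ...) {
  cat(sprintf(
    "<vib_amplitude_fit: Delta = %.3f cm^-1 (mu %.2f, sample sd %.3f, R^2 %.4f)>\n",
    x$sigma, x$mu, x$sample_sd, x$r_squared))
  invisible(x)
}
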