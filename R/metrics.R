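# Capnometry performance metrics: settled per-phase means, relative
# performance, cross-correlation delays, aligned RMSE, global SNR and
# 10-90% rise time.

#' Settled mean of a signal over a capnia phase
#'
#' The phase mean is taken beyond the settling instant: the first time the
#' deviation from the phase's initial level reaches `settle_fraction`
#' (default 90%) of the difference between the equilibrium level after the
#' transition and the initial level. The equilibrium level is estimated as
#' the mean of the final 10% of the phase window.
#'
#' @param times sample times, s
#' @param values signal values, mol/m^3
#' @param start phase start time, s
#' @param duration phase duration, s (> 0)
#' @param settle_fraction settling threshold (default 0.9)
#' @return the settled mean; `NA` (with a warning) if settling is never
#'   reached within the phase, as happens for phases shorter than the
#'   response time
#' @export
settled_phase_mean <- function(times, values, start, duration,
                               settle_fraction = 0.9) {
  stop_if(duration <= 0, "invalid phase: duration must be positive")
  idx <- which(times >= start & times < start + duration)
  stop_if(length(idx) < 2, "phase window outside the signal support")
  v <- values[idx]
  n <- length(v)
  v_init <- v[1]
  v_eq <- mean(v[max(1, ceiling(0.9 * n)):n])
  dv <- v_eq - v_init
  if (dv == 0) return(mean(v))
  reached <- which((v - v_init) / dv >= settle_fraction)
  # undefined if the signal only approaches equilibrium inside the final-10%
  # window that defines it (phase shorter than the response time)
  if (length(reached) == 0 || reached[1] > ceiling(0.9 * n)) {
    warning("settling never reached within the phase; mean undefined")
    return(NA_real_)
  }
  mean(v[reached[1]:n])
}

#' Relative performance of the estimated capnia level
#'
#' `perf_rel = 100 * (mu - mu_hat) / mu` in percent (signed): the relative
#' difference between the true settled phase mean `mu` and the estimated one
#' `mu_hat`.
#'
#' @param mu true settled mean, mol/m^3 (non-zero)
#' @param mu_hat estimated settled mean, mol/m^3
#' @return percent
#' @export
perf_rel <- function(mu, mu_hat) {
  stop_if(mu == 0, "undefined metric: mu must be non-zero")
  100 * (mu - mu_hat) / mu
}

# full discrete cross-correlation r(l) = sum_t ref[t] * sig[t + l] over
# l = -(n-1) .. (n-1), via FFT; both inputs mean-removed by the callers
.xcorr_full <- function(ref, sig) {
  n <- length(ref)
  m <- stats::nextn(2 * n - 1, 2)
  R <- stats::fft(c(ref, numeric(m - n)))
  S <- stats::fft(c(sig, numeric(m - n)))
  cc <- Re(stats::fft(Conj(R) * S, inverse = TRUE)) / m
  lags <- -(n - 1):(n - 1)
  # index 1 of cc is lag 0; negative lags wrap to the tail
  vals <- c(cc[(m - n + 2):m], cc[1:n])
  list(lags = lags, values = vals)
}

#' Delay between two signals by cross-correlation
#'
#' The lag (a multiple of the sampling interval) maximizing the
#' cross-correlation between the mean-removed signals. A positive delay
#' means `signal` lags `reference`. Flat signals have no defined delay.
#'
#' Applied to the capnometry pipeline: the direct delay is
#' `delay(input, observation)`, the inverse delay `delay(observation,
#' estimate)` and the global delay `delay(input, estimate)`.
#'
#' @param reference,signal equal-length, equally-sampled series
#' @param dt sampling interval, s
#' @param max_lag largest |lag| searched, in samples (default: half the
#'   series length)
#' @return delay in seconds
#' @export
delay_by_xcorr <- function(reference, signal, dt = 1,
                           max_lag = floor(length(reference) / 2)) {
  stopifnot(length(reference) == length(signal))
  ref <- reference - mean(reference)
  sig <- signal - mean(signal)
  if (all(abs(ref) < .Machine$double.eps) ||
      all(abs(sig) < .Machine$double.eps)) {
    warning("flat signal: delay undefined")
    return(NA_real_)
  }
  cc <- .xcorr_full(ref, sig)
  keep <- abs(cc$lags) <= max_lag
  lag <- cc$lags[keep][which.max(cc$values[keep])]
  lag * dt
}

#' RMSE between two signals after cross-correlation alignment
#'
#' The estimate is shifted by the delay maximizing the cross-correlation
#' with the truth, then the root mean square error is computed over the
#' overlapping support (which must cover at least half the series).
#'
#' @param truth,estimate equal-length series
#' @param dt sampling interval, s
#' @return RMSE in the units of the inputs; the alignment lag (s) is
#'   attached as attribute `"lag"`
#' @export
aligned_rmse <- function(truth, estimate, dt = 1) {
  n <- length(truth)
  d <- delay_by_xcorr(truth, estimate, dt = dt)
  k <- as.integer(round(d / dt))
  if (k >= 0) {
    est <- estimate[(1 + k):n]; tru <- truth[1:(n - k)]
  } else {
    est <- estimate[1:(n + k)]; tru <- truth[(1 - k):n]
  }
  stop_if(length(est) < n / 2, "alignment leaves less than half the support")
  out <- sqrt(mean((tru - est)^2))
  attr(out, "lag") <- d
  out
}

#' Global signal-to-noise ratio
#'
#' `rsb = 20 log10(rms(truth) / rmse)` in dB, with `rms` the quadratic norm
#' of the (raw, not mean-removed) input signal.
#'
#' @param truth input signal
#' @param rmse aligned RMSE (> 0; 0 returns +Inf)
#' @return dB
#' @export
rsb_global <- function(truth, rmse) {
  if (rmse == 0) return(Inf)
  stop_if(rmse < 0, "invalid rmse")
  20 * log10(sqrt(mean(truth^2)) / rmse)
}

#' 10-90% rise (or fall) time of a level transition
#'
#' Time between the crossings of 10% and 90% of the difference between the
#' level before and after a transition, with sub-sample linear interpolation
#' of the crossing instants. Fall transitions are handled symmetrically and
#' flagged in the `"direction"` attribute.
#'
#' @param times sample times, s
#' @param values signal
#' @param level_before,level_after plateau levels bracketing the transition
#' @return rise time in s, or `NA` (with warning) if the thresholds are not
#'   crossed
#' @export
rise_time <- function(times, values, level_before, level_after) {
  dv <- level_after - level_before
  if (!is.finite(dv) || dv == 0) {
    warning("degenerate transition: levels equal or undefined")
    return(NA_real_)
  }
  frac <- (values - level_before) / dv    # normalized progress, rises 0 -> 1
  cross <- function(thr) {
    above <- frac >= thr
    i <- which(above & !c(FALSE, above[-length(above)]))
    i <- i[i > 1]
    if (length(i) == 0 && above[1]) return(times[1])
    if (length(i) == 0) return(NA_real_)
    i <- i[1]
    # linear interpolation between samples i-1 and i
    t0 <- times[i - 1]; t1 <- times[i]
    f0 <- frac[i - 1]; f1 <- frac[i]
    t0 + (thr - f0) / (f1 - f0) * (t1 - t0)
  }
  t10 <- cross(0.10); t90 <- cross(0.90)
  if (is.na(t10) || is.na(t90)) {
    warning("transition does not cross both thresholds")
    return(NA_real_)
  }
  out <- t90 - t10
  attr(out, "direction") <- if (dv > 0) "rise" else "fall"
  out
}
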