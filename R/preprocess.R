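#' Trapezoidal taper
#'
#' Multiplies every region's series by a trapezoidal window that rises
#' linearly from 0 to 1 over the first `ceil(rise_fraction * T)` samples,
#' stays at 1, and falls symmetrically at the end. With a ramp of length `L`
#' the ramp weights are `k / (L - 1)` for `k = 0..L-1`, so the window is
#' exactly 0 at the first and last sample.
#'
#' @param ts a [parcellated_ts()].
#' @param rise_fraction fraction of the session length used for each ramp,
#'   in (0, 0.5); default 0.025 (2.5% rise and fall).
#' @return A tapered `parcellated_ts` of unchanged length.
#' @examples
#' ts <- parcellated_ts(matrix(1, 100, 1), 1)
#' head(taper_trapezoid(ts)$values)
#' @export
taper_trapezoid <- function(ts, rise_fraction = 0.025) {
  stopifnot(inherits(ts, "parcellated_ts"))
  if (rise_fraction <= 0 || rise_fraction >= 0.5) {
    stop("rise_fraction must lie in (0, 0.5)")
  }
  T <- n_samples(ts)
  L <- ceiling(rise_fraction * T)
  if (T < 2 * L) stop("series shorter than twice the ramp length")
  w <- rep(1, T)
  if (L >= 2) {
    ramp <- (0:(L - 1)) / (L - 1)
    w[1:L] <- ramp
    w[(T - L + 1):T] <- rev(ramp)
  } else {
    w[1] <- 0
    w[T] <- 0
  }
  out <- ts
  out$values <- ts$values * w
  out
}

#' Concatenate runs of one condition
#'
#' Row-wise concatenation of runs sharing region labels and sampling
#' interval, in the given order.
#'
#' @param runs list of [parcellated_ts()] objects.
#' @param session_id id for the concatenated series; defaults to the first
#'   run's id.
#' @return A single `parcellated_ts`.
#' @export
concatenate_runs <- function(runs, session_id = NULL) {
  stopifnot(length(runs) >= 1, all(vapply(runs, inherits, TRUE, "parcellated_ts")))
  first <- runs[[1]]
  for (r in runs[-1]) {
    if (!identical(r$region_labels, first$region_labels)) {
      stop("region labels differ between runs")
    }
    if (!isTRUE(all.equal(r$sampling_interval, first$sampling_interval))) {
      stop("sampling intervals differ between runs")
    }
  }
  parcellated_ts(do.call(rbind, lapply(runs, `[[`, "values")),
                 first$sampling_interval, first$region_labels,
                 session_id %||% first$session_id)
}

#' Decimate a time series
#'
#' Keeps every `factor`-th sample starting at the first one; the sampling
#' interval is multiplied by `factor`. With `antialias = TRUE` a 4th-order
#' Butterworth lowpass (zero-phase, cutoff at `1/factor` of the original
#' Nyquist frequency) is applied before sample picking; by default no filter
#' is applied and decimation is plain sample picking.
#'
#' @param ts a [parcellated_ts()].
#' @param factor integer >= 1.
#' @param antialias apply the pre-decimation lowpass? Default `FALSE`.
#' @return The decimated `parcellated_ts`.
#' @export
decimate <- function(ts, factor = 3, antialias = FALSE) {
  stopifnot(inherits(ts, "parcellated_ts"))
  stopifnot_scalar_count(factor, "factor")
  T <- n_samples(ts)
  if (factor > T) stop("decimation factor exceeds series length")
  vals <- ts$values
  if (antialias && factor > 1) {
    bf <- signal::butter(4, 1 / factor, type = "low")
    vals <- apply(vals, 2, function(x) {
      signal::filtfilt(bf, x - mean(x)) + mean(x)
    })
  }
  out <- ts
  out$values <- vals[seq(1, T, by = factor), , drop = FALSE]
  out$sampling_interval <- ts$sampling_interval * factor
  out
}

# symmetric windowed-sinc interpolation filter; phase-normalized so DC gain
# is exactly 1 at every output phase and original samples pass unchanged
interp_filter <- function(factor, half_length, cutoff) {
  nn <- seq(-half_length * factor, half_length * factor)
  fc <- cutoff / factor          # passband edge in cycles/sample, output rate
  h <- 2 * fc * factor * sinc(2 * fc * nn)
  M <- length(nn)
  w <- 0.54 + 0.46 * cos(pi * nn / (half_length * factor))  # Hamming
  h <- h * w
  # normalize each polyphase branch to unit sum (DC preservation)
  phase <- ((nn %% factor) + factor) %% factor
  for (q in unique(phase)) {
    idx <- phase == q
    h[idx] <- h[idx] / sum(h[idx])
  }
  h
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Upsample by lowpass interpolation
#'
#' Zero-stuffs each region's series by `factor` and convolves with a
#' symmetric windowed-sinc FIR interpolation filter with `half_length`
#' original-rate points of support per side. `cutoff` is the passband edge
#' in cycles per input sample, so the default 0.5 places the edge exactly at
#' the original Nyquist frequency; the filter's polyphase branches are
#' normalized so constants are preserved and, at the default cutoff,
#' original samples are reproduced at their grid positions (up to end
#' effects, handled by edge replication). Output length is exactly
#' `factor * T` and the sampling interval is divided by `factor`.
#'
#' @param ts a [parcellated_ts()].
#' @param factor integer >= 2.
#' @param half_length filter support per side, in input samples (default 4).
#' @param cutoff passband edge in cycles per input sample, in (0, 0.5]
#'   (default 0.5 = original Nyquist).
#' @return The upsampled `parcellated_ts`.
#' @export
upsample_lowpass <- function(ts, factor = 3, half_length = 4, cutoff = 0.5) {
  stopifnot(inherits(ts, "parcellated_ts"))
  stopifnot_scalar_count(factor, "factor", min = 2)
  stopifnot_scalar_count(half_length, "half_length")
  if (cutoff <= 0 || cutoff > 0.5) stop("cutoff must lie in (0, 0.5]")
  T <- n_samples(ts)
  if (T <= 2 * half_length) stop("series shorter than the filter support")
  h <- interp_filter(factor, half_length, cutoff)
  pad <- half_length
  out_vals <- apply(ts$values, 2, function(x) {
    xp <- c(rep(x[1], pad), x, rep(x[T], pad))     # edge replication
    up <- rep(0, length(xp) * factor)
    up[seq(1, length(up), by = factor)] <- xp
    y <- stats::convolve(up, rev(h), type = "open")
    off <- (length(h) - 1) / 2
    y <- y[(off + 1):(off + length(up))]
    y[(pad * factor + 1):(pad * factor + T * factor)]
  })
  out <- ts
  out$values <- out_vals
  out$sampling_interval <- ts$sampling_interval / factor
  out
}
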