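# Preprocessing of raw skin-potential series: Hampel outlier removal,
# gap interpolation, zero-phase low-pass filtering, wavelet denoising,
# per-task min-max normalization.  No stage uses the RNG.

#' Preprocessing configuration
#'
#' @param outlier_window odd rolling-window length (samples) for the
#'   Hampel filter; `>= 3`.
#' @param outlier_k flag threshold in rolling-MAD multiples; `> 0`.
#' @param lowpass_cutoff_hz low-pass cutoff; must lie below Nyquist.
#'   Defaults to 0.5 Hz, the top of the analysed band scheme.
#' @param wavelet_name wavelet used for denoising, see [wt_filters()].
#' @param denoise_level DWT depth for denoising.
#' @param threshold_rule `"soft"` or `"hard"` thresholding.
#' @param normalization normalization method; only `"minmax"` is
#'   implemented.
#' @return list of class `sp_preprocess_config`.
#' @export
preprocess_config <- function(outlier_window = 11L, outlier_k = 4,
                              lowpass_cutoff_hz = 0.5,
                              wavelet_name = "db4", denoise_level = 4L,
                              threshold_rule = "soft",
                              normalization = "minmax") {
  if (outlier_window < 3L || outlier_window %% 2L == 0L) {
    stop(sp_condition("bad_config", "outlier_window must be odd and >= 3"))
  }
  if (outlier_k <= 0) stop(sp_condition("bad_config", "outlier_k must be > 0"))
  if (normalization != "minmax") {
    stop(sp_condition("bad_config", "only minmax normalization is implemented"))
  }
  structure(list(outlier_window = as.integer(outlier_window),
                 outlier_k = outlier_k,
                 lowpass_cutoff_hz = lowpass_cutoff_hz,
                 wavelet_name = wavelet_name,
                 denoise_level = as.integer(denoise_level),
                 threshold_rule = threshold_rule,
                 normalization = normalization),
            class = "sp_preprocess_config")
}

#' Hampel outlier removal
#'
#' Marks samples deviating from the rolling median by more than
#' `k` rolling MADs as missing (`NA`).  The MAD is floored at 1e-9 mV so
#' that locally constant windows still flag genuinely deviant points.
#'
#' @param x numeric series (may contain `NA`, which are left as is and
#'   excluded from window statistics).
#' @param window odd window length `>= 3`.
#' @param k threshold in MAD multiples, `> 0`.
#' @return list with `series` (`x` with outliers set to `NA`) and
#'   `n_flagged`.
#' @export
remove_outliers <- function(x, window = 11L, k = 4) {
  if (window < 3L || window %% 2L == 0L) {
    stop(sp_condition("bad_config", "window must be odd and >= 3"))
  }
  if (k <= 0) stop(sp_condition("bad_config", "k must be > 0"))
  n <- length(x)
  if (n < window) {
    stop(sp_condition("input_too_short", sprintf(
      "series of length %d shorter than outlier window %d", n, window)))
  }
  half <- (window - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[n], half))
  flagged <- logical(n)
  for (i in seq_len(n)) {
    w <- xp[i:(i + window - 1L)]
    w <- w[is.finite(w)]
    if (length(w) == 0L || !is.finite(x[i])) next
    med <- stats::median(w)
    s <- max(stats::mad(w, center = med), 1e-9)
    flagged[i] <- abs(x[i] - med) > k * s
  }
  x[flagged] <- NA_real_
  list(series = x, n_flagged = sum(flagged))
}

#' Linear interpolation across missing samples
#'
#' Fills `NA` runs linearly between their finite neighbours; leading and
#' trailing gaps are extended with the nearest finite value.
#'
#' @param x numeric series with possible `NA` gaps.
#' @return gap-free series of the same length.
#' @export
interpolate_gaps <- function(x) {
  ok <- is.finite(x)
  if (!any(ok)) stop(sp_condition("empty_signal", "all samples missing"))
  if (all(ok)) return(x)
  stats::approx(which(ok), x[ok], xout = seq_along(x), rule = 2)$y
}

# Forward-backward (zero-phase) filtering with odd-symmetric edge
# padding and steady-state initial conditions, so constants and edges
# pass without start-up transients.
.filtfilt_pad <- function(bf, x) {
  b <- bf$b; a <- bf$a
  n <- length(x)
  np <- min(3L * (max(length(b), length(a)) - 1L), n - 1L)
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  dc <- sum(b) / sum(a)
  fwd <- function(z) {
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1], length(b) - 1L),
                              init.y = rep(dc * z[1], length(a) - 1L)))
  }
  y <- rev(fwd(rev(fwd(xp))))
  y[(np + 1):(np + n)]
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' ([signal::filtfilt()]), so the pass band has unit gain and no phase
#' distortion.
#'
#' @param x numeric series.
#' @param rate_hz sampling rate.
#' @param cutoff_hz cutoff; `0 < cutoff_hz < rate_hz / 2`.
#' @return filtered series, same length.
#' @export
lowpass <- function(x, rate_hz, cutoff_hz) {
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= rate_hz / 2) {
    stop(sp_condition("bad_config", sprintf(
      "cutoff %s Hz must lie in (0, %s) Hz", cutoff_hz, rate_hz / 2)))
  }
  bf <- signal::butter(4, cutoff_hz / (rate_hz / 2), type = "low")
  .filtfilt_pad(bf, x)
}

#' Min-max normalization to [0, 1]
#'
#' Maps `x` to `(x - min) / (max - min)`.  A constant series maps to all
#' zeros (the degenerate-range rule used throughout the feature layer).
#'
#' @param x non-empty numeric series.
#' @return series in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  if (length(x) == 0L) stop(sp_condition("empty_signal", "empty series"))
  rng <- range(x)
  if (rng[2] == rng[1]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Preprocess one recording
#'
#' Pipeline: outlier removal -> interpolation -> low-pass -> wavelet
#' denoising -> min-max normalization.  The cleaned series is kept in
#' original mV units (for the `max`/`min` features) alongside the
#' normalized series.
#'
#' @param x numeric voltage series in mV (may contain `NA` for samples
#'   missing in the raw file).
#' @param rate_hz sampling rate in Hz.
#' @param config a [preprocess_config()].
#' @return object of class `sp_preprocessed`: list with `raw_mv`
#'   (cleaned, un-normalized), `normalized` (in `[0, 1]`),
#'   `n_outliers_replaced`, `n_interpolated` and `rate_hz`.
#' @export
sp_preprocess <- function(x, rate_hz, config = preprocess_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, sptask_error = function(e) {
      e$message <- sprintf("[%s] %s", name, e$message)
      stop(e)
    })
  }
  n_missing <- sum(!is.finite(x))
  out <- stage("outliers",
               remove_outliers(x, config$outlier_window, config$outlier_k))
  y <- stage("interpolation", interpolate_gaps(out$series))
  y <- stage("lowpass", lowpass(y, rate_hz, config$lowpass_cutoff_hz))
  y <- stage("denoise",
             wavelet_denoise(y, config$wavelet_name, config$denoise_level,
                             config$threshold_rule))
  z <- stage("normalize", minmax_normalize(y))
  structure(list(raw_mv = y, normalized = z,
                 n_outliers_replaced = out$n_flagged,
                 n_interpolated = n_missing,
                 rate_hz = rate_hz),
            class = "sp_preprocessed")
}

#' @export
print.sp_preprocessed <- function(x, ...) {
  cat(sprintf(
    "Preprocessed SP signal: %d samples at %g Hz (%d outliers replaced, %d missing interpolated)\n",
    length(x$raw_mv), x$rate_hz, x$n_outliers_replaced, x$n_interpolated))
  invisible(x)
}
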