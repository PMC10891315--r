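# The 18-feature set per task: 10 time-domain measures plus 8
# wavelet-packet band energies over 0-0.5 Hz, and the 108-column
# participant feature matrix (6 tasks x 18 features).

#' The 0-0.5 Hz band scheme
#'
#' Eight contiguous 0.0625 Hz-wide frequency bands covering 0-0.5 Hz,
#' matching the terminal nodes of a depth-3 wavelet packet decomposition
#' of a 1 Hz series.
#'
#' @return data.frame with columns `band` (`freq0`..`freq7`),
#'   `lower_hz`, `upper_hz`.
#' @export
band_scheme <- function() {
  edges <- seq(0, 0.5, by = 0.0625)
  data.frame(band = paste0("freq", 0:7),
             lower_hz = edges[1:8], upper_hz = edges[2:9],
             stringsAsFactors = FALSE)
}

.feature_names <- c("max", "min", "n50", "mean", "var", "rms",
                    "diff1_mean", "diff2_mean", "diff1_std", "diff2_std",
                    paste0("freq", 0:7))

# sample SD with the n-1 convention; 0 when fewer than two values
.sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

#' Time-domain features
#'
#' `max` and `min` come from the cleaned series in original mV units;
#' all other measures from the normalized series: median (`n50`), mean,
#' sample variance, RMS, and the mean and sample SD of the first- and
#' second-order differences.
#'
#' @param raw_mv cleaned series in mV.
#' @param normalized same series min-max normalized to `[0, 1]`.
#' @return named numeric vector of 10 values.
#' @export
time_domain_features <- function(raw_mv, normalized) {
  if (length(raw_mv) != length(normalized) || length(raw_mv) < 3L) {
    stop(sp_condition("input_too_short",
                      "need matched series of length >= 3 (second difference undefined below that)"))
  }
  d1 <- diff(normalized)
  d2 <- diff(normalized, differences = 2L)
  c(max = max(raw_mv), min = min(raw_mv),
    n50 = stats::median(normalized), mean = mean(normalized),
    var = stats::var(normalized),
    rms = sqrt(mean(normalized^2)),
    diff1_mean = mean(d1), diff2_mean = mean(d2),
    diff1_std = .sd0(d1), diff2_std = .sd0(d2))
}

#' Wavelet-packet band energies
#'
#' Decimates the series from `rate_hz` to an effective 1 Hz (zero-phase
#' 8th-order Butterworth anti-alias filter at 0.5 Hz, then sample
#' picking), applies a depth-3 periodized wavelet packet decomposition
#' in natural-frequency node order, and returns the energy (sum of
#' squared coefficients) of each terminal node.  Node `k` covers
#' `[k, k+1) * 0.0625` Hz, the printed band scheme.
#'
#' Dyadic packet splitting of the raw 2.5 Hz Nyquist cannot produce
#' 0.0625 Hz bands; the decimation to a 0.5 Hz Nyquist is what makes the
#' depth-3 tree land exactly on the eight analysed bands.
#'
#' @param normalized normalized series.
#' @param rate_hz input sampling rate; must be a positive integer
#'   multiple of 1 Hz.  `rate_hz = 1` skips decimation.
#' @param wavelet wavelet name, see [wt_filters()].
#' @return named numeric vector `freq0`..`freq7`.
#' @export
band_energies <- function(normalized, rate_hz = 5, wavelet = "db4") {
  q <- round(rate_hz)
  if (abs(rate_hz - q) > 1e-9 || q < 1) {
    stop(sp_condition("bad_config", "rate_hz must be a positive integer"))
  }
  x <- normalized
  if (q > 1L) {
    bf <- signal::butter(8, 1 / q, type = "low")  # 0.5 Hz at the input rate
    x <- .filtfilt_pad(bf, x)[seq(1L, length(x), by = q)]
  }
  if (length(x) < 64L) {
    stop(sp_condition("input_too_short", sprintf(
      "only %d samples after decimation; need >= 64 (%d s of recording)",
      length(x), 64L * q)))
  }
  e <- wpd_band_energies(x, depth = 3L, wavelet = wavelet)
  names(e) <- paste0("freq", 0:7)
  e
}

#' Extract the 18-feature vector
#'
#' @param pre an [sp_preprocess()] result.
#' @param rate_hz sampling rate of the recording.
#' @param wavelet wavelet for the band energies.
#' @return named numeric vector of 18 features in stable order
#'   `max, min, n50, mean, var, rms, diff1_mean, diff2_mean, diff1_std,
#'   diff2_std, freq0..freq7`.
#' @export
extract_features <- function(pre, rate_hz = pre$rate_hz, wavelet = "db4") {
  stopifnot(inherits(pre, "sp_preprocessed"))
  td <- time_domain_features(pre$raw_mv, pre$normalized)
  be <- band_energies(pre$normalized, rate_hz, wavelet)
  c(td, be)
}

#' Assemble the participant feature matrix
#'
#' Binds per-task feature vectors into one row per participant with 108
#' columns named `task<t>.<feature>`.  Participants missing any of the
#' six tasks are dropped with a warning, never imputed.
#'
#' @param vectors named list: `vectors[[participant]][[task]]` is an
#'   18-feature vector (tasks keyed `"1"`..`"6"`).
#' @param groups named character vector: participant -> group label.
#' @return object of class `sp_features`: data.frame with
#'   `participant_id`, `group` and 108 feature columns.
#' @export
assemble_feature_matrix <- function(vectors, groups) {
  if (length(vectors) == 0L) {
    stop(sp_condition("insufficient_data", "no participants to assemble"))
  }
  tasks <- as.character(1:6)
  complete <- vapply(vectors, function(v) all(tasks %in% names(v)), logical(1))
  if (any(!complete)) {
    warning(sprintf("dropping %d participant(s) with missing tasks: %s",
                    sum(!complete),
                    paste(names(vectors)[!complete], collapse = ", ")))
    vectors <- vectors[complete]
  }
  if (length(vectors) == 0L) {
    stop(sp_condition("insufficient_data",
                      "no participant has all 6 tasks"))
  }
  rows <- lapply(vectors, function(v) {
    unlist(lapply(tasks, function(t) {
      fv <- v[[t]][.feature_names]
      names(fv) <- paste0("task", t, ".", .feature_names)
      fv
    }))
  })
  mat <- do.call(rbind, rows)
  out <- data.frame(participant_id = names(vectors),
                    group = unname(groups[names(vectors)]),
                    mat, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("sp_features", "data.frame")
  out
}

#' Feature matrix from a cohort
#'
#' Runs preprocessing and feature extraction on every recording of a
#' cohort (or a long recordings data.frame) and assembles the 108-column
#' matrix.
#'
#' @param x an `sp_cohort` or a long recordings data.frame with columns
#'   `participant_id, group, task_id, time_s, voltage_mv`.
#' @param config a [preprocess_config()].
#' @param rate_hz sampling rate; taken from the cohort spec when `x` is
#'   an `sp_cohort`.
#' @param wavelet wavelet for the band energies.
#' @return an `sp_features` data.frame.
#' @export
sp_feature_matrix <- function(x, config = preprocess_config(),
                              rate_hz = 5, wavelet = "db4") {
  if (inherits(x, "sp_cohort")) {
    rate_hz <- x$spec$sampling_rate_hz
    x <- x$recordings
  }
  groups <- tapply(x$group, x$participant_id, function(g) g[[1]])
  vectors <- lapply(split(x, x$participant_id), function(sub) {
    per_task <- lapply(split(sub$voltage_mv, sub$task_id), function(v) {
      pre <- sp_preprocess(v, rate_hz, config)
      extract_features(pre, rate_hz, wavelet)
    })
    per_task
  })
  assemble_feature_matrix(vectors, groups)
}

#' @export
print.sp_features <- function(x, ...) {
  cat(sprintf("SP feature matrix: %d participants x %d features (%s)\n",
              nrow(x), ncol(x) - 2L,
              paste(sprintf("%s n=%d", names(table(x$group)),
                            as.integer(table(x$group))), collapse = ", ")))
  invisible(x)
}

#' Feature column names of the assembled matrix
#' @return character vector of the 108 `task<t>.<feature>` names.
#' @export
feature_columns <- function() {
  as.vector(outer(.feature_names, 1:6,
                  function(f, t) paste0("task", t, ".", f))[, ])
}
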