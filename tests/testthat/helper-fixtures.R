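# Shared fixtures, all built in code at test time.

# a sinusoid sampled at `rate` Hz
make_sine <- function(freq_hz, rate_hz = 5, duration_s = 120, amp = 1,
                      phase = 0, offset = 0) {
  t <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  offset + amp * sin(2 * pi * freq_hz * t + phase)
}

# small cohort spec: quick to generate, long enough for band energies
small_spec <- function(n = c(4, 4, 4), duration = 64, seed = 7, ...) {
  cohort_spec(n_bpd = n[1], n_mdd = n[2], n_hc = n[3],
              task_durations_s = rep(duration, 6), seed = seed, ...)
}

# band profiles putting all energy in one band, for every group and task
single_band_profiles <- function(k) {
  w <- rep(0, 8); w[k] <- 1
  p <- list()
  for (g in c("BPD", "MDD", "HC")) for (t in 1:6) {
    p[[paste(g, t, sep = ".")]] <- band_profile(w)
  }
  p
}

# direct 108-column feature matrix: group-conditional Gaussian columns,
# bypassing signal generation (for classifier / statistics properties)
make_fm <- function(n_per_group = 25, shift_cols = character(),
                    shifts = 0, groups = c("BPD", "MDD", "HC"),
                    sd = 1) {
  cols <- feature_columns()
  n <- n_per_group * length(groups)
  g <- rep(groups, each = n_per_group)
  m <- matrix(rnorm(n * length(cols), sd = sd), nrow = n,
              dimnames = list(NULL, cols))
  if (length(shift_cols)) {
    for (i in seq_along(shift_cols)) {
      delta <- if (length(shifts) == 1) shifts else shifts[i]
      # shift pattern: each group offset by a multiple of delta
      m[, shift_cols[i]] <- m[, shift_cols[i]] +
        delta * (match(g, groups) - 1)
    }
  }
  out <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                    group = g, m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("sp_features", "data.frame")
  out
}

# fraction of non-DC periodogram power inside [lo, hi) Hz
band_power_fraction <- function(x, rate_hz, lo, hi) {
  x <- x - mean(x)
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  fr <- (0:(n - 1)) * rate_hz / n
  half <- 2:(floor(n / 2) + 1)
  sum(P[half][fr[half] >= lo & fr[half] < hi]) / sum(P[half])
}
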