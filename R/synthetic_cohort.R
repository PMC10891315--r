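# Synthetic cohort generator.
#
# The clinical recordings behind this analysis are not publicly
# deposited, so every downstream stage is exercised against simulated
# cohorts with known, controllable structure: group x task band-energy
# profiles over the eight 0.0625 Hz bands in 0-0.5 Hz, slow random-walk
# drift, sparse square artifacts, white sensor noise, and participant
# metadata with planted feature-marker correlations.

#' Band-energy profile
#'
#' Eight non-negative relative energy weights, one per 0.0625 Hz band of
#' the 0-0.5 Hz scheme.  Weights are band variances of the generated slow
#' component in mV^2.
#'
#' @param weights numeric vector of length 8, all `>= 0`.
#' @return validated numeric vector of class `sp_band_profile`.
#' @export
band_profile <- function(weights) {
  if (length(weights) != 8L || any(!is.finite(weights)) || any(weights < 0)) {
    stop(sp_condition("bad_band_profile",
                      "a band profile is 8 finite non-negative weights"))
  }
  structure(as.numeric(weights), class = "sp_band_profile")
}

#' Default group-by-task band profiles
#'
#' A base 1/f-like profile per task, modulated per group to emulate the
#' contrast pattern reported for task-state skin potential: patients
#' (most strongly MDD) show elevated mid/high-band energy in tasks 1-5,
#' controls show elevated lowest-band energy in the emotion-induction
#' task, and task 6 (text stimuli) carries no group difference.
#'
#' @param effect multiplier scaling the group modulations away from 1;
#'   `effect = 0` gives identical groups (a null cohort), `effect = 1`
#'   the default contrasts.
#' @return named list `"<group>.<task>"` -> [band_profile()].
#' @export
default_band_profiles <- function(effect = 1) {
  base <- c(8, 4, 2, 1.5, 1, 0.7, 0.5, 0.4) / 10
  mod <- function(mult) 1 + effect * (mult - 1)
  profiles <- list()
  for (g in c("BPD", "MDD", "HC")) {
    for (task in 1:6) {
      w <- base
      if (g == "MDD") {
        if (task == 1L) w[c(3, 5, 6)] <- w[c(3, 5, 6)] * mod(1.40)
        if (task == 2L) w[c(4, 5, 6)] <- w[c(4, 5, 6)] * mod(1.40)
        if (task == 3L) w[8] <- w[8] * mod(1.35)
        if (task == 4L) w[c(2, 4)] <- w[c(2, 4)] * mod(1.30)
      }
      if (g == "BPD") {
        if (task == 2L) w[c(4, 5)] <- w[c(4, 5)] * mod(1.15)
        if (task == 4L) w[c(2, 4)] <- w[c(2, 4)] * mod(1.20)
      }
      if (g == "HC" && task == 5L) w[1] <- w[1] * mod(1.15)
      profiles[[paste(g, task, sep = ".")]] <- band_profile(w)
    }
  }
  profiles
}

#' Synthetic cohort specification
#'
#' Full parameterization of the simulator.  Defaults mirror the study
#' conditions: group sizes 77/53/79 (BPD/MDD/HC), six tasks of 120 s at
#' 5 Hz, and one planted positive correlation between the task-2 band-3
#' energy and prealbumin in each patient group.
#'
#' @param n_bpd,n_mdd,n_hc participant counts per group.
#' @param task_durations_s six positive task durations in seconds.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param band_profiles named list `"<group>.<task>"` -> [band_profile()].
#' @param baseline_mv baseline potential, mV.
#' @param drift_sd_mv random-walk step standard deviation, mV.
#' @param spike_rate_hz expected artifact rate, spikes per second.
#' @param spike_amp_mv artifact amplitude, mV.
#' @param noise_sd_mv white sensor-noise standard deviation, mV.
#' @param marker_links list of lists with fields `feature` (e.g.
#'   `"task2.freq3"`), `marker` (metadata column) and `r` (target Pearson
#'   correlation, in `[-1, 1]`, planted within each patient group).
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the spec including this seed.
#' @return object of class `sp_cohort_spec`.
#' @export
cohort_spec <- function(n_bpd = 77L, n_mdd = 53L, n_hc = 79L,
                        task_durations_s = rep(120, 6),
                        sampling_rate_hz = 5,
                        band_profiles = default_band_profiles(),
                        baseline_mv = 1.0,
                        drift_sd_mv = 0.02,
                        spike_rate_hz = 0.02,
                        spike_amp_mv = 5,
                        noise_sd_mv = 0.05,
                        marker_links = list(
                          list(feature = "task2.freq3",
                               marker = "prealbumin", r = 0.5)),
                        seed = 1L) {
  stopifnot(n_bpd >= 0, n_mdd >= 0, n_hc >= 0,
            length(task_durations_s) == 6L, all(task_durations_s > 0),
            sampling_rate_hz > 0,
            baseline_mv >= 0 || TRUE, drift_sd_mv >= 0,
            spike_rate_hz >= 0, spike_amp_mv >= 0, noise_sd_mv >= 0)
  for (lk in marker_links) {
    if (is.null(lk$feature) || is.null(lk$marker) || abs(lk$r) > 1) {
      stop(sp_condition("bad_marker_link",
                        "marker links need feature, marker and |r| <= 1"))
    }
  }
  structure(list(
    n_bpd = as.integer(n_bpd), n_mdd = as.integer(n_mdd),
    n_hc = as.integer(n_hc),
    task_durations_s = as.numeric(task_durations_s),
    sampling_rate_hz = sampling_rate_hz,
    band_profiles = band_profiles,
    baseline_mv = baseline_mv, drift_sd_mv = drift_sd_mv,
    spike_rate_hz = spike_rate_hz, spike_amp_mv = spike_amp_mv,
    noise_sd_mv = noise_sd_mv,
    marker_links = marker_links,
    seed = as.integer(seed)
  ), class = "sp_cohort_spec")
}

# FFT-based band-limited upsampling from 1 Hz to `rate` Hz: zero-pad the
# spectrum, so no interpolation images appear above 0.5 Hz.
.fft_upsample <- function(x, factor) {
  n <- length(x)
  X <- stats::fft(x)
  m <- n * factor
  Y <- complex(m)
  half <- floor(n / 2)
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half >= 1) Y[(m - half + 1):m] <- X[(n - half + 1):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Generate one synthetic recording
#'
#' Builds a voltage series of length `round(duration * rate)` as
#' baseline + drift random walk + eight band-limited Gaussian components
#' scaled to the profile weights + white noise + Poisson-placed square
#' spikes.  Band components are synthesized as white noise band-pass
#' filtered at an effective 1 Hz rate (4th-order Butterworth, zero
#' phase) and Fourier-upsampled to the target rate, so their planted
#' spectrum lies where the band-energy extractor looks (0-0.5 Hz).
#'
#' @param spec a [cohort_spec()].
#' @param group `"BPD"`, `"MDD"` or `"HC"`.
#' @param task_id task number 1-6.
#' @param rng_stream optional integer seed for this recording's RNG
#'   stream; `NULL` continues from the current RNG state.
#' @return data.frame with columns `participant_id` (`NA`, filled by
#'   [generate_cohort()]), `group`, `task_id`, `time_s`, `voltage_mv`.
#' @export
generate_recording <- function(spec, group, task_id, rng_stream = NULL) {
  key <- paste(group, task_id, sep = ".")
  prof <- spec$band_profiles[[key]]
  if (is.null(prof)) {
    stop(sp_condition("missing_band_profile", sprintf(
      "no band profile configured for group '%s', task %s", group, task_id)))
  }
  if (!is.null(rng_stream)) set.seed(as.integer(rng_stream))
  rate <- spec$sampling_rate_hz
  dur <- spec$task_durations_s[[task_id]]
  n <- round(dur * rate)
  up <- round(rate)          # 1 Hz -> rate upsampling factor
  n1 <- ceiling(n / up)

  slow <- numeric(n)
  if (any(prof > 0)) {
    edges <- seq(0, 0.5, by = 0.0625)
    acc1 <- numeric(n1)
    comp5 <- matrix(0, nrow = n, ncol = 8)
    for (k in seq_len(8)) {
      w <- prof[k]
      if (w <= 0) next
      e <- stats::rnorm(n1)
      lo <- edges[k] / 0.5
      hi <- edges[k + 1] / 0.5
      bf <- if (k == 1L) {
        signal::butter(4, hi, type = "low")
      } else if (k == 8L) {
        signal::butter(4, lo, type = "high")
      } else {
        signal::butter(4, c(lo, hi), type = "pass")
      }
      c1 <- .filtfilt_pad(bf, e)
      c5 <- .fft_upsample(c1, up)[seq_len(n)]
      s <- stats::sd(c5)
      if (s > 0) comp5[, k] <- c5 / s * sqrt(w)
    }
    slow <- rowSums(comp5)
  }
  drift <- if (spec$drift_sd_mv > 0) cumsum(stats::rnorm(n, 0, spec$drift_sd_mv)) else numeric(n)
  white <- if (spec$noise_sd_mv > 0) stats::rnorm(n, 0, spec$noise_sd_mv) else numeric(n)
  x <- spec$baseline_mv + slow + drift + white
  n_spk <- if (spec$spike_rate_hz > 0) stats::rpois(1, spec$spike_rate_hz * dur) else 0L
  if (n_spk > 0) {
    pos <- sample.int(n, min(n_spk, n))
    sgn <- sample(c(-1, 1), length(pos), replace = TRUE)
    x[pos] <- x[pos] + sgn * spec$spike_amp_mv
  }
  data.frame(participant_id = NA_character_, group = group,
             task_id = as.integer(task_id),
             time_s = (seq_len(n) - 1) / rate, voltage_mv = x,
             stringsAsFactors = FALSE)
}

# Group-conditional metadata models (means, SDs) emulating the reported
# demographic and blood-marker distributions.  HC scale scores and blood
# markers are missing by design (controls were not sampled).
.meta_models <- list(
  age        = list(BPD = c(18.9, 3.9), MDD = c(22.7, 8.5), HC = c(25.3, 4.9)),
  hamd       = list(BPD = c(18.1, 5.8), MDD = c(16.7, 6.0)),
  hama       = list(BPD = c(18.1, 9.1), MDD = c(17.2, 9.2)),
  bdi_ii     = list(BPD = c(32.7, 14.6), MDD = c(30.2, 11.3)),
  bai        = list(BPD = c(42.9, 12.7), MDD = c(40.4, 13.8)),
  cortisol   = list(BPD = c(10.41, 3.61), MDD = c(11.10, 4.43)),
  acth       = list(BPD = c(21.47, 12.42), MDD = c(22.59, 10.72)),
  uric_acid  = list(BPD = c(335.7, 95.6), MDD = c(319.8, 89.7)),
  ibil       = list(BPD = c(5.15, 4.35), MDD = c(5.78, 4.56)),
  dbil       = list(BPD = c(3.61, 1.91), MDD = c(3.92, 2.13)),
  albumin    = list(BPD = c(44.36, 3.14), MDD = c(44.03, 3.09)),
  prealbumin = list(BPD = c(26.43, 5.89), MDD = c(24.34, 5.40))
)

.marker_names <- c("cortisol", "acth", "uric_acid", "ibil", "dbil",
                   "albumin", "prealbumin")

.edu_probs <- list(BPD = c(0.25, 0.45, 0.20, 0.10),
                   MDD = c(0.10, 0.45, 0.30, 0.15),
                   HC  = c(0.02, 0.08, 0.45, 0.45))

.female_prob <- c(BPD = 51 / 77, MDD = 36 / 53, HC = 52 / 79)

#' Generate a full synthetic cohort
#'
#' Generates `n_bpd + n_mdd + n_hc` participants with six task
#' recordings each, plus a metadata table.  Recordings use one RNG
#' stream per participant derived from `(seed, participant index)`, so
#' any participant's data can be regenerated independently.  For every
#' marker link the marker is built as a linear function of the
#' participant's realized feature value (extracted from the generated
#' recording with the default preprocessing) plus Gaussian noise
#' calibrated to the target correlation, within each patient group.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `sp_cohort`: list with `recordings` (long
#'   data.frame: participant_id, group, task_id, time_s, voltage_mv),
#'   `metadata` (one row per participant) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sp_cohort_spec"))
  groups <- rep(c("BPD", "MDD", "HC"), c(spec$n_bpd, spec$n_mdd, spec$n_hc))
  n_p <- length(groups)
  if (n_p == 0L) stop(sp_condition("empty_cohort", "all group counts are zero"))
  ids <- sprintf("P%04d", seq_len(n_p))

  rec_list <- vector("list", n_p * 6L)
  for (i in seq_len(n_p)) {
    p_seed <- (spec$seed %% 100000L) * 20011L + 7L * i
    set.seed(p_seed)
    for (task in 1:6) {
      r <- generate_recording(spec, groups[i], task, rng_stream = NULL)
      r$participant_id <- ids[i]
      rec_list[[(i - 1L) * 6L + task]] <- r
    }
  }
  recordings <- do.call(rbind, rec_list)
  rownames(recordings) <- NULL

  set.seed((spec$seed %% 100000L) * 20011L + 3L)
  md <- data.frame(participant_id = ids, group = groups,
                   stringsAsFactors = FALSE)
  draw <- function(var, g) {
    m <- .meta_models[[var]][[g]]
    if (is.null(m)) rep(NA_real_, sum(groups == g))
    else stats::rnorm(sum(groups == g), m[1], m[2])
  }
  md$age <- NA_real_; md$sex <- NA_character_; md$education <- NA_integer_
  for (g in c("BPD", "MDD", "HC")) {
    sel <- groups == g
    md$age[sel] <- round(pmax(15, draw("age", g)), 1)
    md$sex[sel] <- ifelse(stats::runif(sum(sel)) < .female_prob[[g]], "F", "M")
    md$education[sel] <- sample(1:4, sum(sel), replace = TRUE,
                                prob = .edu_probs[[g]])
  }
  for (v in c("hamd", "hama", "bdi_ii", "bai")) {
    md[[v]] <- NA_real_
    for (g in c("BPD", "MDD")) {
      sel <- groups == g
      md[[v]][sel] <- round(pmax(0, draw(v, g)), 1)
    }
  }
  for (v in .marker_names) {
    md[[v]] <- NA_real_
    for (g in c("BPD", "MDD")) {
      sel <- groups == g
      md[[v]][sel] <- pmax(0.05, draw(v, g))
    }
  }

  # plant feature-marker correlations within each patient group
  linked <- unique(vapply(spec$marker_links, function(l) l$feature, ""))
  if (length(spec$marker_links) > 0) {
    feat_vals <- .realized_features(recordings, linked, spec$sampling_rate_hz)
    for (lk in spec$marker_links) {
      fv <- feat_vals[[lk$feature]][match(md$participant_id, names(feat_vals[[lk$feature]]))]
      for (g in c("BPD", "MDD")) {
        sel <- which(groups == g)
        if (length(sel) < 2L) next
        m <- .meta_models[[lk$marker]][[g]]
        if (is.null(m)) {
          stop(sp_condition("bad_marker_link", sprintf(
            "no distribution model for marker '%s' in group %s", lk$marker, g)))
        }
        z <- as.numeric(scale(fv[sel]))
        eps <- stats::rnorm(length(sel))
        md[[lk$marker]][sel] <- m[1] + m[2] *
          (lk$r * z + sqrt(1 - lk$r^2) * eps)
      }
    }
  }
  structure(list(recordings = recordings, metadata = md, spec = spec),
            class = "sp_cohort")
}

# Extract the named features (e.g. "task2.freq3") for every participant,
# using the default preprocessing configuration.
.realized_features <- function(recordings, features, rate_hz) {
  parsed <- lapply(features, function(f) {
    m <- regmatches(f, regexec("^task([1-6])\\.(.+)$", f))[[1]]
    if (length(m) != 3L) {
      stop(sp_condition("bad_marker_link", sprintf(
        "linked feature '%s' is not of the form task<t>.<name>", f)))
    }
    list(task = as.integer(m[2]), name = m[3])
  })
  names(parsed) <- features
  cfg <- preprocess_config()
  out <- lapply(parsed, function(p) {
    sub <- recordings[recordings$task_id == p$task, ]
    vals <- vapply(split(sub$voltage_mv, sub$participant_id), function(v) {
      pre <- sp_preprocess(v, rate_hz, cfg)
      fv <- extract_features(pre, rate_hz)
      fv[[p$name]]
    }, numeric(1))
    vals
  })
  out
}

#' @export
print.sp_cohort <- function(x, ...) {
  n_rec <- nrow(unique(x$recordings[, c("participant_id", "task_id")]))
  cat(sprintf(
    "Synthetic SP cohort: %d participants (BPD %d / MDD %d / HC %d), %d recordings at %g Hz\n",
    nrow(x$metadata), x$spec$n_bpd, x$spec$n_mdd, x$spec$n_hc,
    n_rec, x$spec$sampling_rate_hz))
  invisible(x)
}
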