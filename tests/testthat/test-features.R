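# The 18-feature layer: hand-checked arithmetic, a brute-force oracle,
# band-energy localization and Parseval conservation, matrix assembly.

test_that("time-domain features match hand-computed values on [0, 0.5, 1]", {
  fv <- time_domain_features(raw_mv = c(-2, 1, 4), normalized = c(0, 0.5, 1))
  expect_equal(unname(fv["max"]), 4)
  expect_equal(unname(fv["min"]), -2)
  expect_equal(unname(fv["n50"]), 0.5)
  expect_equal(unname(fv["mean"]), 0.5)
  expect_equal(unname(fv["var"]), 0.25)
  expect_equal(unname(fv["rms"]), sqrt(5 / 12))
  expect_equal(unname(fv["diff1_mean"]), 0.5)
  expect_equal(unname(fv["diff1_std"]), 0)
  expect_equal(unname(fv["diff2_mean"]), 0)
  expect_error(time_domain_features(1:2 / 2, 1:2 / 2),
               class = "sptask_error_input_too_short")
})

test_that("time-domain features equal a brute-force reimplementation to 1e-12", {
  # independent oracle: every statistic rebuilt from first principles
  oracle <- function(raw, z) {
    n <- length(z)
    mu <- sum(z) / n
    srt <- sort(z)
    med <- if (n %% 2) srt[(n + 1) / 2] else (srt[n / 2] + srt[n / 2 + 1]) / 2
    v <- sum((z - mu)^2) / (n - 1)
    d1 <- z[2:n] - z[1:(n - 1)]
    d2 <- d1[2:(n - 1)] - d1[1:(n - 2)]
    msd <- function(d) {
      m <- sum(d) / length(d)
      c(m, sqrt(sum((d - m)^2) / (length(d) - 1)))
    }
    s1 <- msd(d1); s2 <- msd(d2)
    c(max = max(raw), min = min(raw), n50 = med, mean = mu, var = v,
      rms = sqrt(sum(z^2) / n), diff1_mean = s1[1], diff2_mean = s2[1],
      diff1_std = s1[2], diff2_std = s2[2])
  }
  set.seed(12)
  for (i in 1:100) {
    z <- runif(1000)
    raw <- z * 7 - 3
    expect_lt(max(abs(time_domain_features(raw, z) - oracle(raw, z))), 1e-12)
  }
})

test_that("a constant series puts all band energy in freq0", {
  e <- band_energies(rep(0.7, 600), 5)
  expect_gt(e["freq0"], 0)
  expect_true(all(e[2:8] < 1e-9 * sum(e)))
})

test_that("a pure mid-band sinusoid localizes to its band, for every band", {
  for (k in 0:7) {
    f <- 0.03125 + k * 0.0625
    s <- make_sine(f, duration_s = 600, amp = 0.4)
    expect_equal(unname(which.max(band_energies(s, 5))), k + 1,
                 info = sprintf("band %d", k))
  }
  # the worked case: 0.15 Hz lands in freq2 (0.125-0.1875 Hz)
  s <- make_sine(0.15, duration_s = 600, amp = 0.4)
  expect_equal(names(which.max(band_energies(s, 5))), "freq2")
})

test_that("band energies conserve the decimated series' energy (Parseval)", {
  set.seed(77)
  for (i in 1:10) {
    x <- rnorm(256)           # already at 1 Hz: no decimation
    e <- band_energies(x, 1)
    expect_lt(abs(sum(e) / sum(x^2) - 1), 0.02)
  }
})

test_that("too-short series are rejected with the minimum length", {
  err <- tryCatch(band_energies(rnorm(200), 5),
                  sptask_error_input_too_short = function(e) e)
  expect_s3_class(err, "sptask_error_input_too_short")
  expect_match(conditionMessage(err), "64")
})

test_that("extract_features is deterministic and satisfies the bounds", {
  spec <- small_spec()
  for (g in c("BPD", "MDD", "HC")) {
    r <- generate_recording(spec, g, 2, rng_stream = 40 + match(g, c("BPD", "MDD", "HC")))
    pre <- sp_preprocess(r$voltage_mv, 5)
    fv <- extract_features(pre, 5)
    expect_length(fv, 18L)
    expect_identical(extract_features(pre, 5), fv)
    expect_gte(fv[["max"]], fv[["min"]])
    expect_true(all(fv[c("n50", "mean", "rms")] >= 0 &
                      fv[c("n50", "mean", "rms")] <= 1))
    expect_true(fv[["var"]] >= 0 && fv[["var"]] <= 0.25)
    expect_true(all(fv[paste0("freq", 0:7)] >= 0))
  }
})

test_that("a planted band dominates the oscillatory band energies", {
  spec <- cohort_spec(n_bpd = 1, n_mdd = 0, n_hc = 0,
                      task_durations_s = rep(120, 6),
                      band_profiles = single_band_profiles(4),  # freq3
                      drift_sd_mv = 0, spike_rate_hz = 0,
                      noise_sd_mv = 0.02)
  r <- generate_recording(spec, "BPD", 1, rng_stream = 55)
  fv <- extract_features(sp_preprocess(r$voltage_mv, 5), 5)
  osc <- fv[paste0("freq", 1:7)]
  expect_equal(names(which.max(osc)), "freq3")
})

test_that("matrix assembly yields 108 stable columns and drops incomplete participants", {
  spec <- small_spec(n = c(1, 1, 1))
  spec$marker_links <- list()
  co <- generate_cohort(spec)
  fm <- sp_feature_matrix(co)
  expect_s3_class(fm, "sp_features")
  expect_equal(dim(fm), c(3L, 110L))
  expect_identical(names(fm)[-(1:2)], feature_columns())
  expect_identical(names(fm)[3], "task1.max")
  expect_identical(names(fm)[110], "task6.freq7")
  expect_false(anyNA(fm))

  # participant missing task 4 is dropped with a warning
  rec <- co$recordings
  drop_id <- fm$participant_id[2]
  rec <- rec[!(rec$participant_id == drop_id & rec$task_id == 4L), ]
  expect_warning(fm2 <- sp_feature_matrix(rec), "missing tasks")
  expect_equal(nrow(fm2), 2L)
  expect_false(drop_id %in% fm2$participant_id)
})
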