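# File formats, run configuration and the subcommand interface.
# All tabular formats are plain CSV (UTF-8, comma, header, '.' decimal);
# reports and the run manifest are JSON; configs are YAML or JSON.

#' Write cohort recordings and metadata
#'
#' @param cohort an `sp_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (`recordings`, `metadata`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec_path <- file.path(dir, "recordings.csv")
  meta_path <- file.path(dir, "metadata.csv")
  utils::write.csv(cohort$recordings, rec_path, row.names = FALSE)
  utils::write.csv(cohort$metadata, meta_path, row.names = FALSE)
  invisible(list(recordings = rec_path, metadata = meta_path))
}

#' Read SP recordings
#'
#' Reads the long recordings CSV (`participant_id, group, task_id,
#' time_s, voltage_mv`), validates column presence and per-recording
#' timestamp regularity (sample gaps must match `1/rate` within 1%),
#' and orders samples by time.  Missing voltage cells are kept as `NA`
#' and flagged for the interpolation stage.
#'
#' @param path recordings CSV.
#' @param rate_hz expected sampling rate.
#' @return validated long data.frame.
#' @export
read_recordings <- function(path, rate_hz = 5) {
  if (!file.exists(path)) {
    stop(sp_condition("missing_file", sprintf("no such file: %s", path)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "task_id", "time_s", "voltage_mv")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sp_condition("missing_column", sprintf(
      "recordings file lacks column(s): %s", paste(miss, collapse = ", "))))
  }
  df <- df[order(df$participant_id, df$task_id, df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  step <- 1 / rate_hz
  for (key in split(seq_len(nrow(df)),
                    paste(df$participant_id, df$task_id))) {
    gaps <- diff(df$time_s[key])
    if (length(gaps) && any(abs(gaps - step) > 0.01 * step)) {
      stop(sp_condition("irregular_sampling", sprintf(
        "irregular timestamps for participant %s task %s (expected %g s gaps)",
        df$participant_id[key[1]], df$task_id[key[1]], step)))
    }
  }
  df
}

#' Read participant metadata
#' @param path metadata CSV.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    stop(sp_condition("missing_file", sprintf("no such file: %s", path)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("participant_id", "group"), names(df))
  if (length(miss)) {
    stop(sp_condition("missing_column", sprintf(
      "metadata file lacks column(s): %s", paste(miss, collapse = ", "))))
  }
  df
}

#' Write / read the feature matrix
#'
#' The matrix CSV carries `participant_id`, `group` and the 108
#' `task<t>.<feature>` columns; a JSON sidecar records provenance
#' (preprocessing config and package version).
#'
#' @param fm an `sp_features` matrix.
#' @param path output CSV path.
#' @param config the [preprocess_config()] used, echoed in the sidecar.
#' @return invisibly, `path`.
#' @export
write_feature_matrix <- function(fm, path, config = preprocess_config()) {
  utils::write.csv(fm, path, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(
    columns = ncol(fm) - 2L,
    participants = nrow(fm),
    preprocess = unclass(config),
    package_version = as.character(utils::packageVersion("sptask"))),
    sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) {
    stop(sp_condition("missing_file", sprintf("no such file: %s", path)))
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(df) <- c("sp_features", "data.frame")
  df
}

#' Read a run configuration
#'
#' YAML (or JSON) with optional blocks `simulate`, `preprocess`, `svm`,
#' `balancing`, `correlation` and a global `seed`; absent entries fall
#' back to package defaults.
#'
#' @param path config file, or `NULL` for all defaults.
#' @return list of class `sp_run_config`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- list(
    seed = raw$seed %||% 1L,
    simulate = raw$simulate %||% list(),
    preprocess = do.call(preprocess_config, raw$preprocess %||% list()),
    svm = do.call(svm_config, raw$svm %||% list()),
    n_per_group = raw$balancing$n_per_group %||% 50L,
    correlation_method = raw$correlation$method %||% "pearson"
  )
  structure(cfg, class = "sp_run_config")
}

.cohort_spec_from_config <- function(cfg) {
  sim <- cfg$simulate
  sim$seed <- sim$seed %||% cfg$seed
  if (!is.null(sim$band_profiles)) {
    sim$band_profiles <- lapply(sim$band_profiles, band_profile)
  }
  do.call(cohort_spec, sim)
}

#' Run the full pipeline
#'
#' simulate (or read) -> preprocess + features -> group comparison ->
#' discriminant analyses -> correlation screen, writing every stage's
#' output plus a JSON manifest (config echo, seed, package version and
#' MD5 hash of each file) sufficient to regenerate the run.
#'
#' @param config an `sp_run_config` (or path to one).
#' @param out_dir output directory.
#' @param recordings_path,metadata_path optional existing inputs; when
#'   `NULL` a cohort is simulated from the config.
#' @return invisibly, the manifest list.
#' @export
sp_run_all <- function(config = read_run_config(), out_dir,
                       recordings_path = NULL, metadata_path = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(recordings_path)) {
    cohort <- generate_cohort(.cohort_spec_from_config(config))
    paths <- write_cohort(cohort, out_dir)
    recordings <- cohort$recordings
    metadata <- cohort$metadata
    rate <- cohort$spec$sampling_rate_hz
  } else {
    recordings <- read_recordings(recordings_path)
    metadata <- if (is.null(metadata_path)) NULL else read_metadata(metadata_path)
    rate <- 5
    paths <- list()
  }
  fm <- sp_feature_matrix(recordings, config$preprocess, rate_hz = rate)
  write_feature_matrix(fm, file.path(out_dir, "features.csv"),
                       config$preprocess)
  cmp <- compare_all_features(fm)
  utils::write.csv(cmp, file.path(out_dir, "group_comparison.csv"),
                   row.names = FALSE)
  disc <- tryCatch(
    run_discriminations(fm, svm = config$svm,
                        n_per_group = config$n_per_group,
                        seed = config$seed),
    sptask_error_insufficient_group = function(e) NULL)
  if (!is.null(disc)) {
    jsonlite::write_json(
      lapply(disc$analyses, function(a) list(
        confusion = unclass(a$confusion),
        metrics = as.list(a$report$metrics), n = a$n)),
      file.path(out_dir, "discriminant.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  }
  cors <- list()
  if (!is.null(metadata)) {
    for (g in intersect(c("BPD", "MDD"), unique(metadata$group))) {
      cors[[g]] <- tryCatch(
        correlate_features_markers(fm, metadata, g,
                                   method = config$correlation_method),
        sptask_error_no_marker_data = function(e) NULL)
    }
    cors <- do.call(rbind, cors[!vapply(cors, is.null, logical(1))])
    if (!is.null(cors)) {
      utils::write.csv(cors, file.path(out_dir, "correlations.csv"),
                       row.names = FALSE)
    }
  }
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    seed = config$seed,
    n_per_group = config$n_per_group,
    svm = unclass(config$svm),
    preprocess = unclass(config$preprocess),
    package_version = as.character(utils::packageVersion("sptask")),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.cli_usage <- "usage: sptask <subcommand> [--config FILE] [--seed N] [options]

subcommands:
  simulate    --out DIR                         generate a synthetic cohort
  preprocess  --recordings FILE --out FILE      write cleaned recordings
  features    --recordings FILE --out FILE      extract the feature matrix
  compare     --features FILE --out FILE        per-feature group comparison
  classify    --features FILE --out FILE        balanced-subsample SVM LOOCV
  correlate   --features FILE --metadata FILE --out FILE
  run-all     --out DIR                         full pipeline + manifest
"

.cli_args <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      opts[[substring(a, 3)]] <- argv[i + 1L]
      i <- i + 2L
    } else i <- i + 1L
  }
  opts
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher over the package functions; see
#' `inst/scripts/sptask-cli.R` for the executable wrapper.  Every
#' subcommand accepts `--config` and `--seed`; failures print an
#' actionable message and return a non-zero exit code.
#'
#' @param argv character vector of arguments (subcommand first).
#' @return integer exit code (0 on success).
#' @export
sp_cli <- function(argv) {
  if (length(argv) == 0L) { message(.cli_usage); return(2L) }
  sub <- argv[1L]
  opts <- .cli_args(argv[-1L])
  cfg <- read_run_config(opts$config)
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  run <- function(expr) {
    tryCatch({ expr; 0L },
             error = function(e) { message("error: ", conditionMessage(e)); 1L })
  }
  need <- function(what) {
    if (is.null(opts[[what]])) {
      stop(sprintf("missing required option --%s", what), call. = FALSE)
    }
    opts[[what]]
  }
  switch(sub,
    simulate = run({
      cohort <- generate_cohort(.cohort_spec_from_config(cfg))
      write_cohort(cohort, need("out"))
    }),
    preprocess = run({
      rec <- read_recordings(need("recordings"))
      cleaned <- do.call(rbind, lapply(
        split(rec, paste(rec$participant_id, rec$task_id)), function(sub) {
          pre <- sp_preprocess(sub$voltage_mv, 5, cfg$preprocess)
          sub$voltage_mv <- pre$raw_mv
          sub
        }))
      utils::write.csv(cleaned[order(cleaned$participant_id, cleaned$task_id,
                                     cleaned$time_s), ],
                       need("out"), row.names = FALSE)
    }),
    features = run({
      rec <- read_recordings(need("recordings"))
      fm <- sp_feature_matrix(rec, cfg$preprocess)
      write_feature_matrix(fm, need("out"), cfg$preprocess)
    }),
    compare = run({
      fm <- read_feature_matrix(need("features"))
      utils::write.csv(compare_all_features(fm), need("out"),
                       row.names = FALSE)
    }),
    classify = run({
      fm <- read_feature_matrix(need("features"))
      disc <- run_discriminations(fm, svm = cfg$svm,
                                  n_per_group = cfg$n_per_group,
                                  seed = cfg$seed)
      jsonlite::write_json(
        lapply(disc$analyses, function(a) list(
          confusion = unclass(a$confusion),
          metrics = as.list(a$report$metrics), n = a$n)),
        need("out"), auto_unbox = TRUE, pretty = TRUE, digits = NA,
        na = "null")
    }),
    correlate = run({
      fm <- read_feature_matrix(need("features"))
      md <- read_metadata(need("metadata"))
      res <- do.call(rbind, lapply(
        intersect(c("BPD", "MDD"), unique(md$group)),
        function(g) correlate_features_markers(
          fm, md, g, method = cfg$correlation_method)))
      utils::write.csv(res, need("out"), row.names = FALSE)
    }),
    `run-all` = run(sp_run_all(cfg, need("out"))),
    { message("unknown subcommand: ", sub, "\n", .cli_usage); 2L }
  )
}
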