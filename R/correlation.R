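# Correlation screen: SP features against blood oxidative-stress
# markers (and scale scores) within a patient group.

#' Correlation with degenerate-input guards
#'
#' Pearson (default) or Spearman correlation with a two-tailed p-value,
#' after pairwise deletion of incomplete pairs.
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p`, `n`.
#' @export
sp_cor <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    stop(sp_condition("insufficient_data",
                      "need >= 3 complete pairs"))
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop(sp_condition("degenerate_input",
                      "zero variance in one of the inputs"))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Correlate features against blood markers within a group
#'
#' Screens every feature column of the matrix against every blood
#' marker for one patient group, with pairwise deletion of missing
#' marker values.  Pairs are flagged significant at two-tailed p < 0.05,
#' uncorrected by default (per-pair reporting); `p_adjust = "BH"` flags
#' on Benjamini-Hochberg adjusted p-values instead.  Healthy controls
#' carry no marker data by design, so requesting them is an error.
#'
#' @param fm an `sp_features` matrix.
#' @param metadata participant metadata with `participant_id`, `group`
#'   and marker columns.
#' @param group `"BPD"` or `"MDD"`.
#' @param markers marker column names to screen (defaults to the seven
#'   blood markers).
#' @param method `"pearson"` or `"spearman"`.
#' @param p_adjust `"none"` or `"BH"`.
#' @return data.frame of class `sp_correlation`: `group`, `feature`,
#'   `marker`, `r`, `p`, `n`, `significant`.
#' @export
correlate_features_markers <- function(fm, metadata, group,
                                       markers = c("cortisol", "acth",
                                                   "uric_acid", "ibil",
                                                   "dbil", "albumin",
                                                   "prealbumin"),
                                       method = c("pearson", "spearman"),
                                       p_adjust = c("none", "BH")) {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  md <- metadata[metadata$group == group, , drop = FALSE]
  markers <- intersect(markers, names(md))
  has_data <- vapply(markers, function(m) any(is.finite(md[[m]])), logical(1))
  if (nrow(md) == 0L || !any(has_data)) {
    stop(sp_condition("no_marker_data", sprintf(
      "group '%s' has no marker data (controls are not sampled)", group)))
  }
  markers <- markers[has_data]
  sub <- fm[fm$group == group, , drop = FALSE]
  md <- md[match(sub$participant_id, md$participant_id), , drop = FALSE]
  feat_cols <- setdiff(names(sub), c("participant_id", "group"))
  rows <- list()
  for (fc in feat_cols) {
    for (mk in markers) {
      res <- tryCatch(sp_cor(sub[[fc]], md[[mk]], method),
                      sptask_error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = group, feature = fc, marker = mk,
        r = res$r, p = res$p, n = res$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  p_use <- if (p_adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  if (p_adjust == "BH") out$p_adjusted <- p_use
  out$significant <- p_use < 0.05
  class(out) <- c("sp_correlation", "data.frame")
  out
}

#' @export
print.sp_correlation <- function(x, ...) {
  cat(sprintf(
    "Feature-marker correlation screen (%s): %d pairs, %d significant\n",
    x$group[1], nrow(x), sum(x$significant)))
  sig <- x[x$significant, c("feature", "marker", "r", "p", "n")]
  if (nrow(sig)) {
    sig$r <- round(sig$r, 3); sig$p <- signif(sig$p, 3)
    print.data.frame(utils::head(sig[order(sig$p), ], 15), row.names = FALSE)
  }
  invisible(x)
}
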