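# Per-feature group comparison: one-way ANOVA (raw-data and
# summary-statistics paths), Levene-gated Bonferroni / Tamhane T2 post
# hoc pairwise comparisons, and the demographic tests.

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance: F is the ratio
#' of between- to within-group mean squares, with `(k - 1, N - k)`
#' degrees of freedom.  When the between-group sum of squares is zero
#' (identical group means) F is 0 and p is 1, even if the within-group
#' variance is also degenerate.
#'
#' @param samples list of numeric vectors, one per group; at least two
#'   groups with `n >= 2` each.
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
anova_oneway <- function(samples) {
  if (length(samples) < 2L || any(vapply(samples, length, 1L) < 2L)) {
    stop(sp_condition("insufficient_data",
                      "need >= 2 groups with >= 2 observations each"))
  }
  n <- vapply(samples, length, 1L)
  m <- vapply(samples, mean, 1)
  v <- vapply(samples, stats::var, 1)
  anova_from_summary(n, m, sqrt(v))
}

#' One-way ANOVA from summary statistics
#'
#' Recovers the F test from per-group `n`, mean and SD alone:
#' `SSb = sum n_i (m_i - grand)^2`, `SSw = sum (n_i - 1) s_i^2`,
#' `F = (SSb / (k-1)) / (SSw / (N-k))`.  This is exactly the statistic
#' the raw-data path computes, so published group summaries can be
#' checked without the underlying data.
#'
#' @param n,mean,sd equal-length vectors of per-group counts, means and
#'   standard deviations.
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
anova_from_summary <- function(n, mean, sd) {
  if (length(n) < 2L || length(mean) != length(n) || length(sd) != length(n)) {
    stop(sp_condition("incomplete_summary",
                      "need matched n, mean, sd for >= 2 groups"))
  }
  if (any(!is.finite(sd))) {
    stop(sp_condition("incomplete_summary", "missing group SD"))
  }
  if (any(n < 2L)) {
    stop(sp_condition("insufficient_data", "each group needs n >= 2"))
  }
  k <- length(n)
  N <- sum(n)
  grand <- sum(n * mean) / N
  ssb <- sum(n * (mean - grand)^2)
  ssw <- sum((n - 1) * sd^2)
  df1 <- k - 1L
  df2 <- N - k
  if (ssb <= 0) return(list(F = 0, p = 1, df1 = df1, df2 = df2))
  if (ssw <= 0) return(list(F = Inf, p = 0, df1 = df1, df2 = df2))
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

# pooled-variance two-sample t p-value
.pooled_t_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) return(if (mean(x) == mean(y)) 1 else 0)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(t), n1 + n2 - 2)
}

# Welch two-sample t p-value (Welch-Satterthwaite df)
.welch_t_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x) / n1; v2 <- stats::var(y) / n2
  if (v1 + v2 <= 0) return(if (mean(x) == mean(y)) 1 else 0)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  2 * stats::pt(-abs(t), df)
}

#' Post hoc pairwise comparisons
#'
#' `bonferroni`: pooled-variance pairwise t tests with p multiplied by
#' the number of pairs (capped at 1).  `tamhane_t2`: Welch t tests with
#' the conservative Sidak-style correction `1 - (1 - p)^m`, which does
#' not assume equal group variances.
#'
#' @param samples named list of numeric vectors, one per group.
#' @param method `"bonferroni"` or `"tamhane_t2"`.
#' @return data.frame with columns `group1`, `group2`, `p_raw`,
#'   `p_corrected`.
#' @export
posthoc_pairwise <- function(samples, method = c("bonferroni", "tamhane_t2")) {
  method <- match.arg(method)
  if (length(samples) < 2L) {
    stop(sp_condition("insufficient_data", "need >= 2 groups"))
  }
  gn <- names(samples) %||% as.character(seq_along(samples))
  pairs <- utils::combn(seq_along(samples), 2L)
  m <- ncol(pairs)
  res <- apply(pairs, 2L, function(ij) {
    x <- samples[[ij[1]]]; y <- samples[[ij[2]]]
    p <- if (method == "bonferroni") .pooled_t_p(x, y) else .welch_t_p(x, y)
    c(p_raw = p,
      p_corrected = if (method == "bonferroni") min(1, p * m)
                    else min(1, 1 - (1 - p)^m))
  })
  data.frame(group1 = gn[pairs[1, ]], group2 = gn[pairs[2, ]],
             p_raw = res["p_raw", ], p_corrected = res["p_corrected", ],
             stringsAsFactors = FALSE)
}

#' Choose the post hoc method
#'
#' Brown-Forsythe Levene test (one-way ANOVA on absolute deviations from
#' group medians) at alpha = 0.05: homogeneous variances select
#' Bonferroni, heterogeneous select Tamhane's T2.  Degenerate inputs
#' (constant deviations) fall back to Bonferroni.
#'
#' @param samples list of numeric vectors, one per group.
#' @param alpha significance level of the variance-homogeneity gate.
#' @return `"bonferroni"` or `"tamhane_t2"`.
#' @export
choose_posthoc <- function(samples, alpha = 0.05) {
  dev <- lapply(samples, function(x) abs(x - stats::median(x)))
  p <- tryCatch(anova_oneway(dev)$p, sptask_error = function(e) 1)
  if (!is.finite(p) || p >= alpha) "bonferroni" else "tamhane_t2"
}

#' Demographic and clinical metadata tests
#'
#' Applies the comparison layer used for participant characteristics:
#' one-way ANOVA for quantitative variables present in all three groups
#' (age), Welch two-sample t tests for patient-only quantitative scores
#' (HAMD, HAMA, BDI-II, BAI), a chi-square test for sex (Yates
#' continuity correction on 2x2 tables, R's default), and a rank-sum
#' test for ordinal education (Kruskal-Wallis across three groups,
#' Wilcoxon for two).
#'
#' @param metadata data.frame with columns `group`, `age`, `sex`,
#'   `education` and optionally the scale scores.
#' @return data.frame with `variable`, `test`, `statistic`, `p`,
#'   `significant` (p < 0.05).
#' @export
demographic_tests <- function(metadata) {
  rows <- list()
  add <- function(variable, test, statistic, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, test = test, statistic = statistic, p = p,
      significant = is.finite(p) && p < 0.05, stringsAsFactors = FALSE)
  }
  grp <- metadata$group
  if ("age" %in% names(metadata)) {
    a <- anova_oneway(split(metadata$age, grp))
    add("age", "anova", a$F, a$p)
  }
  if ("sex" %in% names(metadata)) {
    tab <- table(grp, metadata$sex)
    if (any(tab == 0L)) {
      stop(sp_condition("sparse_table", "empty cell in sex contingency table"))
    }
    ct <- stats::chisq.test(tab)
    add("sex", "chi_square", unname(ct$statistic), ct$p.value)
  }
  if ("education" %in% names(metadata)) {
    k <- length(unique(grp))
    if (k > 2L) {
      kt <- stats::kruskal.test(metadata$education, factor(grp))
      add("education", "kruskal_wallis", unname(kt$statistic), kt$p.value)
    } else {
      sp <- split(metadata$education, grp)
      wt <- stats::wilcox.test(sp[[1]], sp[[2]], exact = FALSE)
      add("education", "rank_sum", unname(wt$statistic), wt$p.value)
    }
  }
  for (v in c("hamd", "hama", "bdi_ii", "bai")) {
    if (!v %in% names(metadata)) next
    sp <- split(metadata[[v]], grp)
    sp <- lapply(sp, function(x) x[is.finite(x)])
    sp <- sp[vapply(sp, length, 1L) >= 2L]
    if (length(sp) < 2L) next
    tt <- stats::t.test(sp[[1]], sp[[2]])
    add(v, "t_test", unname(tt$statistic), tt$p.value)
  }
  do.call(rbind, rows)
}

#' Compare all features across groups
#'
#' One row per feature column: per-group mean and SD, omnibus one-way
#' ANOVA F and p, and corrected pairwise p-values for BPD-vs-HC,
#' MDD-vs-HC and BPD-vs-MDD.  The post hoc method is chosen per feature
#' by [choose_posthoc()] unless fixed.  Features are flagged significant
#' when the omnibus p < 0.05 (two-tailed); no correction is applied
#' across features by default, mirroring per-feature reporting, but
#' `p_adjust = "BH"` adds a Benjamini-Hochberg adjusted omnibus p and
#' bases the flag on it.
#'
#' @param fm an `sp_features` matrix (or data.frame with `group` plus
#'   feature columns).
#' @param posthoc `"auto"`, `"bonferroni"` or `"tamhane_t2"`.
#' @param p_adjust `"none"` or `"BH"`.
#' @return data.frame of class `sp_group_comparison`.
#' @export
compare_all_features <- function(fm, posthoc = "auto", p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  groups <- unique(fm$group)
  if (length(groups) < 2L) {
    stop(sp_condition("insufficient_data",
                      "need >= 2 groups to compare features"))
  }
  feat_cols <- setdiff(names(fm), c("participant_id", "group"))
  pair_name <- function(g1, g2) paste0("p_", tolower(g1), "_", tolower(g2))
  # canonical group order so pairwise columns come out as p_bpd_hc,
  # p_mdd_hc, p_bpd_mdd for the standard three-group design
  g_order <- c(intersect(c("BPD", "MDD", "HC"), groups),
               setdiff(sort(groups), c("BPD", "MDD", "HC")))
  rows <- lapply(feat_cols, function(fc) {
    sp <- split(fm[[fc]], factor(fm$group, levels = g_order))
    a <- anova_oneway(sp)
    method <- if (posthoc == "auto") choose_posthoc(sp) else posthoc
    ph <- posthoc_pairwise(sp, method)
    row <- data.frame(feature = fc, stringsAsFactors = FALSE)
    for (g in names(sp)) {
      row[[paste0(tolower(g), "_mean")]] <- mean(sp[[g]])
      row[[paste0(tolower(g), "_sd")]] <- stats::sd(sp[[g]])
    }
    row$F <- a$F; row$p <- a$p; row$posthoc_method <- method
    for (i in seq_len(nrow(ph))) {
      row[[pair_name(ph$group1[i], ph$group2[i])]] <- ph$p_corrected[i]
    }
    row
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$p_adjusted < 0.05
  } else {
    out$significant <- out$p < 0.05
  }
  class(out) <- c("sp_group_comparison", "data.frame")
  out
}

#' @export
print.sp_group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of %d features: %d significant (omnibus p < 0.05)\n",
              nrow(x), sum(x$significant)))
  sig <- x[x$significant, c("feature", "F", "p")]
  if (nrow(sig)) {
    sig$F <- round(sig$F, 3); sig$p <- signif(sig$p, 3)
    print.data.frame(utils::head(sig[order(sig$p), ], 20), row.names = FALSE)
  }
  invisible(x)
}
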