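# Published reference results of the source clinical study, used as
# fixed inputs when re-deriving its metric suite: the four SVM
# confusion matrices and one summary-statistics row of the
# feature-comparison table.

#' Published SVM confusion matrices
#'
#' The four confusion matrices reported for the RBF-SVM discriminant
#' analyses (balanced subsamples of 50 per group under LOOCV): MDD vs
#' HC, BPD vs HC, BPD vs MDD, and the three-class problem.  Rows are
#' true classes, columns predicted.
#'
#' @return named list of [confusion()] matrices: `mdd_hc`, `bpd_hc`,
#'   `bpd_mdd`, `three_class`.
#' @export
reference_confusions <- function() {
  m <- function(counts, classes) {
    structure(matrix(as.integer(counts), nrow = length(classes), byrow = TRUE,
                     dimnames = list(true = classes, predicted = classes)),
              class = c("sp_confusion", "matrix", "array"))
  }
  list(
    mdd_hc = m(c(37, 13,
                 9, 41), c("MDD", "HC")),
    bpd_hc = m(c(31, 19,
                 16, 34), c("BPD", "HC")),
    bpd_mdd = m(c(38, 12,
                  19, 31), c("BPD", "MDD")),
    three_class = m(c(24, 9, 17,
                      12, 31, 7,
                      13, 4, 33), c("BPD", "MDD", "HC"))
  )
}

#' Published group summary for the task-5 lowest-band energy
#'
#' Per-group n, mean and SD of the `task5.freq0` feature (the 0-0.0625
#' Hz band energy during the emotion-induction task) as reported for
#' the clinical cohort; the omnibus F can be recomputed from these
#' alone with [anova_from_summary()].
#'
#' @return list with `n`, `mean`, `sd` (named BPD/MDD/HC) and the
#'   published `F_reported`.
#' @export
reference_summary_task5_freq0 <- function() {
  list(n = c(BPD = 77, MDD = 53, HC = 79),
       mean = c(BPD = 2.513, MDD = 2.450, HC = 2.773),
       sd = c(BPD = 0.616, MDD = 0.560, HC = 0.618),
       F_reported = 5.660)
}
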