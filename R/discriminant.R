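# Balanced-subsample discrimination of BPD / MDD / HC from the
# 108-column feature matrix: RBF-SVM under leave-one-out
# cross-validation, confusion matrices, and the binary / macro-averaged
# multiclass metric suite.

#' SVM configuration
#'
#' The discriminant model is an RBF-kernel support vector machine with
#' fixed hyperparameters: penalty C = 1.3 and kernel width
#' gamma = 0.0085.  No hyperparameter search is performed.
#'
#' @param cost penalty coefficient C, `> 0`.
#' @param gamma RBF kernel width, `> 0`.
#' @return list of class `sp_svm_config`.
#' @export
svm_config <- function(cost = 1.3, gamma = 0.0085) {
  stopifnot(cost > 0, gamma > 0)
  structure(list(cost = cost, gamma = gamma, kernel = "radial"),
            class = "sp_svm_config")
}

#' Classifier registry
#'
#' Pluggable classifiers usable in [loocv_predict()].  `"svm"` (the
#' default model, and the only one whose performance is characterized
#' here), `"knn"`, `"lda"`, `"logistic"` and `"gbdt"` are registered.
#' Each spec provides `fit(x, y)` and `predict(model, x)`; predictions
#' carry a decision score for the first factor level so binary ROC
#' curves can be computed.
#'
#' @param name registered classifier name.
#' @param svm a [svm_config()] used when `name = "svm"`.
#' @return list with `name`, `fit`, `predict`.
#' @export
classifier_registry <- function(name = "svm", svm = svm_config()) {
  registry <- c("svm", "knn", "lda", "logistic", "gbdt")
  if (!name %in% registry) {
    stop(sp_condition("unknown_classifier", sprintf(
      "unknown classifier '%s'; registered: %s",
      name, paste(registry, collapse = ", "))))
  }
  pos_score <- function(prob_matrix, lev) prob_matrix[, lev[1L], drop = TRUE]
  spec <- switch(name,
    svm = list(
      fit = function(x, y) e1071::svm(x, y, type = "C-classification",
                                      kernel = svm$kernel, cost = svm$cost,
                                      gamma = svm$gamma, scale = FALSE),
      predict = function(model, x, lev) {
        p <- stats::predict(model, x, decision.values = TRUE)
        score <- rep(NA_real_, nrow(x))
        if (length(lev) == 2L) {
          dv <- attr(p, "decision.values")
          # e1071 labels the column "<a>/<b>"; positive values vote <a>
          score <- if (startsWith(colnames(dv)[1L], paste0(lev[1L], "/")))
            dv[, 1L] else -dv[, 1L]
        }
        list(label = as.character(p), score = score)
      }),
    knn = list(
      fit = function(x, y) list(x = x, y = y),
      predict = function(model, x, lev) {
        p <- class::knn(model$x, x, model$y, k = 5L, prob = TRUE)
        win <- attr(p, "prob")
        score <- ifelse(as.character(p) == lev[1L], win, 1 - win)
        list(label = as.character(p), score = score)
      }),
    lda = list(
      fit = function(x, y) MASS::lda(x, grouping = y),
      predict = function(model, x, lev) {
        p <- stats::predict(model, x)
        list(label = as.character(p$class),
             score = p$posterior[, lev[1L], drop = TRUE])
      }),
    logistic = list(
      fit = function(x, y) {
        if (nlevels(y) == 2L) {
          df <- data.frame(x, check.names = FALSE)
          df$.y <- y
          suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
        } else {
          df <- data.frame(x, check.names = FALSE)
          df$.y <- y
          nnet::multinom(.y ~ ., data = df, trace = FALSE, MaxNWts = 5000)
        }
      },
      predict = function(model, x, lev) {
        df <- data.frame(x, check.names = FALSE)
        if (inherits(model, "glm")) {
          pr2 <- stats::predict(model, df, type = "response")  # P(level 2)
          lab <- ifelse(pr2 > 0.5, lev[2L], lev[1L])
          list(label = lab, score = 1 - pr2)
        } else {
          pr <- stats::predict(model, df, type = "probs")
          if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1, dimnames = list(NULL, model$lev))
          lab <- colnames(pr)[max.col(pr)]
          list(label = lab, score = pos_score(pr, lev))
        }
      }),
    gbdt = list(
      fit = function(x, y) {
        k <- nlevels(y)
        params <- if (k == 2L) {
          list(objective = "binary:logistic", max_depth = 3, eta = 0.3)
        } else {
          list(objective = "multi:softprob", num_class = k,
               max_depth = 3, eta = 0.3)
        }
        booster <- xgboost::xgb.train(
          params = params,
          data = xgboost::xgb.DMatrix(as.matrix(x),
                                      label = as.integer(y) - 1L),
          nrounds = 30, verbose = 0)
        list(booster = booster, k = k)
      },
      predict = function(model, x, lev) {
        pr <- stats::predict(model$booster,
                             xgboost::xgb.DMatrix(as.matrix(x)))
        if (model$k == 2L) {
          lab <- ifelse(pr > 0.5, lev[2L], lev[1L])  # pr = P(class 2)
          list(label = lab, score = 1 - pr)
        } else {
          pm <- matrix(pr, ncol = model$k, byrow = TRUE,
                       dimnames = list(NULL, lev))
          list(label = lev[max.col(pm)], score = pm[, 1L])
        }
      })
  )
  c(list(name = name), spec)
}

#' Balanced subsampling
#'
#' Draws exactly `n_per_group` participants per group without
#' replacement, to remove class imbalance before fitting the
#' discriminant model.  Seed-reproducible.
#'
#' @param fm an `sp_features` matrix (any data.frame with a `group`
#'   column).
#' @param n_per_group rows to keep per group (default 50).
#' @param seed RNG seed for the draw.
#' @return subset of `fm` with `n_per_group` rows per group.
#' @export
subsample_balanced <- function(fm, n_per_group = 50L, seed = 1L) {
  counts <- table(fm$group)
  if (any(counts < n_per_group)) {
    small <- names(counts)[counts < n_per_group]
    stop(sp_condition("insufficient_group", sprintf(
      "group(s) %s have fewer than %d members",
      paste(small, collapse = ", "), n_per_group)))
  }
  set.seed(as.integer(seed))
  keep <- unlist(lapply(sort(unique(fm$group)), function(g) {
    idx <- which(fm$group == g)
    if (length(idx) == n_per_group) idx else sort(sample(idx, n_per_group))
  }))
  fm[sort(keep), , drop = FALSE]
}

#' Leave-one-out cross-validated prediction
#'
#' For each row i the feature standardization (per-column mean/SD) and
#' the classifier are fit on all rows except i, then row i is predicted;
#' nothing from the held-out row enters the training fold.
#'
#' @param x numeric feature matrix or data.frame (rows = participants).
#' @param labels class labels, coerced to factor.
#' @param model classifier name or a [classifier_registry()] spec.
#' @param standardize z-score features on each training fold (default
#'   `TRUE`; the RBF kernel width is scale-sensitive).
#' @param return_fold_stats also return the per-fold training means
#'   (diagnostic for leakage checks).
#' @return list with `predicted` (character), `score` (positive-class
#'   decision score, `NA` for multiclass models without one), `levels`,
#'   and optionally `fold_means`.
#' @export
loocv_predict <- function(x, labels, model = "svm", standardize = TRUE,
                          return_fold_stats = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(labels)
  n <- nrow(x)
  if (nlevels(y) < 2L || n < 3L) {
    stop(sp_condition("insufficient_data",
                      "need >= 2 classes and >= 3 rows"))
  }
  if (is.character(model)) model <- classifier_registry(model)
  lev <- levels(y)
  pred <- character(n)
  score <- rep(NA_real_, n)
  fold_means <- if (return_fold_stats) matrix(NA_real_, n, ncol(x)) else NULL
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < 2L) {
      # only reachable with tiny inputs: the fold offers a single class,
      # so that class is the only possible prediction
      warning(structure(
        class = c("sptask_warning_degenerate_fold", "warning", "condition"),
        list(message = sprintf(
          "training fold %d contains a single class; predicting it", i),
          call = NULL)))
      pred[i] <- levels(ytr)[1L]
      next
    }
    xte <- x[i, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(xtr)
      sg <- apply(xtr, 2L, stats::sd)
      sg[sg < 1e-12] <- 1
      xtr <- sweep(sweep(xtr, 2L, mu), 2L, sg, "/")
      xte <- sweep(sweep(xte, 2L, mu), 2L, sg, "/")
      if (return_fold_stats) fold_means[i, ] <- mu
    }
    fit <- model$fit(xtr, ytr)
    p <- model$predict(fit, xte, lev)
    pred[i] <- p$label[1L]
    score[i] <- p$score[1L]
  }
  out <- list(predicted = pred, score = score, levels = lev)
  if (return_fold_stats) out$fold_means <- fold_means
  out
}

#' Confusion matrix
#'
#' @param true,predicted equal-length label vectors.
#' @param classes class order (rows = true, columns = predicted);
#'   defaults to the sorted union of the true labels.
#' @return K x K integer matrix of class `sp_confusion`.
#' @export
confusion <- function(true, predicted, classes = sort(unique(true))) {
  if (length(true) == 0L || length(true) != length(predicted)) {
    stop(sp_condition("insufficient_data",
                      "need equal-length, non-empty label vectors"))
  }
  bad <- setdiff(unique(c(true, predicted)), classes)
  if (length(bad)) {
    stop(sp_condition("unknown_label", sprintf(
      "label(s) outside the class order: %s", paste(bad, collapse = ", "))))
  }
  cm <- table(factor(true, levels = classes),
              factor(predicted, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  structure(m, class = c("sp_confusion", class(m)))
}

#' @export
print.sp_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = true, columns = predicted):\n")
  print(unclass(x))
  invisible(x)
}

.safe_div <- function(num, den, flags, what) {
  if (den == 0) {
    flags$zero <- c(flags$zero, what)
    return(list(v = 0, flags = flags))
  }
  list(v = num / den, flags = flags)
}

#' Binary classification report
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy,
#' precision `TP/(TP+FP)` and F1 (harmonic mean of precision and
#' sensitivity) from a 2x2 confusion matrix.  Metrics with a zero
#' denominator are reported as 0 and flagged (with a warning).
#'
#' @param cm 2x2 [confusion()] matrix.
#' @param positive the positive class; defaults to the first row.
#' @param auc optional AUC to attach (from [roc_auc()]).
#' @return list of class `sp_report` with `metrics` (named numeric),
#'   `positive`, `confusion`, `zero_denominator`.
#' @export
report_binary <- function(cm, positive = rownames(cm)[1L], auc = NA_real_) {
  if (!all(dim(cm) == c(2L, 2L))) {
    stop(sp_condition("bad_confusion", "report_binary needs a 2x2 matrix"))
  }
  stopifnot(positive %in% rownames(cm))
  neg <- setdiff(rownames(cm), positive)
  tp <- cm[positive, positive]; fn <- cm[positive, neg]
  fp <- cm[neg, positive]; tn <- cm[neg, neg]
  flags <- list(zero = character())
  r <- .safe_div(tp, tp + fn, flags, "sensitivity"); sens <- r$v; flags <- r$flags
  r <- .safe_div(tn, tn + fp, flags, "specificity"); spec <- r$v; flags <- r$flags
  r <- .safe_div(tp + tn, sum(cm), flags, "accuracy"); acc <- r$v; flags <- r$flags
  r <- .safe_div(tp, tp + fp, flags, "precision"); prec <- r$v; flags <- r$flags
  r <- .safe_div(2 * prec * sens, prec + sens, flags, "f1"); f1 <- r$v; flags <- r$flags
  if (length(flags$zero)) {
    warning(sprintf("zero denominator; reported as 0: %s",
                    paste(unique(flags$zero), collapse = ", ")))
  }
  structure(list(
    metrics = c(sensitivity = sens, specificity = spec, accuracy = acc,
                precision = prec, f1 = f1, auc = auc),
    positive = positive, confusion = cm,
    zero_denominator = unique(flags$zero)),
    class = "sp_report")
}

#' Macro-averaged multiclass report
#'
#' One-vs-rest sensitivity, specificity, precision and F1 per class,
#' averaged with equal weight (macro-averaging); accuracy is
#' `trace / total`.
#'
#' @param cm K x K [confusion()] matrix, K >= 3.
#' @return list of class `sp_report` with `metrics`, `per_class`,
#'   `confusion`, `zero_denominator`.
#' @export
report_multiclass_macro <- function(cm) {
  k <- nrow(cm)
  if (is.null(dim(cm)) || k < 3L || ncol(cm) != k) {
    stop(sp_condition("bad_confusion", "need a K x K matrix with K >= 3"))
  }
  total <- sum(cm)
  flags <- character()
  per <- t(vapply(seq_len(k), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, -i]); fp <- sum(cm[-i, i])
    tn <- total - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else { flags <<- c(flags, "sensitivity"); 0 }
    spec <- if (tn + fp > 0) tn / (tn + fp) else { flags <<- c(flags, "specificity"); 0 }
    prec <- if (tp + fp > 0) tp / (tp + fp) else { flags <<- c(flags, "precision"); 0 }
    f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else { flags <<- c(flags, "f1"); 0 }
    c(sensitivity = sens, specificity = spec, precision = prec, f1 = f1)
  }, numeric(4)))
  rownames(per) <- rownames(cm)
  if (length(flags)) {
    warning(sprintf("zero denominator; reported as 0: %s",
                    paste(unique(flags), collapse = ", ")))
  }
  structure(list(
    metrics = c(sensitivity = mean(per[, "sensitivity"]),
                specificity = mean(per[, "specificity"]),
                accuracy = sum(diag(cm)) / total,
                precision = mean(per[, "precision"]),
                f1 = mean(per[, "f1"]), auc = NA_real_),
    per_class = per, confusion = cm, zero_denominator = unique(flags)),
    class = "sp_report")
}

#' @export
print.sp_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("%s report%s:\n",
              if (is.null(x$per_class)) "Binary" else "Macro-averaged multiclass",
              if (!is.null(x$positive)) sprintf(" (positive: %s)", x$positive) else ""))
  cat(paste(sprintf("  %-11s %.3f", names(m)[!is.na(m)], m[!is.na(m)]),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney AUC of decision scores: the probability that a random
#' positive scores above a random negative, with ties sharing rank.
#'
#' @param scores numeric decision scores (higher = more positive).
#' @param labels binary labels.
#' @param positive the positive class; defaults to the first sorted
#'   label.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = sort(unique(labels))[1L]) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop(sp_condition("insufficient_data", "both classes must be present"))
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run the four discriminant analyses
#'
#' Reproduces the discriminant protocol: for each of MDD-vs-HC,
#' BPD-vs-HC, BPD-vs-MDD and the three-class problem, draw a balanced
#' subsample (`n_per_group` per group), run leave-one-out
#' cross-validated classification, and compute the confusion matrix and
#' metric suite (plus rank-based AUC for the binary analyses).
#'
#' @param fm an `sp_features` matrix with all three groups.
#' @param svm a [svm_config()].
#' @param model classifier name from [classifier_registry()].
#' @param n_per_group balanced subsample size per group (default 50).
#' @param seed RNG seed for the subsampling.
#' @return object of class `sp_discrimination`: named list of analyses
#'   (`mdd_hc`, `bpd_hc`, `bpd_mdd`, `three_class`), each with
#'   `confusion`, `report`, `n`; plus `config` and `seed`.
#' @export
run_discriminations <- function(fm, svm = svm_config(), model = "svm",
                                n_per_group = 50L, seed = 1L) {
  need <- c("BPD", "MDD", "HC")
  missing_g <- setdiff(need, unique(fm$group))
  if (length(missing_g)) {
    stop(sp_condition("insufficient_group", sprintf(
      "group(s) absent from the feature matrix: %s",
      paste(missing_g, collapse = ", "))))
  }
  analyses <- list(
    mdd_hc = list(groups = c("MDD", "HC"), positive = "MDD"),
    bpd_hc = list(groups = c("BPD", "HC"), positive = "BPD"),
    bpd_mdd = list(groups = c("BPD", "MDD"), positive = "BPD"),
    three_class = list(groups = c("BPD", "MDD", "HC"), positive = NULL)
  )
  spec <- classifier_registry(model, svm = svm)
  feat_cols <- setdiff(names(fm), c("participant_id", "group"))
  out <- list()
  for (i in seq_along(analyses)) {
    an <- analyses[[i]]
    sub <- fm[fm$group %in% an$groups, , drop = FALSE]
    bal <- subsample_balanced(sub, n_per_group, seed = seed + i - 1L)
    cv <- loocv_predict(bal[, feat_cols], bal$group, model = spec)
    classes <- if (is.null(an$positive)) need else
      c(an$positive, setdiff(an$groups, an$positive))
    cm <- confusion(bal$group, cv$predicted, classes)
    rep <- if (is.null(an$positive)) {
      report_multiclass_macro(cm)
    } else {
      # the ROC of a binary rule is invariant to which class is called
      # positive once the score direction is matched, so the AUC is
      # computed with the score's own reference class
      auc <- roc_auc(cv$score, bal$group, positive = cv$levels[1L])
      report_binary(cm, positive = an$positive, auc = auc)
    }
    out[[names(analyses)[i]]] <- list(confusion = cm, report = rep,
                                      n = nrow(bal))
  }
  structure(list(analyses = out, config = spec$name,
                 svm = if (model == "svm") unclass(svm) else NULL,
                 n_per_group = n_per_group, seed = seed),
            class = "sp_discrimination")
}

#' @export
print.sp_discrimination <- function(x, ...) {
  cat(sprintf("Discriminant analyses (%s, %d per group, LOOCV):\n",
              x$config, x$n_per_group))
  for (nm in names(x$analyses)) {
    m <- x$analyses[[nm]]$report$metrics
    cat(sprintf("  %-12s accuracy %.2f  sensitivity %.2f  specificity %.2f\n",
                nm, m["accuracy"], m["sensitivity"], m["specificity"]))
  }
  invisible(x)
}

#' @export
summary.sp_discrimination <- function(object, ...) {
  rows <- lapply(names(object$analyses), function(nm) {
    m <- object$analyses[[nm]]$report$metrics
    data.frame(analysis = nm, t(m), check.names = FALSE)
  })
  do.call(rbind, rows)
}
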