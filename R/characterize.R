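# Missingness diagnostics: completeness ranking and presence prediction.

#' Rank variables by missingness and trace the complete-case curve
#'
#' Variables are sorted by missing count, lowest to highest. At each rank the
#' table reports the percentage of patients missing that variable and the
#' percentage of patients complete for all variables of equal or lower rank.
#' The curve's elbow indicates how many variables can be kept before the
#' complete-case pool collapses.
#'
#' @param x A [lab_matrix()] or matrix with `NA` for missing cells.
#' @return A data.frame with columns `rank`, `variable`, `n_missing`,
#'   `pct_missing`, `pct_complete` (cumulative).
#' @export
missingness_ranking <- function(x) {
  v <- lab_values(x)
  if (!nrow(v) || !ncol(v)) stop("matrix must be nonempty", call. = FALSE)
  miss <- colSums(is.na(v))
  ord <- order(miss, colnames(v))
  complete <- rep(TRUE, nrow(v))
  pct_complete <- numeric(ncol(v))
  for (r in seq_along(ord)) {
    complete <- complete & !is.na(v[, ord[r]])
    pct_complete[r] <- 100 * mean(complete)
  }
  data.frame(rank = seq_along(ord), variable = colnames(v)[ord],
             n_missing = unname(miss[ord]),
             pct_missing = unname(100 * miss[ord] / nrow(v)),
             pct_complete = pct_complete,
             stringsAsFactors = FALSE)
}

#' Area under the ROC curve by the trapezoidal rule
#'
#' Equivalent to the normalized Mann-Whitney statistic: tied score pairs
#' count as half concordant.
#'
#' @param labels Binary vector (logical, or 0/1) with both classes present.
#' @param scores Numeric scores; higher means more likely positive.
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))  # 0.75
auroc <- function(labels, scores) {
  labels <- as.numeric(labels)
  if (length(labels) != length(scores))
    stop("`labels` and `scores` must have equal length", call. = FALSE)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute an AUROC", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Predict the presence of a laboratory variable from other variables' values
#'
#' Converts the target variable to a binary presence label and trains a
#' random-forest classifier on the values of all variables outside the
#' target's panel (panel co-members are excluded because their presence is
#' trivially informative: panels are ordered jointly). Feature cells that are
#' themselves missing are mean-filled and flagged by per-variable missing
#' indicators. Accuracy is assessed by per-fold AUROC under label-stratified
#' k-fold cross-validation. AUROCs near 0.5 indicate unpredictable (MCAR-like)
#' missingness; high AUROCs indicate MAR-like structure.
#'
#' @param x A [lab_matrix()] whose `NA` pattern defines presence.
#' @param target Column name of the target variable.
#' @param folds Number of cross-validation folds (default 10); lowered with a
#'   message when the rarer class has fewer members than folds.
#' @param seed Integer seed for fold assignment and forest fitting.
#' @param num_trees Trees per forest (default 100).
#' @return An object of class `presence_prediction`: list with `target`,
#'   `auroc` (per fold), `mean_auroc`, `features`, `folds`.
#' @export
predict_presence <- function(x, target, folds = 10, seed = 1, num_trees = 100) {
  stopifnot(inherits(x, "lab_matrix"))
  v <- x$values
  if (!target %in% colnames(v)) stop("unknown target '", target, "'", call. = FALSE)
  panels <- panel_of(x)
  feat_vars <- colnames(v)[panels != panels[match(target, colnames(v))]]
  if (!length(feat_vars))
    stop("no feature variables outside the panel of '", target, "'", call. = FALSE)

  label <- factor(ifelse(is.na(v[, target]), "missing", "present"),
                  levels = c("missing", "present"))
  if (nlevels(droplevels(label)) < 2)
    stop("target '", target, "' must have both observed and missing patients",
         call. = FALSE)

  feats <- v[, feat_vars, drop = FALSE]
  filled <- feats
  ind <- NULL
  for (j in seq_len(ncol(feats))) {
    nas <- is.na(feats[, j])
    if (any(nas)) {
      filled[nas, j] <- mean(feats[, j], na.rm = TRUE)
      ind <- cbind(ind, as.numeric(nas))
      colnames(ind)[ncol(ind)] <- paste0(feat_vars[j], "_missing")
    }
  }
  design <- as.data.frame(cbind(filled, ind))

  min_class <- min(table(label))
  if (min_class < folds) {
    message("reducing folds from ", folds, " to ", min_class,
            " (rarer class size)")
    folds <- max(2L, as.integer(min_class))
  }

  set.seed(derive_seed(seed, "presence_folds", target))
  fold_id <- integer(length(label))
  for (cl in levels(label)) {
    idx <- which(label == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }

  aucs <- numeric(folds)
  for (k in seq_len(folds)) {
    test <- fold_id == k
    fit <- ranger::ranger(
      x = design[!test, , drop = FALSE], y = label[!test],
      num.trees = num_trees, probability = TRUE,
      seed = derive_seed(seed, "presence_rf", target, k), num.threads = 1)
    prob <- stats::predict(fit, design[test, , drop = FALSE],
                           num.threads = 1)$predictions[, "missing"]
    aucs[k] <- auroc(label[test] == "missing", prob)
  }
  structure(list(target = target, auroc = aucs, mean_auroc = mean(aucs),
                 features = feat_vars, folds = folds),
            class = "presence_prediction")
}

#' @export
print.presence_prediction <- function(x, ...) {
  cat("<presence_prediction> target ", x$target, ": mean AUROC ",
      sprintf("%.3f", x$mean_auroc), " over ", x$folds, " folds (",
      length(x$features), " features)\n", sep = "")
  invisible(x)
}
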