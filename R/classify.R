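#' Area under the ROC curve with bootstrap confidence interval
#'
#' AUC is computed as the Mann-Whitney U statistic over positive/negative
#' score pairs divided by `n_pos * n_neg`, with half credit for ties —
#' the probability that a random case outscores a random control. The 95%
#' CI comes from a stratified bootstrap (cases and controls resampled
#' separately).
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical/0-1/two-level vector; `TRUE`, `1` or level
#'   `"case"` marks positives.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return List: `auc`, `ci_low`, `ci_high`.
#' @export
roc_auc <- function(scores, labels, n_boot = 2000L, seed = 1L) {
  pos <- .as_positive(labels)
  if (!any(pos) || all(pos)) stop("need both classes", call. = FALSE)
  auc <- .auc(scores, pos)
  ip <- which(pos); in_ <- which(!pos)
  boots <- .seeded(seed, vapply(seq_len(n_boot), function(b) {
    bi <- c(sample(ip, length(ip), replace = TRUE),
            sample(in_, length(in_), replace = TRUE))
    .auc(scores[bi], pos[bi])
  }, numeric(1L)))
  ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  list(auc = auc, ci_low = ci[1L], ci_high = ci[2L])
}

.auc <- function(scores, pos) {
  r <- rank(scores)
  n1 <- sum(pos); n2 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

.as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  g <- as.character(labels)
  lev <- unique(g)
  if (length(lev) != 2L) stop("labels must have exactly 2 classes", call. = FALSE)
  case_level <- if ("case" %in% lev) "case" else
    if ("1" %in% lev) "1" else lev[1L]
  g == case_level
}

#' Random-forest classification of disease status from MLG profiles
#'
#' Trains a random forest (default 10,000 trees, the convention for
#' microbiome classifiers at cohort scale) inside stratified k-fold
#' cross-validation. Out-of-fold predicted probabilities are pooled into a
#' single ROC curve: `cv_error` is the pooled misclassification rate at
#' probability 0.5, `auc` the pooled out-of-fold AUC with stratified
#' bootstrap CI, and `importance` the mean-decrease-in-impurity scores
#' averaged over folds (top `n_top` reported).
#'
#' @param mlg_profile `rel_abundance` at MLG level (features x samples).
#' @param labels Two-class vector aligned with samples ("case" = positive).
#' @param n_trees Trees per forest (default 10000).
#' @param n_folds Stratified folds (default 5).
#' @param seed Integer seed controlling folds and forests.
#' @param n_top Number of top-importance features to report (default 20).
#' @return A `classification_report` list: `cv_error`, `auc`, `auc_ci`,
#'   `importance` (data.frame mlg_id, score, non-increasing), `oob_scores`
#'   (pooled out-of-fold case probabilities), `n_trees`, `seed`.
#' @export
train_and_evaluate <- function(mlg_profile, labels, n_trees = 10000L,
                               n_folds = 5L, seed = 1L, n_top = 20L) {
  m <- t(as.matrix(mlg_profile))           # samples x features
  pos <- .as_positive(labels)
  if (sum(pos) < 10L || sum(!pos) < 10L)
    warning("fewer than 10 samples in a class; CV estimates will be noisy")
  y <- factor(ifelse(pos, "case", "control"), levels = c("control", "case"))
  n <- nrow(m)
  .seeded(seed, {
    folds <- integer(n)
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    prob <- numeric(n)
    imp <- matrix(0, ncol(m), n_folds,
                  dimnames = list(colnames(m), NULL))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      fit <- randomForest::randomForest(
        x = m[tr, , drop = FALSE], y = y[tr], ntree = n_trees)
      prob[!tr] <- stats::predict(fit, m[!tr, , drop = FALSE],
                                  type = "prob")[, "case"]
      imp[, f] <- fit$importance[, "MeanDecreaseGini"]
    }
    cv_error <- mean((prob >= 0.5) != (y == "case"))
    roc <- roc_auc(prob, pos, seed = seed + 1L)
    sc <- sort(rowMeans(imp), decreasing = TRUE)
    structure(list(cv_error = cv_error,
                   auc = roc$auc,
                   auc_ci = c(low = roc$ci_low, high = roc$ci_high),
                   importance = data.frame(
                     mlg_id = names(sc)[seq_len(min(n_top, length(sc)))],
                     score = unname(sc)[seq_len(min(n_top, length(sc)))],
                     stringsAsFactors = FALSE),
                   oob_scores = stats::setNames(prob, rownames(m)),
                   n_trees = n_trees, n_folds = n_folds, seed = seed),
              class = "classification_report")
  })
}

#' ROC curve points from scores
#'
#' @param scores Classifier scores.
#' @param labels Two-class labels ("case" positive).
#' @return data.frame: threshold, fpr, tpr.
#' @export
roc_curve <- function(scores, labels) {
  pos <- .as_positive(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  data.frame(
    threshold = th,
    fpr = vapply(th, function(t) mean(scores[!pos] >= t), numeric(1L)),
    tpr = vapply(th, function(t) mean(scores[pos] >= t), numeric(1L)))
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "random forest (%d trees, %d-fold CV): cv_error = %.3f, AUC = %.3f (95%% CI %.3f-%.3f)\n",
    x$n_trees, x$n_folds, x$cv_error, x$auc, x$auc_ci[1L], x$auc_ci[2L]))
  invisible(x)
}
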