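#' Mann-Whitney AUC
#'
#' The area under the ROC curve as the probability that a random case
#' scores above a random control, with ties counted half:
#' `AUC = (#{case > control} + 0.5 * #{ties}) / (n_case * n_control)`.
#'
#' @param scores Numeric vector of classifier scores (higher = more
#'   case-like).
#' @param labels `"case"`/`"control"` vector aligned with `scores`.
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels) {
  is_case <- labels == "case"
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) {
    stop("AUC needs at least one case and one control", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC points from scores
#'
#' Sweeps the decision threshold over the distinct score values (ties
#' grouped) and returns the (FPR, TPR) staircase from (0, 0) to (1, 1).
#'
#' @inheritParams auc_mann_whitney
#' @return Tibble with columns `fpr`, `tpr`, monotone non-decreasing.
#' @export
roc_points <- function(scores, labels) {
  is_case <- labels == "case"
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- is_case[o]
  last_of_tie <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(!y)[last_of_tie]
  tibble::tibble(fpr = c(0, fp / sum(!is_case)),
                 tpr = c(0, tp / sum(is_case)))
}

#' Cross-validated single-feature ROC AUC
#'
#' Evaluates how well one feature separates case from control samples by
#' stratified k-fold cross-validation: on each training split a univariate
#' logistic score is fit (`method = "logistic"`, default) or the raw
#' expression is used unchanged (`method = "raw"`), held-out samples are
#' scored, and the pooled out-of-fold scores give the ROC curve and its
#' Mann-Whitney AUC. Deterministic for a fixed seed.
#'
#' @param study An [expression_study].
#' @param feature Feature id present in the study.
#' @param k Number of folds (default 5); each class must have at least `k`
#'   samples.
#' @param seed Integer seed for the fold shuffle.
#' @param method `"logistic"` or `"raw"`.
#' @return Object of class `auc_result`: list with `feature`, `auc`, `roc`
#'   (tibble), `orientation` (`case-high`/`case-low`), `folds` (named
#'   integer vector), `scores`, `k`, `seed`, `method`.
#' @export
cv_feature_auc <- function(study, feature, k = 5, seed = 1,
                           method = c("logistic", "raw")) {
  method <- match.arg(method)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (!feature %in% rownames(study$values)) {
    stop("feature not found in study", call. = FALSE)
  }
  x <- study$values[feature, ]
  y <- as.integer(study$labels == "case")
  if (min(sum(y), sum(1 - y)) < k) {
    stop("class too small for ", k, "-fold stratification; use smaller k",
         call. = FALSE)
  }
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  names(folds) <- names(x)

  scores <- numeric(length(x))
  for (f in seq_len(k)) {
    test <- folds == f
    if (method == "raw") {
      scores[test] <- x[test]
    } else {
      fit <- suppressWarnings(
        glm(y[!test] ~ x[!test], family = binomial())
      )
      beta <- coef(fit)
      beta[is.na(beta)] <- 0
      scores[test] <- beta[1] + beta[2] * x[test]
    }
  }
  labels <- study$labels
  auc <- auc_mann_whitney(scores, labels)
  orientation <- if (mean(x[y == 1]) >= mean(x[y == 0])) "case-high" else "case-low"
  structure(
    list(feature = feature, auc = auc, roc = roc_points(scores, labels),
         orientation = orientation, folds = folds, scores = scores,
         k = k, seed = seed, method = method),
    class = "auc_result"
  )
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> %s: %d-fold CV AUC = %.4f (%s)\n",
              x$feature, x$k, x$auc, x$orientation))
  invisible(x)
}

#' @export
tidy.auc_result <- function(x, ...) x$roc

#' @export
glance.auc_result <- function(x, ...) {
  tibble::tibble(feature = x$feature, auc = x$auc,
                 orientation = x$orientation, k = x$k, seed = x$seed,
                 method = x$method)
}

#' Cross-validated AUC for a set of features
#'
#' @inheritParams cv_feature_auc
#' @param features Character vector of feature ids.
#' @return Tibble: `feature`, `auc`, `orientation`, `k`, `seed`, ordered by
#'   decreasing AUC.
#' @export
evaluate_biomarkers <- function(study, features, k = 5, seed = 1,
                                method = "logistic") {
  features <- intersect(features, rownames(study$values))
  purrr::map_dfr(features, function(f) {
    glance(cv_feature_auc(study, f, k = k, seed = seed, method = method))
  }) |>
    dplyr::select("feature", "auc", "orientation", "k", "seed") |>
    dplyr::arrange(dplyr::desc(.data$auc))
}
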