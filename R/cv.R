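#' Cross-validation and classifier configuration
#'
#' Bundles the settings of the repeated, stratified k-fold cross-validation
#' used to estimate single-feature and feature-pair classification
#' accuracies.
#'
#' @param n_folds Number of CV folds (default 5; each fold holds ~20% out).
#' @param n_repeats Number of independent fold randomizations averaged over
#'   (default 5).
#' @param classifier One of `"svm_linear"` (default), `"svm_rbf"`,
#'   `"naive_bayes"`, `"random_forest"`.
#' @param cost SVM regularization constant C (default 1).
#' @param gamma RBF kernel width; `NULL` uses 1 / n_features.
#' @param standardize Z-score each feature with training-fold mean/sd
#'   before fitting, applying the same constants to the held-out fold
#'   (default `TRUE`).
#' @param seed Integer seed controlling fold randomization (and any
#'   classifier-internal randomness).
#' @param workers Number of parallel workers for the all-pairs sweep;
#'   results are independent of this value.
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_folds = 5, n_repeats = 5,
                      classifier = c("svm_linear", "svm_rbf",
                                     "naive_bayes", "random_forest"),
                      cost = 1, gamma = NULL, standardize = TRUE,
                      seed = 1, workers = 1) {
  classifier <- match.arg(classifier)
  stopifnot(n_folds >= 2, n_repeats >= 1, cost > 0, workers >= 1)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 classifier = classifier, cost = cost, gamma = gamma,
                 standardize = isTRUE(standardize),
                 seed = as.integer(seed), workers = as.integer(workers)),
            class = "cv_config")
}

#' Build a shared stratified fold plan
#'
#' Partitions the samples into `n_folds` folds, once per repeat, stratified
#' by class so every fold's class composition is within one sample of
#' proportionality. The same plan is reused for every feature and every
#' pair within a run, so accuracy differences reflect the features rather
#' than split noise.
#'
#' @param labels Label tibble (two classes).
#' @param config A [cv_config()].
#' @return An integer matrix (samples x repeats) of fold ids 1..n_folds,
#'   with sample ids as row names; class `fold_plan`.
#' @export
make_fold_plan <- function(labels, config = cv_config()) {
  validate_labels(labels)
  k <- config$n_folds
  counts <- table(labels$class)
  if (any(counts < k)) {
    stop(sprintf("each class needs >= %d samples for %d-fold CV (have %s)",
                 k, k, paste(counts, collapse = "+")), call. = FALSE)
  }
  if (any(counts < 2 * k)) {
    warning("a class has fewer than 2 x n_folds samples; accuracy estimates will be coarse")
  }
  n <- nrow(labels)
  plan <- matrix(NA_integer_, n, config$n_repeats,
                 dimnames = list(labels$sample_id, NULL))
  withr::with_seed(config$seed, {
    for (r in seq_len(config$n_repeats)) {
      for (cl in unique(labels$class)) {
        idx <- which(labels$class == cl)
        plan[idx, r] <- sample(rep(seq_len(k), length.out = length(idx)))
      }
    }
  })
  structure(plan, class = c("fold_plan", class(plan)),
            n_folds = k, n_repeats = config$n_repeats, seed = config$seed)
}
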