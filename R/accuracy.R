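#' Cross-validated accuracy of a single feature or a feature pair
#'
#' Runs the repeated stratified k-fold scheme of a shared [make_fold_plan()]
#' on one feature (or one unordered pair), fitting the configured classifier
#' on the training folds and scoring fraction-correct on each held-out fold.
#' Features are z-scored with training-fold constants when
#' `config$standardize` is `TRUE`. A training fold with zero variance never
#' raises an error: the prediction falls back to the training-fold majority
#' class (ties resolve to the class listed first in the labels).
#'
#' @param expr Expression tibble (complete, no `NA`).
#' @param labels Label tibble covering the expression samples.
#' @param features Character vector of 1 or 2 feature ids to use.
#' @param plan Fold plan from [make_fold_plan()].
#' @param config A [cv_config()].
#' @return An `accuracy_estimate`: list with `mean_accuracy` and the
#'   per-repeat accuracy vector `per_repeat`.
#' @export
estimate_accuracy <- function(expr, labels, features, plan,
                              config = cv_config()) {
  stopifnot(length(features) %in% c(1, 2))
  labels <- bind_labels(expr, labels)
  m <- expr_as_matrix(expr)
  if (!all(features %in% rownames(m))) {
    stop("unknown feature id(s): ",
         paste(setdiff(features, rownames(m)), collapse = ", "), call. = FALSE)
  }
  acc <- accuracy_backend(m, labels, list(match(features, rownames(m))),
                          plan, config)
  new_accuracy_estimate(acc[1, ])
}

#' Single-feature accuracies for every feature
#'
#' @inheritParams estimate_accuracy
#' @return Tibble with `feature_id`, `mean_accuracy`, and a `per_repeat`
#'   list column, in matrix row order.
#' @export
all_single_accuracies <- function(expr, labels, plan, config = cv_config()) {
  labels <- bind_labels(expr, labels)
  m <- expr_as_matrix(expr)
  acc <- accuracy_backend(m, labels, as.list(seq_len(nrow(m))), plan, config)
  tibble::tibble(
    feature_id = rownames(m),
    mean_accuracy = rowMeans(acc),
    per_repeat = lapply(seq_len(nrow(acc)), function(i) acc[i, ])
  )
}

#' Accuracies for all feature pairs
#'
#' Evaluates every unordered pair of features — N(N-1)/2 evaluations, each
#' on the identical fold plan used for the single features — and returns a
#' store holding the single-feature accuracy vector and the symmetric pair
#' accuracy matrix. The sweep may be split across `config$workers`
#' processes; results are gathered by pair index so the outcome is
#' independent of worker count and scheduling.
#'
#' @inheritParams estimate_accuracy
#' @param singles Optional precomputed result of [all_single_accuracies()]
#'   (computed here when `NULL`).
#' @return An `accuracy_store`: list with `feature_ids`, `single` (named
#'   vector), `pair` (symmetric matrix, `NA` diagonal), `n_pair_evals`
#'   (evaluation counter), and `config`.
#' @export
all_pair_accuracies <- function(expr, labels, plan, config = cv_config(),
                                singles = NULL) {
  labels <- bind_labels(expr, labels)
  m <- expr_as_matrix(expr)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 features for pair accuracies", call. = FALSE)
  if (is.null(singles)) {
    singles <- all_single_accuracies(expr, labels, plan, config)
  }
  pairs_idx <- utils::combn(n, 2)
  subsets <- lapply(seq_len(ncol(pairs_idx)), function(i) pairs_idx[, i])

  if (config$workers > 1 && length(subsets) > 1) {
    chunks <- split(seq_along(subsets),
                    cut(seq_along(subsets), config$workers, labels = FALSE))
    parts <- parallel::mclapply(chunks, function(ix) {
      accuracy_backend(m, labels, subsets[ix], plan, config)
    }, mc.cores = config$workers)
    acc <- do.call(rbind, parts)  # chunk order = pair-index order
  } else {
    acc <- accuracy_backend(m, labels, subsets, plan, config)
  }

  pair <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  mean_acc <- rowMeans(acc)
  for (i in seq_len(ncol(pairs_idx))) {
    pair[pairs_idx[1, i], pairs_idx[2, i]] <- mean_acc[i]
    pair[pairs_idx[2, i], pairs_idx[1, i]] <- mean_acc[i]
  }
  structure(list(feature_ids = rownames(m),
                 single = stats::setNames(singles$mean_accuracy,
                                          singles$feature_id),
                 pair = pair,
                 n_pair_evals = length(subsets),
                 config = config),
            class = "accuracy_store")
}

#' @export
print.accuracy_store <- function(x, ...) {
  cat(sprintf("<accuracy_store> %d features, %d pair evaluations (%s)\n",
              length(x$feature_ids), x$n_pair_evals, x$config$classifier))
  invisible(x)
}

new_accuracy_estimate <- function(per_repeat) {
  structure(list(mean_accuracy = mean(per_repeat), per_repeat = per_repeat),
            class = "accuracy_estimate")
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  cat(sprintf("<accuracy_estimate> mean %.3f over %d repeats\n",
              x$mean_accuracy, length(x$per_repeat)))
  invisible(x)
}

# ---- backends --------------------------------------------------------------

# m: features x samples; subsets: list of integer feature-index vectors.
# Returns length(subsets) x n_repeats accuracy matrix.
accuracy_backend <- function(m, labels, subsets, plan, config) {
  if (any(is.na(m))) {
    stop("expression matrix contains missing values; run filter_and_impute() first",
         call. = FALSE)
  }
  lv <- attr(labels, "class_levels") %||% class_levels(labels)
  y01 <- as.integer(labels$class != lv[1])  # 0 = first class level
  plan_m <- unclass(plan)[labels$sample_id, , drop = FALSE]
  X <- t(m)  # samples x features
  if (config$classifier %in% c("svm_linear", "svm_rbf")) {
    cv_accuracy_batch(X, y01, plan_m, subsets, config$cost,
                      if (config$classifier == "svm_linear") 0L else 1L,
                      config$gamma %||% -1, config$standardize)
  } else {
    r_accuracy_backend(X, y01, plan_m, subsets, config)
  }
}

# plug-in classifiers (naive Bayes, random forest) evaluated fold by fold
r_accuracy_backend <- function(X, y01, plan_m, subsets, config) {
  n <- nrow(X)
  R <- ncol(plan_m)
  out <- matrix(NA_real_, length(subsets), R)
  for (b in seq_along(subsets)) {
    for (r in seq_len(R)) {
      correct <- 0L
      for (f in seq_len(attr_or(plan_m, "n_folds", max(plan_m)))) {
        te <- which(plan_m[, r] == f)
        if (length(te) == 0) next
        tr <- setdiff(seq_len(n), te)
        Ztr <- X[tr, subsets[[b]], drop = FALSE]
        Zte <- X[te, subsets[[b]], drop = FALSE]
        if (config$standardize) {
          mu <- colMeans(Ztr)
          s <- apply(Ztr, 2, sd)
          s[s == 0] <- 1
          Ztr <- scale(Ztr, mu, s)
          Zte <- scale(Zte, mu, s)
        }
        pred <- fit_predict_r(Ztr, y01[tr], Zte, config,
                              fit_seed = config$seed + 7919L * r + f)
        correct <- correct + sum(pred == y01[te])
      }
      out[b, r] <- correct / n
    }
  }
  out
}

# returns predicted 0/1; any failure (e.g. zero-variance feature) falls back
# to the training majority, ties toward class 0 (first label-file class)
fit_predict_r <- function(Ztr, ytr, Zte, config, fit_seed) {
  majority <- if (sum(ytr == 0) >= sum(ytr == 1)) 0L else 1L
  if (length(unique(ytr)) < 2 || all(apply(Ztr, 2, function(c) length(unique(c))) == 1)) {
    return(rep(majority, nrow(Zte)))
  }
  yf <- factor(ytr, levels = c(0, 1))
  colnames(Ztr) <- colnames(Zte) <- paste0("V", seq_len(ncol(Ztr)))
  pred <- tryCatch(withr::with_seed(fit_seed, {
    if (config$classifier == "naive_bayes") {
      fit <- e1071::naiveBayes(Ztr, yf)
      as.integer(as.character(predict(fit, Zte)))
    } else {
      if (!requireNamespace("randomForest", quietly = TRUE)) {
        stop("the random_forest classifier needs the randomForest package")
      }
      fit <- randomForest::randomForest(Ztr, yf)
      as.integer(as.character(predict(fit, Zte)))
    }
  }), error = function(e) rep(majority, nrow(Zte)))
  pred[is.na(pred)] <- majority
  pred
}

attr_or <- function(x, name, default) attr(x, name) %||% default
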