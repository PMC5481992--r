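#' Welch t-test prefilter
#'
#' Ranks features by the absolute Welch (unequal-variance) two-sample t
#' statistic between the two classes and keeps the top `k`, making the
#' all-pairs accuracy sweep tractable. Ties in |t| break by feature id
#' (lexicographic). A feature with zero variance in both classes and equal
#' means gets t = 0; with unequal means it gets an infinite |t| and ranks
#' at the top.
#'
#' @param expr Expression tibble.
#' @param labels Two-class label tibble.
#' @param k Number of features to keep (default 300); `k >= N` keeps all.
#' @return A `prefilter_result` tibble: `feature_id`, `t`, `p_value`,
#'   `kept`, ordered by |t| descending. The kept ids (in that order) are in
#'   attribute `"kept"`.
#' @export
prefilter_ttest <- function(expr, labels, k = 300) {
  labels <- bind_labels(expr, labels)
  m <- expr_as_matrix(expr)
  lv <- attr(labels, "class_levels") %||% class_levels(labels)
  g1 <- m[, labels$class == lv[1], drop = FALSE]
  g2 <- m[, labels$class == lv[2], drop = FALSE]
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  if (any(n1 < 2) || any(n2 < 2)) {
    stop("each class needs >= 2 observations per feature", call. = FALSE)
  }
  m1 <- rowMeans(g1, na.rm = TRUE); m2 <- rowMeans(g2, na.rm = TRUE)
  v1 <- apply(g1, 1, stats::var, na.rm = TRUE)
  v2 <- apply(g2, 1, stats::var, na.rm = TRUE)
  se2 <- v1 / n1 + v2 / n2
  t <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2),
              ifelse(m1 == m2, 0, Inf * sign(m1 - m2)))
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- ifelse(is.finite(t) & se2 > 0, 2 * pt(-abs(t), df),
              ifelse(t == 0, 1, 0))
  res <- tibble::tibble(feature_id = rownames(m), t = unname(t),
                        p_value = unname(p)) |>
    dplyr::arrange(dplyr::desc(abs(.data$t)), .data$feature_id) |>
    dplyr::mutate(kept = dplyr::row_number() <= min(k, dplyr::n()))
  structure(res, kept = res$feature_id[res$kept],
            class = c("prefilter_result", class(res)))
}

#' Improvement scores from an accuracy store
#'
#' The improvement score of an unordered feature pair is the cross-validated
#' accuracy of the pair minus the better of the two single-feature
#' accuracies:
#' `IS(Fi, Fj) = Acc(Fi, Fj) - max(Acc(Fi), Acc(Fj))`.
#' Negative values (harmful pairings) are preserved.
#'
#' @param store An `accuracy_store` from [all_pair_accuracies()].
#' @return Symmetric numeric matrix of improvement scores (class
#'   `is_matrix`), `NA` diagonal, feature ids as dimnames.
#' @export
improvement_scores <- function(store) {
  stopifnot(inherits(store, "accuracy_store"))
  best_single <- outer(store$single, store$single, pmax)
  is_mat <- store$pair - best_single
  diag(is_mat) <- NA_real_
  structure(is_mat, class = c("is_matrix", class(is_mat)))
}

#' Early Response Index scores
#'
#' A feature's ERI is the average of its improvement scores over all N - 1
#' partner features: `ERI(Fi) = sum_{j != i} IS(Fi, Fj) / (N - 1)`, where N
#' is the number of features entering the pairwise sweep. Features that
#' consistently help other features classify — even when individually
#' unremarkable — obtain high ERI.
#'
#' @param is_matrix Improvement-score matrix from [improvement_scores()].
#' @return Tibble `feature_id`, `eri`, `rank`, `significant` (all `NA`
#'   until a cutoff is attached via [call_significant()]), sorted by
#'   descending ERI with ties broken by feature id.
#' @export
eri_scores <- function(is_matrix) {
  n <- nrow(is_matrix)
  if (is.null(n) || n < 2) stop("ERI needs at least 2 features", call. = FALSE)
  eri <- rowSums(is_matrix, na.rm = TRUE) / (n - 1)
  tibble::tibble(feature_id = rownames(is_matrix), eri = unname(eri)) |>
    dplyr::arrange(dplyr::desc(.data$eri), .data$feature_id) |>
    dplyr::mutate(rank = dplyr::row_number(), significant = NA)
}

#' Run the full ERI scoring pipeline
#'
#' Orchestrates prefiltering, the shared fold plan, single and pairwise
#' accuracy estimation, improvement scores and ERI ranking. Deterministic
#' given `(expr, labels, config, k)`.
#'
#' @param expr Complete expression tibble (run [filter_and_impute()] first
#'   if it has missing cells).
#' @param labels Two-class label tibble.
#' @param config A [cv_config()]; its `seed` pins the fold randomization.
#' @param k Prefilter size passed to [prefilter_ttest()].
#' @return An `eri_fit` object with components `table` (the ERI tibble),
#'   `is` (improvement-score matrix), `store` (accuracies), `prefilter`,
#'   `plan`, `config`, `k`, `n_input_features`. Use [tidy()], [glance()],
#'   [autoplot()] on it.
#' @export
#' @examples
#' sim <- simulate_expression(n_features = 8, n_per_class = 10,
#'                            n_responders = 2, effect_size = 1.5, seed = 3)
#' fit <- run_eri(sim$expression, sim$labels, cv_config(seed = 3), k = 8)
#' head(tidy(fit))
run_eri <- function(expr, labels, config = cv_config(), k = 300) {
  validate_expression(expr)
  labels <- bind_labels(expr, labels)
  pre <- prefilter_ttest(expr, labels, k = k)
  kept <- attr(pre, "kept")
  expr_k <- expr[match(kept, expr$feature_id), , drop = FALSE]
  plan <- make_fold_plan(labels, config)
  singles <- all_single_accuracies(expr_k, labels, plan, config)
  store <- all_pair_accuracies(expr_k, labels, plan, config, singles = singles)
  is_mat <- improvement_scores(store)
  table <- eri_scores(is_mat)
  structure(list(table = table, is = is_mat, store = store, prefilter = pre,
                 plan = plan, config = config, k = k,
                 n_input_features = nrow(expr),
                 class_levels = attr(labels, "class_levels")),
            class = "eri_fit")
}

#' @export
print.eri_fit <- function(x, ...) {
  cat(sprintf(
    "<eri_fit> %d features scored (from %d input, prefilter k=%d), %s, seed %d\n",
    nrow(x$table), x$n_input_features, x$k, x$config$classifier,
    x$config$seed))
  print(head(x$table, 5))
  invisible(x)
}
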