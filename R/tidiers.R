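#' Tidy an ERI fit
#'
#' @param x An `eri_fit` from [run_eri()].
#' @param ... Unused.
#' @return The per-feature ERI tibble (`feature_id`, `eri`, `rank`,
#'   `significant`).
#' @export
tidy.eri_fit <- function(x, ...) x$table

#' @rdname tidy.eri_fit
#' @export
tidy.eri_select <- function(x, ...) x$table

#' @rdname tidy.eri_fit
#' @export
tidy.eri_null <- function(x, ...) tibble::as_tibble(unclass(x))

#' One-row summary of an ERI fit
#'
#' @param x An `eri_fit` or `eri_select`.
#' @param ... Unused.
#' @return One-row tibble of run-level quantities.
#' @export
glance.eri_fit <- function(x, ...) {
  tibble::tibble(
    n_input_features = x$n_input_features,
    n_features = nrow(x$table),
    n_pair_evals = x$store$n_pair_evals,
    classifier = x$config$classifier,
    n_folds = x$config$n_folds,
    n_repeats = x$config$n_repeats,
    seed = x$config$seed,
    mean_single_accuracy = mean(x$store$single),
    max_eri = max(x$table$eri)
  )
}

#' @rdname glance.eri_fit
#' @export
glance.eri_select <- function(x, ...) {
  dplyr::mutate(glance(x$fit),
                cutoff = x$threshold$cutoff,
                rounding = x$threshold$rounding,
                n_trials = x$threshold$n_trials,
                n_significant = sum(x$table$significant))
}
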