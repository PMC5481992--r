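#' Permute two-class sample labels
#'
#' Uniformly random permutation of the label multiset over the sample ids;
#' class sizes are preserved exactly.
#'
#' @param labels Label tibble.
#' @param seed Integer seed.
#' @return Label tibble with permuted `class` column.
#' @export
permute_labels <- function(labels, seed) {
  validate_labels(labels)
  out <- labels
  out$class <- withr::with_seed(seed, sample(labels$class))
  out
}

#' Null distribution of the maximum ERI under label permutation
#'
#' Repeats, `n_trials` times: permute the class labels, rerun the FULL ERI
#' pipeline on the permuted labels (including the t-test prefilter, which
#' also sees the permuted labels), and record the maximum ERI score any
#' feature attains. Trial i uses seed `base_seed + i` for both the
#' permutation and the trial's fold plan.
#'
#' @inheritParams run_eri
#' @param n_trials Number of permutation trials (default 10).
#' @param base_seed Base seed for the trial-derived seeds; defaults to
#'   `config$seed`.
#' @return An `eri_null` tibble: `trial`, `seed`, `max_eri`.
#' @export
null_max_eri <- function(expr, labels, config = cv_config(), k = 300,
                         n_trials = 10, base_seed = config$seed) {
  stopifnot(n_trials >= 1)
  rows <- purrr::map(seq_len(n_trials), function(i) {
    trial_seed <- as.integer(base_seed + i)
    perm <- permute_labels(labels, seed = trial_seed)
    cfg <- config
    cfg$seed <- trial_seed
    fit <- run_eri(expr, perm, cfg, k = k)
    tibble::tibble(trial = i, seed = trial_seed, max_eri = max(fit$table$eri))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, n_trials = n_trials, base_seed = base_seed,
            class = c("eri_null", class(out)))
}

#' Significance cutoff from the permutation null
#'
#' The cutoff is the overall maximum ERI observed across the permutation
#' trials — by construction no permuted (null) feature reaches it, giving a
#' 0% false-positive-rate threshold. Mode `"ceil_3dp"` rounds the maximum
#' up to the next 3-decimal value (e.g. a null maximum of 0.0258 gives a
#' cutoff of 0.026).
#'
#' @param null An `eri_null` from [null_max_eri()].
#' @param rounding `"exact"` (default) or `"ceil_3dp"`.
#' @return An `eri_threshold`: list with `cutoff`, `rounding`, `n_trials`.
#' @export
cutoff_from_null <- function(null, rounding = c("exact", "ceil_3dp")) {
  rounding <- match.arg(rounding)
  if (is.null(null) || nrow(null) == 0) {
    stop("empty null distribution", call. = FALSE)
  }
  mx <- max(null$max_eri)
  cutoff <- if (rounding == "ceil_3dp") ceiling(mx * 1000) / 1000 else mx
  structure(list(cutoff = cutoff, rounding = rounding,
                 n_trials = nrow(null)),
            class = "eri_threshold")
}

#' @export
print.eri_threshold <- function(x, ...) {
  cat(sprintf("<eri_threshold> cutoff %.4g (%s, %d permutation trials)\n",
              x$cutoff, x$rounding, x$n_trials))
  invisible(x)
}

#' Call significant features at an ERI cutoff
#'
#' Marks a feature significant when its ERI score is greater than or equal
#' to the cutoff (inclusive comparison).
#'
#' @param table ERI tibble (from [eri_scores()]) or an `eri_fit`.
#' @param threshold An `eri_threshold` (or a bare numeric cutoff).
#' @return The ERI tibble with the `significant` column filled in.
#' @export
call_significant <- function(table, threshold) {
  cutoff <- if (inherits(threshold, "eri_threshold")) threshold$cutoff
            else as.numeric(threshold)
  if (inherits(table, "eri_fit")) table <- table$table
  dplyr::mutate(table, significant = .data$eri >= cutoff)
}

#' End-to-end ERI feature selection
#'
#' Runs the observed-label ERI pipeline, estimates the permutation null and
#' its 0%-FPR cutoff, and calls significance — the complete feature
#' selection procedure.
#'
#' @inheritParams null_max_eri
#' @param rounding Cutoff rounding mode, see [cutoff_from_null()].
#' @return An `eri_select` object: list with `fit` (the observed
#'   [run_eri()] result), `null`, `threshold`, and `table` (the ERI tibble
#'   with significance calls). Supports [tidy()], [glance()], [autoplot()].
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_expression(n_features = 12, n_per_class = 10,
#'                            n_responders = 3, effect_size = 2, seed = 7)
#' sel <- eri_select(sim$expression, sim$labels, cv_config(seed = 7),
#'                   k = 12, n_trials = 3)
#' glance(sel)
#' }
eri_select <- function(expr, labels, config = cv_config(), k = 300,
                       n_trials = 10, base_seed = config$seed,
                       rounding = c("exact", "ceil_3dp")) {
  fit <- run_eri(expr, labels, config, k = k)
  null <- null_max_eri(expr, labels, config, k = k, n_trials = n_trials,
                       base_seed = base_seed)
  threshold <- cutoff_from_null(null, rounding = match.arg(rounding))
  structure(list(fit = fit, null = null, threshold = threshold,
                 table = call_significant(fit$table, threshold)),
            class = "eri_select")
}

#' @export
print.eri_select <- function(x, ...) {
  cat(sprintf("<eri_select> %d of %d features significant at ERI >= %.4g (%d permutation trials)\n",
              sum(x$table$significant), nrow(x$table), x$threshold$cutoff,
              x$threshold$n_trials))
  invisible(x)
}
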