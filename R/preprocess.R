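#' Merge repeatedly identified peptides within each run
#'
#' In isobaric-label (e.g. TMT 6-plex) experiments the same peptide is often
#' identified by several spectra in one run. Those rows are merged by adding
#' their reporter-channel abundances, so that one row per
#' (`run_id`, `peptide_id`) remains. A merged channel value is missing only
#' when it was missing in every merged row.
#'
#' @param peptides Peptide tibble: columns `run_id`, `peptide_id`,
#'   `protein_id`, then one numeric abundance column per reporter channel
#'   (`NA` = not quantified).
#' @return A tibble with the same columns and at most one row per
#'   (`run_id`, `peptide_id`).
#' @export
merge_duplicate_peptides <- function(peptides) {
  chans <- channel_cols(peptides)
  sum_or_na <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  peptides |>
    dplyr::group_by(.data$run_id, .data$peptide_id) |>
    dplyr::summarise(
      protein_id = dplyr::first(.data$protein_id),
      dplyr::across(dplyr::all_of(chans), sum_or_na),
      .groups = "drop"
    ) |>
    dplyr::select("run_id", "peptide_id", "protein_id",
                  dplyr::all_of(chans))
}

#' Reference-channel ratio normalization
#'
#' Divides each informative channel's abundance by the mean of the
#' reference-channel abundances of the same peptide row. Reference channels
#' measure a pooled sample common to all runs, so the ratio removes
#' run-level experimental bias. Rows where every reference channel is
#' missing carry no usable scale and are dropped (counted in the
#' `"n_dropped"` attribute); a reference mean of zero yields missing ratios
#' with a warning.
#'
#' @param peptides Peptide tibble (see [merge_duplicate_peptides()]).
#' @param reference_channels Names of the reference channel columns.
#' @return Tibble with the id columns and one `ratio` column per
#'   informative channel (original channel column names retained).
#'   Attribute `"n_dropped"` records rows removed for lack of a reference.
#' @export
reference_normalize <- function(peptides, reference_channels) {
  chans <- channel_cols(peptides)
  if (!all(reference_channels %in% chans)) {
    stop("reference_channels must name abundance columns of the table",
         call. = FALSE)
  }
  info <- setdiff(chans, reference_channels)
  if (length(info) == 0) stop("no informative channels left", call. = FALSE)

  ref <- as.matrix(peptides[reference_channels])
  ref_mean <- rowMeans(ref, na.rm = TRUE)
  ref_mean[is.nan(ref_mean)] <- NA_real_

  keep <- !is.na(ref_mean)
  n_zero <- sum(ref_mean[keep] == 0, na.rm = TRUE)
  if (n_zero > 0) {
    warning(sprintf("%d row(s) with zero reference mean; ratios set missing",
                    n_zero))
    ref_mean[!is.na(ref_mean) & ref_mean == 0] <- NA_real_
    keep <- !is.na(ref_mean)
  }

  out <- peptides[keep, c("run_id", "peptide_id", "protein_id", info)]
  out[info] <- as.matrix(out[info]) / ref_mean[keep]
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "informative_channels") <- info
  out
}

#' Quantile normalization across columns
#'
#' Forces the columns of a numeric table to share one distribution: within
#' each column present values are ranked and replaced by the cross-column
#' mean of the values at the same rank, with rank interpolation when
#' columns have unequal numbers of present values (missing entries stay
#' missing). Used here to remove reporter-channel effects from the
#' informative-channel ratio columns, since channel assignment is
#' randomized across runs. Delegates to [limma::normalizeQuantiles()].
#'
#' @param x Numeric matrix or data frame of >= 2 numeric columns (a leading
#'   `feature_id`/id columns are carried through untouched).
#' @return Object of the same shape and class as `x`.
#' @export
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
quantile_normalize <- function(x) {
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    if (sum(num) < 2) stop("need at least 2 numeric columns", call. = FALSE)
    x[num] <- as.data.frame(quantile_normalize(as.matrix(x[num])))
    return(x)
  }
  stopifnot(is.matrix(x))
  if (ncol(x) < 2) stop("need at least 2 columns", call. = FALSE)
  n_present <- colSums(!is.na(x))
  if (any(n_present < 2)) {
    stop(sprintf("column(s) with fewer than 2 present values: %s",
                 paste(colnames(x)[n_present < 2], collapse = ", ")),
         call. = FALSE)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Roll peptide ratios up to protein-level expression
#'
#' A protein's abundance in a biological sample is the median of the ratios
#' of all its unique peptides measured in the run/channel that carries that
#' sample. Cells with no quantified peptide stay missing.
#'
#' @param ratios Ratio tibble from [reference_normalize()] (optionally
#'   quantile normalized).
#' @param channel_map Tibble with columns `run_id`, `channel` (informative
#'   channel column name), `sample_id`: the one-to-one assignment of
#'   run/channel slots to biological samples.
#' @return Expression tibble (`feature_id` = protein, one column per
#'   sample, ordered as in `channel_map`).
#' @export
rollup_proteins <- function(ratios, channel_map) {
  stopifnot(all(c("run_id", "channel", "sample_id") %in% names(channel_map)))
  if (anyDuplicated(channel_map[c("run_id", "channel")]) ||
      anyDuplicated(channel_map$sample_id)) {
    stop("(run, channel) -> sample map must be one-to-one", call. = FALSE)
  }
  info <- setdiff(names(ratios), c("run_id", "peptide_id", "protein_id"))
  long <- ratios |>
    tidyr::pivot_longer(dplyr::all_of(info), names_to = "channel",
                        values_to = "ratio") |>
    dplyr::filter(!is.na(.data$ratio)) |>
    dplyr::inner_join(channel_map, by = c("run_id", "channel"))
  prot <- long |>
    dplyr::group_by(.data$protein_id, .data$sample_id) |>
    dplyr::summarise(value = median(.data$ratio), .groups = "drop")
  wide <- prot |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value") |>
    dplyr::rename(feature_id = "protein_id") |>
    dplyr::arrange(.data$feature_id)
  # all mapped samples appear as columns, in map order, even if empty
  for (s in setdiff(channel_map$sample_id, names(wide))) wide[[s]] <- NA_real_
  wide[c("feature_id", channel_map$sample_id)]
}

#' Filter under-observed features and impute the rest
#'
#' Features (rows) with fewer than `min_observed` present measurements are
#' discarded; remaining missing cells are filled by sampling uniformly,
#' with replacement, from the same row's observed values. Observed values
#' are never altered, and the result is bit-reproducible for a given seed.
#'
#' @param expr Expression tibble with `NA` cells.
#' @param min_observed Minimum number of present measurements a feature
#'   needs to survive (default 12, chosen for designs with 18-20 samples).
#' @param seed Integer seed for the imputation draws.
#' @return Complete expression tibble; attribute `"n_dropped"` records how
#'   many features were discarded.
#' @export
filter_and_impute <- function(expr, min_observed = 12, seed = 1) {
  stopifnot(min_observed >= 1)
  validate_expression(expr)
  m <- expr_as_matrix(expr)
  observed <- rowSums(!is.na(m))
  keep <- observed >= min_observed
  m <- m[keep, , drop = FALSE]
  withr::with_seed(seed, {
    for (i in seq_len(nrow(m))) {
      miss <- is.na(m[i, ])
      if (any(miss)) {
        m[i, miss] <- sample(m[i, !miss], sum(miss), replace = TRUE)
      }
    }
  })
  out <- expr_as_tibble(m)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Full peptide-to-protein preprocessing chain
#'
#' Convenience wrapper running duplicate-peptide merging, reference-channel
#' ratio normalization, quantile normalization of the informative-channel
#' ratios (pooled over runs by default, per run on request), median protein
#' rollup, and the missing-value filter/imputation step.
#'
#' @inheritParams reference_normalize
#' @inheritParams rollup_proteins
#' @inheritParams filter_and_impute
#' @param quantile `"pooled"` (default: one normalization across all runs),
#'   `"per_run"`, or `"none"`.
#' @param log2_transform If `TRUE`, log2-transform the protein matrix after
#'   rollup (ratios are otherwise carried on the natural scale).
#' @return Expression tibble; attributes `"log"` (named counts per stage)
#'   carry the dropped-row bookkeeping.
#' @export
preprocess_peptides <- function(peptides, reference_channels, channel_map,
                                min_observed = 12, seed = 1,
                                quantile = c("pooled", "per_run", "none"),
                                log2_transform = FALSE) {
  quantile <- match.arg(quantile)
  merged <- merge_duplicate_peptides(peptides)
  ratios <- reference_normalize(merged, reference_channels)
  info <- attr(ratios, "informative_channels")
  n_ref_dropped <- attr(ratios, "n_dropped")
  if (quantile == "pooled") {
    ratios[info] <- as.data.frame(quantile_normalize(as.matrix(ratios[info])))
  } else if (quantile == "per_run") {
    ratios <- ratios |>
      dplyr::group_by(.data$run_id) |>
      dplyr::group_modify(function(df, key) {
        df[info] <- as.data.frame(quantile_normalize(as.matrix(df[info])))
        df
      }) |>
      dplyr::ungroup()
  }
  expr <- rollup_proteins(ratios, channel_map)
  n_prot <- nrow(expr)
  expr <- filter_and_impute(expr, min_observed = min_observed, seed = seed)
  if (log2_transform) {
    expr[-1] <- log2(expr[-1])
  }
  attr(expr, "log") <- c(
    peptide_rows_in = nrow(peptides),
    peptide_rows_merged = nrow(merged),
    rows_dropped_no_reference = n_ref_dropped,
    proteins_quantified = n_prot,
    proteins_dropped_min_observed = attr(expr, "n_dropped"),
    proteins_out = nrow(expr)
  )
  expr
}

channel_cols <- function(peptides) {
  ids <- c("run_id", "peptide_id", "protein_id")
  if (!all(ids %in% names(peptides))) {
    stop("peptide table needs columns run_id, peptide_id, protein_id",
         call. = FALSE)
  }
  chans <- setdiff(names(peptides), ids)
  if (length(chans) == 0) stop("no channel abundance columns", call. = FALSE)
  chans
}
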