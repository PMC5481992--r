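#' Simulate a two-class expression matrix with planted early responders
#'
#' Gaussian feature model emulating the early-disease regime the ERI
#' statistic targets: most features carry no class signal, while a minority
#' of "early responder" features are shifted in the second class by a small
#' multiple of the within-class standard deviation. Optionally features
#' share block-wise latent factors to induce within-block correlation.
#'
#' @param n_features Number of features (default 100).
#' @param n_per_class Samples per class (default 20, mimicking a 20 + 20
#'   two-time-point contrast).
#' @param n_responders Number of shifted features (default 10); responders
#'   occupy the first rows and are flagged in the truth table.
#' @param effect_size Mean shift in units of the within-class SD (default
#'   0.8 — a weak, early-stage shift).
#' @param noise_sd Within-class standard deviation (default 1).
#' @param correlation `"independent"` (default) or `"block"`.
#' @param block_size,block_rho Block width and within-block correlation for
#'   `correlation = "block"`.
#' @param class_names Two class labels (default `c("day0", "day5")`); the
#'   shift is applied in the second.
#' @param seed Integer seed.
#' @return List with `expression` (tibble), `labels` (tibble), `truth`
#'   (tibble: `feature_id`, `is_responder`, `effect_size`).
#' @export
simulate_expression <- function(n_features = 100, n_per_class = 20,
                                n_responders = 10, effect_size = 0.8,
                                noise_sd = 1,
                                correlation = c("independent", "block"),
                                block_size = 10, block_rho = 0.5,
                                class_names = c("day0", "day5"), seed = 1) {
  correlation <- match.arg(correlation)
  stopifnot(n_responders <= n_features, effect_size >= 0, noise_sd > 0,
            length(class_names) == 2)
  n <- 2 * n_per_class
  feature_ids <- sprintf("F%04d", seq_len(n_features))
  sample_ids <- sprintf("S%03d", seq_len(n))
  classes <- rep(class_names, each = n_per_class)

  m <- withr::with_seed(seed, {
    if (correlation == "independent") {
      matrix(rnorm(n_features * n, sd = noise_sd), n_features, n)
    } else {
      blocks <- ceiling(seq_len(n_features) / block_size)
      latent <- matrix(rnorm(max(blocks) * n), max(blocks), n)
      sqrt(block_rho) * noise_sd * latent[blocks, , drop = FALSE] +
        sqrt(1 - block_rho) * noise_sd *
          matrix(rnorm(n_features * n), n_features, n)
    }
  })
  if (n_responders > 0) {
    m[seq_len(n_responders), classes == class_names[2]] <-
      m[seq_len(n_responders), classes == class_names[2]] +
      effect_size * noise_sd
  }
  dimnames(m) <- list(feature_ids, sample_ids)
  list(
    expression = expr_as_tibble(m),
    labels = tibble::tibble(sample_id = sample_ids, class = classes),
    truth = tibble::tibble(
      feature_id = feature_ids,
      is_responder = seq_len(n_features) <= n_responders,
      effect_size = ifelse(seq_len(n_features) <= n_responders,
                           effect_size, 0)
    )
  )
}

#' Simulate an isobaric-label peptide quantification table
#'
#' Emulates a multiplexed reporter-channel design (TMT 6-plex by default:
#' channels 1 and 6 measure a pooled reference, channels 2-5 carry
#' individual samples) at the peptide level. Peptide abundance is
#' `protein level x peptide response factor x channel bias x lognormal
#' noise`; duplicate identifications split a row's abundance in two, and
#' missing cells are injected at a stated rate — the artefacts the
#' preprocessing chain has to undo.
#'
#' @param n_proteins Number of proteins (default 40).
#' @param n_runs Number of MS runs (default 5); each run's informative
#'   channels carry distinct biological samples.
#' @param peptides_per_protein Unique peptides per protein (default 3).
#' @param n_channels Total reporter channels per run (default 6).
#' @param reference_channels Indices of the reference channels (default
#'   `c(1, 6)`).
#' @param true_ratio_sdlog Spread (sdlog) of the true protein ratios around
#'   1 across samples (default 0.25).
#' @param channel_balanced If `TRUE` (default), sample-to-channel
#'   assignment is exactly exchangeable across channels: every informative
#'   channel carries the same multiset of true ratio profiles across runs,
#'   the finite-sample counterpart of randomized channel assignment (which
#'   is what makes cross-channel quantile normalization distortion-free).
#'   `FALSE` draws ratios independently per sample.
#' @param noise_sdlog Lognormal measurement noise sdlog (default 0; set > 0
#'   for noisy tables).
#' @param channel_bias Multiplicative bias per channel, length
#'   `n_channels` (default all 1).
#' @param duplicate_rate Fraction of peptide rows identified twice
#'   (default 0).
#' @param missing_rate Fraction of abundance cells set missing (default 0).
#' @param seed Integer seed.
#' @return List with `peptides` (tibble ready for the preprocessing
#'   chain), `channel_map` (run/channel to sample-id map over the
#'   informative channels), `reference_channels` (column names), and
#'   `truth` (expression tibble of true protein ratios per sample).
#' @export
simulate_peptide_table <- function(n_proteins = 40, n_runs = 5,
                                   peptides_per_protein = 3, n_channels = 6,
                                   reference_channels = c(1, 6),
                                   true_ratio_sdlog = 0.25, noise_sdlog = 0,
                                   channel_balanced = TRUE,
                                   channel_bias = rep(1, n_channels),
                                   duplicate_rate = 0, missing_rate = 0,
                                   seed = 1) {
  stopifnot(length(channel_bias) == n_channels,
            all(reference_channels %in% seq_len(n_channels)),
            duplicate_rate >= 0, duplicate_rate < 1,
            missing_rate >= 0, missing_rate < 1)
  info_idx <- setdiff(seq_len(n_channels), reference_channels)
  chan_names <- sprintf("ch%d", seq_len(n_channels))
  run_ids <- sprintf("run%d", seq_len(n_runs))
  protein_ids <- sprintf("P%04d", seq_len(n_proteins))

  channel_map <- tidyr::expand_grid(run_id = run_ids,
                                    channel = chan_names[info_idx]) |>
    dplyr::mutate(sample_id = sprintf("S%03d", dplyr::row_number()))
  n_samples <- nrow(channel_map)

  withr::with_seed(seed, {
    # true protein ratio (vs. the pooled reference) per protein x sample
    truth_m <- if (channel_balanced) {
      # draw one ratio profile per run-slot; each channel sees all profiles,
      # in a channel-specific run order, so channel ratio distributions are
      # identical multisets by construction
      profiles <- matrix(exp(rnorm(n_proteins * n_runs,
                                   sd = true_ratio_sdlog)),
                         n_proteins, n_runs)
      cols <- matrix(NA_real_, n_proteins, n_samples)
      for (j in seq_along(info_idx)) {
        ord <- sample(n_runs)
        for (t in seq_len(n_runs)) {
          s <- which(channel_map$run_id == run_ids[t] &
                       channel_map$channel == chan_names[info_idx[j]])
          cols[, s] <- profiles[, ord[t]]
        }
      }
      dimnames(cols) <- list(protein_ids, channel_map$sample_id)
      cols
    } else {
      matrix(exp(rnorm(n_proteins * n_samples, sd = true_ratio_sdlog)),
             n_proteins, n_samples,
             dimnames = list(protein_ids, channel_map$sample_id))
    }
    # per-peptide ionization/response factor, constant across runs
    pep_factor <- exp(rnorm(n_proteins * peptides_per_protein, sd = 0.3))

    rows <- tidyr::expand_grid(run_id = run_ids, protein_id = protein_ids,
                               pep = seq_len(peptides_per_protein)) |>
      dplyr::mutate(peptide_id = sprintf("%s_pep%d", .data$protein_id,
                                         .data$pep))
    base <- 1000 * pep_factor[match(rows$peptide_id,
                                    unique(rows$peptide_id))]
    ab <- matrix(NA_real_, nrow(rows), n_channels,
                 dimnames = list(NULL, chan_names))
    run_of <- match(rows$run_id, run_ids)
    prot_of <- match(rows$protein_id, protein_ids)
    for (c in seq_len(n_channels)) {
      ratio <- if (c %in% reference_channels) {
        rep(1, nrow(rows))  # pooled reference: ratio 1 by construction
      } else {
        smp <- channel_map$sample_id[match(
          paste(rows$run_id, chan_names[c]),
          paste(channel_map$run_id, channel_map$channel))]
        truth_m[cbind(prot_of, match(smp, colnames(truth_m)))]
      }
      noise <- if (noise_sdlog > 0) {
        exp(rnorm(nrow(rows), sd = noise_sdlog))
      } else 1
      ab[, c] <- base * ratio * channel_bias[c] * noise
    }

    peptides <- dplyr::bind_cols(
      rows[c("run_id", "peptide_id", "protein_id")],
      tibble::as_tibble(ab)
    )

    if (missing_rate > 0) {
      cells <- as.matrix(peptides[chan_names])
      drop <- matrix(runif(length(cells)) < missing_rate, nrow(cells))
      cells[drop] <- NA_real_
      peptides[chan_names] <- tibble::as_tibble(cells)
    }

    if (duplicate_rate > 0) {
      n_dup <- round(duplicate_rate * nrow(peptides))
      if (n_dup > 0) {
        idx <- sample(nrow(peptides), n_dup)
        frac <- runif(n_dup, 0.2, 0.8)
        top <- peptides[idx, ]
        bottom <- peptides[idx, ]
        top[chan_names] <- top[chan_names] * frac
        bottom[chan_names] <- bottom[chan_names] * (1 - frac)
        peptides <- dplyr::bind_rows(peptides[-idx, ], top, bottom) |>
          dplyr::arrange(.data$run_id, .data$peptide_id)
      }
    }

    list(peptides = peptides, channel_map = channel_map,
         reference_channels = chan_names[reference_channels],
         truth = expr_as_tibble(truth_m))
  })
}
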