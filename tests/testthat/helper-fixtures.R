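# shared fixture builders; everything is generated in code at test time

tiny_expr <- function(values, feature_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(values)
  rownames(m) <- feature_ids %||% sprintf("F%02d", seq_len(nrow(m)))
  colnames(m) <- sample_ids %||% sprintf("S%02d", seq_len(ncol(m)))
  eriselect:::expr_as_tibble(m)
}

balanced_labels <- function(n_per_class, classes = c("day0", "day5"),
                            sample_ids = NULL) {
  n <- 2 * n_per_class
  tibble::tibble(
    sample_id = sample_ids %||% sprintf("S%02d", seq_len(n)),
    class = rep(classes, each = n_per_class)
  )
}

# hand-built accuracy store with arbitrary single/pair accuracies
fake_store <- function(single, pair) {
  ids <- names(single) %||% sprintf("F%02d", seq_along(single))
  names(single) <- ids
  dimnames(pair) <- list(ids, ids)
  diag(pair) <- NA_real_
  structure(list(feature_ids = ids, single = single, pair = pair,
                 n_pair_evals = sum(upper.tri(pair)),
                 config = cv_config()),
            class = "accuracy_store")
}

# random symmetric store with accuracies in [0, 1]
random_store <- function(n, seed) {
  withr::with_seed(seed, {
    single <- runif(n, 0.4, 0.9)
    pair <- matrix(NA_real_, n, n)
    pair[upper.tri(pair)] <- runif(n * (n - 1) / 2, 0.3, 1)
    pair[lower.tri(pair)] <- t(pair)[lower.tri(pair)]
    fake_store(single, pair)
  })
}

# two interleaved diagonal clusters: only the feature PAIR separates the
# classes, and only with a non-linear boundary
xor_data <- function(n_per_class = 20, spread = 0.15, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    centers_a <- matrix(c(1, 1, -1, -1), 2, 2, byrow = TRUE)
    centers_b <- matrix(c(1, -1, -1, 1), 2, 2, byrow = TRUE)
    pick <- function(centers) {
      idx <- sample(rep(1:2, length.out = n_per_class))
      centers[idx, ] + matrix(rnorm(n_per_class * 2, sd = spread),
                              n_per_class, 2)
    }
    X <- rbind(pick(centers_a), pick(centers_b))
    m <- t(X)
    rownames(m) <- c("Fx", "Fy")
    colnames(m) <- sprintf("S%02d", seq_len(n))
    list(expr = eriselect:::expr_as_tibble(m),
         labels = balanced_labels(n_per_class,
                                  sample_ids = colnames(m)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
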