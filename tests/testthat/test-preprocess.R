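make_peptides <- function(rows) {
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(run_id = r[[1]], peptide_id = r[[2]], protein_id = r[[3]],
                   ch1 = r[[4]], ch2 = r[[5]], ch3 = r[[6]])
  }))
}

test_that("duplicate peptide identifications merge by channel-wise sum", {
  pep <- make_peptides(list(
    list("r1", "pepA", "P1", 100, 10, NA),
    list("r1", "pepA", "P1", 150, NA, NA),
    list("r2", "pepA", "P1", 7, 8, 9)      # other run: untouched
  ))
  merged <- merge_duplicate_peptides(pep)
  expect_equal(nrow(merged), 2)
  r1 <- merged[merged$run_id == "r1", ]
  expect_equal(r1$ch1, 250)        # abundances added
  expect_equal(r1$ch2, 10)         # missing in one row only
  expect_true(is.na(r1$ch3))       # missing in all merged rows

  # duplicate-free table is unchanged (up to grouping order)
  nodup <- make_peptides(list(list("r1", "a", "P1", 1, 2, 3),
                              list("r1", "b", "P1", 4, 5, 6)))
  expect_equal(merge_duplicate_peptides(nodup), nodup)
})

test_that("merging matches a brute-force group-by-sum oracle", {
  withr::with_seed(21, {
    n <- 200
    pep <- tibble::tibble(
      run_id = sample(c("r1", "r2"), n, TRUE),
      peptide_id = sample(sprintf("pep%02d", 1:30), n, TRUE),
      ch1 = ifelse(runif(n) < 0.2, NA, runif(n, 1, 100)),
      ch2 = runif(n, 1, 100)
    )
    pep$protein_id <- sub("pep", "P", pep$peptide_id)
  })
  pep <- pep[c("run_id", "peptide_id", "protein_id", "ch1", "ch2")]
  merged <- merge_duplicate_peptides(pep)
  key <- paste(pep$run_id, pep$peptide_id)
  for (ch in c("ch1", "ch2")) {
    oracle <- tapply(pep[[ch]], key,
                     function(x) if (all(is.na(x))) NA_real_
                                 else sum(x, na.rm = TRUE))
    oracle <- stats::setNames(as.vector(oracle), names(oracle))
    got <- stats::setNames(merged[[ch]],
                           paste(merged$run_id, merged$peptide_id))
    expect_equal(got[names(oracle)], oracle)
  }
  expect_equal(nrow(merged), length(unique(key)))
})

test_that("reference normalization divides by the mean of present references", {
  pep <- make_peptides(list(list("r1", "a", "P1", 100, 300, 200),
                            list("r1", "b", "P2", 100, NA, 50),
                            list("r1", "c", "P3", NA, NA, 7)))
  rat <- reference_normalize(pep, c("ch1", "ch2"))
  expect_equal(rat$ch3, c(1.0, 0.5))       # 200/mean(100,300); 50/100
  expect_equal(nrow(rat), 2)               # all-reference-missing row dropped
  expect_equal(attr(rat, "n_dropped"), 1)

  zero <- make_peptides(list(list("r1", "a", "P1", 0, 0, 5)))
  expect_warning(out <- reference_normalize(zero, c("ch1", "ch2")),
                 "zero reference")
  expect_equal(nrow(out), 0)
})

test_that("reference normalization matches a row-wise oracle on random tables", {
  withr::with_seed(31, {
    n <- 120
    pep <- tibble::tibble(
      run_id = "r1", peptide_id = sprintf("pep%03d", 1:n),
      protein_id = "P1",
      ch1 = ifelse(runif(n) < 0.3, NA, runif(n, 1, 10)),
      ch2 = ifelse(runif(n) < 0.3, NA, runif(n, 1, 10)),
      ch3 = runif(n, 1, 10), ch4 = ifelse(runif(n) < 0.2, NA, runif(n, 1, 10))
    )
  })
  rat <- reference_normalize(pep, c("ch1", "ch2"))
  ref_mean <- apply(cbind(pep$ch1, pep$ch2), 1,
                    function(r) if (all(is.na(r))) NA else mean(r, na.rm = TRUE))
  keep <- !is.na(ref_mean)
  expect_equal(rat$ch3, (pep$ch3 / ref_mean)[keep])
  expect_equal(rat$ch4, (pep$ch4 / ref_mean)[keep])
  expect_equal(attr(rat, "n_dropped"), sum(!keep))
})

test_that("quantile normalization equalizes column distributions", {
  # hand-computed rank-mean oracle
  expect_equal(quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6))),
               cbind(a = c(2.5, 3.5, 4.5), b = c(2.5, 3.5, 4.5)))
  # identical columns are a fixed point
  m <- cbind(x = c(3, 1, 2), y = c(3, 1, 2))
  expect_equal(quantile_normalize(m), m)
  # definitional invariant + idempotence on a random complete matrix
  withr::with_seed(41, q <- matrix(rexp(400), 100, 4))
  qn <- quantile_normalize(q)
  for (j in 2:4) expect_equal(sort(qn[, j]), sort(qn[, 1]))
  expect_equal(quantile_normalize(qn), qn)
  # rank order within each column is preserved
  for (j in 1:4) expect_equal(order(qn[, j]), order(q[, j]))
  expect_error(quantile_normalize(cbind(c(1, NA, NA), c(1, 2, 3))),
               "fewer than 2")
})

test_that("protein rollup takes the median over unique peptide ratios", {
  rat <- tibble::tibble(
    run_id = "r1",
    peptide_id = c("a", "b", "c", "d"),
    protein_id = c("P1", "P1", "P1", "P2"),
    ch2 = c(0.8, 1.0, 1.4, 2.0),
    ch3 = c(NA, NA, NA, 0.7)
  )
  map <- tibble::tibble(run_id = "r1", channel = c("ch2", "ch3"),
                        sample_id = c("m1", "m2"))
  expr <- rollup_proteins(rat, map)
  expect_equal(expr$m1[expr$feature_id == "P1"], 1.0)   # median{0.8,1,1.4}
  expect_equal(expr$m1[expr$feature_id == "P2"], 2.0)   # single peptide
  expect_true(is.na(expr$m2[expr$feature_id == "P1"]))  # nothing quantified

  bad_map <- dplyr::bind_rows(map, map[1, ])
  expect_error(rollup_proteins(rat, bad_map), "one-to-one")
})

test_that("rollup matches a group-by-median oracle on random tables", {
  withr::with_seed(51, {
    n <- 300
    rat <- tibble::tibble(
      run_id = sample(c("r1", "r2"), n, TRUE),
      peptide_id = sprintf("pep%03d", 1:n),
      protein_id = sample(sprintf("P%02d", 1:12), n, TRUE),
      ch2 = ifelse(runif(n) < 0.2, NA, runif(n, 0.2, 3)),
      ch3 = runif(n, 0.2, 3)
    )
  })
  map <- tidyr::expand_grid(run_id = c("r1", "r2"),
                            channel = c("ch2", "ch3")) |>
    dplyr::mutate(sample_id = paste0("m", dplyr::row_number()))
  expr <- rollup_proteins(rat, map)
  for (i in seq_len(nrow(map))) {
    sub <- rat[rat$run_id == map$run_id[i], ]
    oracle <- tapply(sub[[map$channel[i]]], sub$protein_id,
                     function(x) median(x, na.rm = TRUE))
    oracle <- stats::setNames(as.vector(oracle), names(oracle))
    oracle <- oracle[!is.na(oracle)]
    got <- stats::setNames(expr[[map$sample_id[i]]], expr$feature_id)
    expect_equal(sort(names(oracle)), sort(names(got[!is.na(got)])))
    expect_equal(got[names(oracle)], oracle)
  }
})

test_that("under-observed features are dropped and imputation fills from the row", {
  withr::with_seed(61, {
    m <- matrix(runif(6 * 20), 6, 20,
                dimnames = list(sprintf("P%d", 1:6), sprintf("S%02d", 1:20)))
    m[1, 1:9] <- NA    # 11 observed -> dropped at min_observed = 12
    m[2, 1:8] <- NA    # 12 observed -> kept
    m[3, 1] <- NA
  })
  expr <- tiny_expr(m, rownames(m), colnames(m))
  out <- filter_and_impute(expr, min_observed = 12, seed = 7)
  expect_false("P1" %in% out$feature_id)
  expect_equal(attr(out, "n_dropped"), 1)
  expect_false(anyNA(out[-1]))
  # observed values never altered
  kept <- as.matrix(out[-1]); orig <- m[out$feature_id, ]
  expect_equal(kept[!is.na(orig)], orig[!is.na(orig)])
  # every imputed value is a member of the row's observed multiset
  for (i in seq_len(nrow(out))) {
    row_orig <- orig[i, ]
    expect_true(all(kept[i, is.na(row_orig)] %in% row_orig[!is.na(row_orig)]))
  }
  # bit-reproducible given the seed; complete rows unchanged
  expect_identical(out, filter_and_impute(expr, min_observed = 12, seed = 7))
  expect_false(identical(out, filter_and_impute(expr, 12, seed = 8)))
  complete <- tiny_expr(matrix(1:10, 1), "C1", sprintf("S%02d", 1:10))
  expect_equal(filter_and_impute(complete, 5, seed = 1), complete,
               ignore_attr = TRUE)
})

test_that("raising min_observed never increases surviving rows", {
  withr::with_seed(71, {
    m <- matrix(runif(200), 10, 20)
    m[sample(length(m), 60)] <- NA
    dimnames(m) <- list(sprintf("P%02d", 1:10), sprintf("S%02d", 1:20))
  })
  expr <- tiny_expr(m, rownames(m), colnames(m))
  n_kept <- vapply(1:20, function(k) nrow(filter_and_impute(expr, k, seed = 1)),
                   numeric(1))
  expect_true(all(diff(n_kept) <= 0))
})
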