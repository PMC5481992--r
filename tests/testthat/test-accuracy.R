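smo_dec <- function(X, y, Xt, kern, gamma) {
  eriselect:::smo_decision_values(X, as.integer(y), Xt, 1.0,
                                  as.integer(kern), gamma)
}

sep_fixture <- function(n_per_class = 20, gap = 10, seed = 2) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    m <- rbind(
      sep = c(rnorm(n_per_class), rnorm(n_per_class) + gap),
      flat = rep(1, n),
      noise = rnorm(n)
    )
    colnames(m) <- sprintf("S%02d", seq_len(n))
  })
  list(expr = eriselect:::expr_as_tibble(m),
       labels = balanced_labels(n_per_class, sample_ids = colnames(m)))
}

test_that("a widely separated feature classifies perfectly", {
  fx <- sep_fixture()
  plan <- make_fold_plan(fx$labels, cv_config(seed = 2))
  est <- estimate_accuracy(fx$expr, fx$labels, "sep", plan, cv_config(seed = 2))
  expect_equal(est$mean_accuracy, 1.0)
  expect_equal(est$per_repeat, rep(1, 5))
})

test_that("a constant feature on balanced classes gives exactly chance accuracy", {
  fx <- sep_fixture()
  cfg <- cv_config(seed = 9)
  plan <- make_fold_plan(fx$labels, cfg)
  est <- estimate_accuracy(fx$expr, fx$labels, "flat", plan, cfg)
  # majority fallback, tie -> first class: half the test fold is correct
  expect_equal(est$mean_accuracy, 0.5)
  again <- estimate_accuracy(fx$expr, fx$labels, "flat", plan, cfg)
  expect_identical(est, again)
})

test_that("accuracies are within [0,1] and deterministic given the seed", {
  withr::with_seed(8, {
    m <- matrix(rnorm(6 * 30), 6, 30,
                dimnames = list(sprintf("F%d", 1:6), sprintf("S%02d", 1:30)))
  })
  expr <- eriselect:::expr_as_tibble(m)
  lab <- balanced_labels(15, sample_ids = colnames(m))
  cfg <- cv_config(seed = 5)
  plan <- make_fold_plan(lab, cfg)
  a1 <- all_single_accuracies(expr, lab, plan, cfg)
  a2 <- all_single_accuracies(expr, lab, plan, cfg)
  expect_identical(a1, a2)
  expect_true(all(a1$mean_accuracy >= 0 & a1$mean_accuracy <= 1))
  expect_equal(a1$mean_accuracy,
               vapply(a1$per_repeat, mean, numeric(1)))
})

test_that("batch single accuracies match independent per-feature calls", {
  fx <- sep_fixture()
  cfg <- cv_config(seed = 4)
  plan <- make_fold_plan(fx$labels, cfg)
  batch <- all_single_accuracies(fx$expr, fx$labels, plan, cfg)
  for (f in batch$feature_id) {
    solo <- estimate_accuracy(fx$expr, fx$labels, f, plan, cfg)
    expect_equal(batch$mean_accuracy[batch$feature_id == f],
                 solo$mean_accuracy)
  }
  # reordering the input rows permutes the output identically
  rev_expr <- fx$expr[rev(seq_len(nrow(fx$expr))), ]
  rev_batch <- all_single_accuracies(rev_expr, fx$labels, plan, cfg)
  expect_equal(rev_batch$mean_accuracy, rev(batch$mean_accuracy))
})

test_that("the pair sweep covers each unordered pair once, symmetrically", {
  withr::with_seed(14, {
    m <- matrix(rnorm(5 * 30), 5, 30,
                dimnames = list(sprintf("F%d", 1:5), sprintf("S%02d", 1:30)))
  })
  expr <- eriselect:::expr_as_tibble(m)
  lab <- balanced_labels(15, sample_ids = colnames(m))
  cfg <- cv_config(seed = 14)
  plan <- make_fold_plan(lab, cfg)
  store <- all_pair_accuracies(expr, lab, plan, cfg)
  expect_equal(store$n_pair_evals, choose(5, 2))
  expect_true(all(is.na(diag(store$pair))))
  expect_equal(store$pair, t(store$pair))
  # matches independent two-feature estimates (brute-force oracle)
  for (i in 1:4) for (j in (i + 1):5) {
    solo <- estimate_accuracy(expr, lab, rownames(m)[c(i, j)], plan, cfg)
    expect_equal(store$pair[i, j], solo$mean_accuracy)
  }
  # N = 2 evaluates exactly one pair
  two <- all_pair_accuracies(expr[1:2, ], lab, plan, cfg)
  expect_equal(two$n_pair_evals, 1)
})

test_that("results are independent of the worker count", {
  withr::with_seed(15, {
    m <- matrix(rnorm(8 * 24), 8, 24,
                dimnames = list(sprintf("F%d", 1:8), sprintf("S%02d", 1:24)))
  })
  expr <- eriselect:::expr_as_tibble(m)
  lab <- balanced_labels(12, sample_ids = colnames(m))
  plan <- make_fold_plan(lab, cv_config(seed = 1))
  s1 <- all_pair_accuracies(expr, lab, plan, cv_config(seed = 1, workers = 1))
  s3 <- all_pair_accuracies(expr, lab, plan, cv_config(seed = 1, workers = 3))
  expect_equal(s1$pair, s3$pair)
  expect_equal(s1$single, s3$single)
})

test_that("an XOR pair needs both features and a non-linear kernel", {
  fx <- xor_data(n_per_class = 20, spread = 0.15, seed = 6)
  rbf <- cv_config(classifier = "svm_rbf", seed = 6)
  lin <- cv_config(classifier = "svm_linear", seed = 6)
  plan <- make_fold_plan(fx$labels, rbf)

  singles_rbf <- all_single_accuracies(fx$expr, fx$labels, plan, rbf)
  pair_rbf <- estimate_accuracy(fx$expr, fx$labels, c("Fx", "Fy"), plan, rbf)
  pair_lin <- estimate_accuracy(fx$expr, fx$labels, c("Fx", "Fy"), plan, lin)

  expect_gt(pair_rbf$mean_accuracy, max(singles_rbf$mean_accuracy) + 0.3)
  expect_lt(abs(pair_lin$mean_accuracy - 0.5), 0.2)
})

test_that("the compiled SVM agrees with an independent implementation", {
  library(e1071)
  withr::with_seed(33, {
    for (case in 1:6) {
      p <- sample(1:2, 1)
      kern <- sample(0:1, 1)
      X <- matrix(rnorm(30 * p), 30, p)
      y <- rep(0:1, 15)
      X[y == 1, 1] <- X[y == 1, 1] + runif(1, 0.5, 2)
      Xt <- matrix(rnorm(12 * p), 12, p)
      ours <- smo_dec(X, y, Xt, kern, 1 / p)
      ref <- e1071::svm(X, factor(y, levels = c(0, 1)),
                        kernel = if (kern == 0) "linear" else "radial",
                        cost = 1, gamma = 1 / p, scale = FALSE)
      theirs <- unname(attr(predict(ref, Xt, decision.values = TRUE),
                            "decision.values")[, 1])
      # identical predicted labels, closely matching decision values
      expect_equal(sign(ours), sign(theirs))
      expect_lt(max(abs(ours - theirs)), 0.05)
    }
  })
})

test_that("under permuted labels single-feature accuracy concentrates at chance", {
  sim <- simulate_expression(n_features = 100, n_per_class = 20,
                             n_responders = 0, seed = 17)
  cfg <- cv_config(seed = 17)
  plan <- make_fold_plan(sim$labels, cfg)
  acc <- all_single_accuracies(sim$expression, sim$labels, plan, cfg)
  expect_lt(abs(mean(acc$mean_accuracy) - 0.5), 0.05)
})

test_that("the naive Bayes plug-in runs and separates an obvious feature", {
  fx <- sep_fixture(n_per_class = 10)
  cfg <- cv_config(classifier = "naive_bayes", seed = 3)
  plan <- make_fold_plan(fx$labels, cfg)
  est <- estimate_accuracy(fx$expr, fx$labels, "sep", plan, cfg)
  expect_equal(est$mean_accuracy, 1.0)
  # degenerate constant feature must not error
  flat <- estimate_accuracy(fx$expr, fx$labels, "flat", plan, cfg)
  expect_equal(flat$mean_accuracy, 0.5)
})
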