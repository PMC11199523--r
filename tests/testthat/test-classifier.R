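# fixed two-class feature fixture: `informative` separates the classes,
# the rest is noise; one duplicated column probes collinearity handling
make_fixture <- function(n_per_class = 30, margin = 3, seed = 101,
                         label_noise = 0) {
  set.seed(seed)
  n <- 2 * n_per_class
  grp <- rep(c("patient", "control"), each = n_per_class)
  informative <- rnorm(n) + ifelse(grp == "patient", margin, 0)
  tbl <- tibble::tibble(
    subject = sprintf("s%03d", 1:n),
    group = grp,
    informative = informative,
    informative_copy = informative,
    noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n),
    noise4 = rnorm(n), noise5 = rnorm(n)
  )
  if (label_noise > 0) {
    flip <- sample(n, round(label_noise * n))
    tbl$group[flip] <- ifelse(tbl$group[flip] == "patient", "control", "patient")
  }
  tbl
}

test_that("ROC/AUC handles perfect, inverted and tied rankings", {
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0), positive = 1)
  expect_equal(r$auc, 1.0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c(0, 0, 1, 1), positive = 1)$auc, 0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5), positive = 1)$auc, 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "two classes")
  # curve is monotone from (0,0) to (1,1)
  set.seed(51)
  r2 <- roc_auc(rnorm(50), rep(c("a", "b"), 25), positive = "b")
  expect_false(is.unsorted(r2$curve$fpr))
  expect_false(is.unsorted(r2$curve$tpr))
  expect_equal(tail(r2$curve$fpr, 1), 1)
  expect_equal(tail(r2$curve$tpr, 1), 1)
})

test_that("AUC equals the pairwise Mann-Whitney probability and pROC agrees", {
  set.seed(53)
  for (i in 1:10) {
    n <- sample(10:1000, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    labels <- sample(c("neg", "pos"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels, positive = "pos")
    pos <- scores[labels == "pos"]
    neg <- scores[labels == "neg"]
    pairwise <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(r$auc, pairwise, tolerance = 1e-12)
    ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores, levels = c("neg", "pos"),
                                                direction = "<")))
    expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("lasso keeps the separating feature and prunes duplicates", {
  fx <- make_fixture()
  x <- scale(as.matrix(fx[, -(1:2)]))
  y <- fx$group
  # small penalty: superset of the large-penalty selection
  sel_small <- lasso_select(x, y, 0.02)$selected
  sel_large <- lasso_select(x, y, 0.4)$selected
  expect_true(all(sel_large %in% sel_small))
  # the informative feature family is selected first along the path
  expect_true(any(grepl("^informative", sel_large)) || length(sel_large) == 0)
  expect_true(any(grepl("^informative", sel_small)))
  # at a penalty that kills all noise, only the informative family survives
  expect_true(all(grepl("^informative", sel_large)))
  # the duplicated pair shares weight: each copy carries less than a lone copy
  w_pair <- lasso_select(x, y, 0.1)$weights
  x_single <- x[, colnames(x) != "informative_copy"]
  w_single <- lasso_select(x_single, y, 0.1)$weights
  expect_lt(abs(w_pair["informative"]), abs(w_single["informative"]))
  expect_error(lasso_select(x, y, -1), "positive")
})

test_that("collinearity pruning drops one of each near-duplicate pair", {
  fx <- make_fixture()
  pruned <- prune_collinear(fx)
  expect_equal(sum(c("informative", "informative_copy") %in% names(pruned)), 1)
  expect_true(all(c("noise1", "noise5") %in% names(pruned)))
})

test_that("separable classes yield near-perfect repeated-split accuracy", {
  fx <- make_fixture(margin = 4)
  cfg <- classifier_config(lambda = c(0.05, 0.1, 0.2), n_realizations = 40,
                           seed = 11)
  rep1 <- multirealization_eval(fx, cfg)
  expect_gt(rep1$accuracy_mean, 95)
  expect_gt(rep1$auc, 0.98)
  expect_true("informative" %in% rep1$selected_features ||
                "informative_copy" %in% rep1$selected_features)
  # determinism: identical config gives identical report
  rep2 <- multirealization_eval(fx, cfg)
  expect_equal(rep1$by_lambda, rep2$by_lambda)
  expect_equal(rep1$auc, rep2$auc)
})

test_that("permuted labels fall to chance under balanced truncation", {
  fx <- make_fixture(margin = 4)
  set.seed(61)
  fx$group <- sample(fx$group)
  cfg <- classifier_config(lambda = c(0.05, 0.15), n_realizations = 60, seed = 13)
  rep_null <- multirealization_eval(fx, cfg)
  expect_lt(abs(rep_null$accuracy_mean - 50), 8)
})

test_that("accuracy degrades monotonically with label noise", {
  cfg <- classifier_config(lambda = 0.1, n_realizations = 30, seed = 17)
  accs <- vapply(c(0, 0.2, 0.4), function(p) {
    multirealization_eval(make_fixture(margin = 3, label_noise = p,
                                       seed = 300 + round(100 * p)),
                          cfg)$accuracy_mean
  }, numeric(1))
  expect_true(accs[1] > accs[2] && accs[2] > accs[3])
})
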