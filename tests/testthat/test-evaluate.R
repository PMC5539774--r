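test_that("stratified folds partition records with balanced class counts", {
  labels <- c(rep(1, 10), rep(0, 90))
  cv <- stratified_folds(labels, k = 10, seed = 4)
  expect_length(cv$folds, 10)
  for (f in cv$folds) {
    expect_equal(sum(labels[f]), 1)   # exactly one positive per fold
    expect_length(f, 10)
  }
  all_idx <- sort(unlist(cv$folds))
  expect_equal(all_idx, 1:100)                       # partition
  expect_equal(anyDuplicated(unlist(cv$folds)), 0)   # disjoint
  # determinism
  cv2 <- stratified_folds(labels, k = 10, seed = 4)
  expect_identical(cv, cv2)
  cv3 <- stratified_folds(labels, k = 10, seed = 5)
  expect_false(identical(cv$folds, cv3$folds))
  expect_error(stratified_folds(c(1, rep(0, 50)), k = 10), "fewer members")
})

test_that("per-fold positive counts are within one of perfect stratification", {
  set.seed(2)
  labels <- rbinom(333, 1, 0.23)
  cv <- stratified_folds(labels, k = 7, seed = 11)
  pos <- vapply(cv$folds, function(f) sum(labels[f]), numeric(1))
  expect_lte(max(pos) - min(pos), 1)
  sizes <- lengths(cv$folds)
  expect_lte(max(sizes) - min(sizes), 2)
})

test_that("cross-validated scores cover every record once and separate a separable fixture", {
  set.seed(14)
  y <- rbinom(300, 1, 0.3)
  tbl <- toy_table(perfect = c("n", "p")[y + 1],
                   other = sample(c("u", "v"), 300, TRUE), class = y)
  cv <- stratified_folds(y, k = 5, seed = 21)
  s <- cross_validated_scores(tbl, list(structure = "nb"), cv)
  expect_length(s, 300)
  expect_true(all(is.finite(s)))
  expect_gt(min(s[y == 1]), max(s[y == 0]))  # complete separation
  # determinism
  s2 <- cross_validated_scores(tbl, list(structure = "nb"), cv)
  expect_identical(s, s2)
})

test_that("ROC/AUC matches pair counting, an independent package, and its dual identity", {
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "single-class")
  # sensitivity and fpr non-decreasing along the curve
  set.seed(3)
  sc <- round(runif(50), 1)
  lb <- rbinom(50, 1, 0.4)
  rr <- roc_auc(sc, lb)
  expect_true(all(diff(rr$points$sensitivity) >= 0))
  expect_true(all(diff(rr$points$fpr) >= 0))
  expect_equal(rr$auc, oracle_auc(sc, lb))
  skip_if_not_installed("pROC")
  p <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                      direction = "<")))
  expect_equal(rr$auc, p, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(6)
  sc <- rnorm(80)
  lb <- rbinom(80, 1, 0.5)
  a1 <- roc_auc(sc, lb)$auc
  expect_equal(roc_auc(exp(sc), lb)$auc, a1)
  expect_equal(roc_auc(3 * sc + 7, lb)$auc, a1)
})

test_that("cutoff selection minimizes the distance to the (0, 1) corner", {
  # curve containing the perfect point -> that threshold, distance 0
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  ct <- select_cutoff(r)
  i <- which(r$points$threshold == ct)
  expect_equal(r$points$sensitivity[i], 1)
  expect_equal(r$points$fpr[i], 0)
  # two-point toy curve: hand-computed distances
  r2 <- roc_auc(c(0.7, 0.7, 0.4, 0.4, 0.4), c(1, 0, 1, 0, 0))
  # thresholds Inf/0.7/0.4/-Inf: sens 0, .5, 1, 1; fpr 0, 1/3, 1, 1
  d <- (1 - r2$points$sensitivity)^2 + r2$points$fpr^2
  expect_equal(select_cutoff(r2), r2$points$threshold[which.min(d)])
  # degenerate one-point curve (all scores equal): a threshold is returned
  r3 <- roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_true(select_cutoff(r3) %in% r3$points$threshold)
})

test_that("classification alerts strictly above the cutoff", {
  tbl <- toy_table(a = c("u", "u", "v", "v"), class = c(0, 0, 1, 1))
  m <- fit_cpts(tbl, k2_search(tbl, max_parents = 1), pseudocount = 0)
  p <- posterior(m, c(a = "v"))
  expect_equal(classify(m, c(a = "v"), cutoff = p), "no-alert")  # equality
  expect_equal(classify(m, c(a = "v"), cutoff = p - 1e-9), "alert")
  expect_equal(classify(m, character(0), cutoff = 1.0), "no-alert")
  prior <- posterior(m)
  expect_equal(classify(m, character(0), cutoff = prior / 2), "alert")
})

test_that("incremental evaluation matches the full run at full m and the prior at m = 0", {
  sp <- discrete_spec(n = 500, n_relevant = 5, seed = 61)
  tbl <- sample_dataset(sp)$table
  cv <- stratified_folds(class_labels(tbl), k = 5, seed = 3)
  spec <- list(structure = "tan")
  rk <- rank_attributes(tbl)
  rep_inc <- incremental_auc(tbl, spec, cv, rk, start_m = 0)
  expect_equal(unname(rep_inc$auc_by_m["0"]), 0.5)
  full_auc <- roc_auc(cross_validated_scores(tbl, spec, cv),
                      class_labels(tbl))$auc
  expect_identical(unname(rep_inc$auc_by_m["5"]), full_auc)  # exact
  expect_equal(names(rep_inc$auc_by_m), as.character(0:5))
  # retrain mode agrees at the endpoints too
  rep_rt <- incremental_auc(tbl, spec, cv, rk, start_m = 0, mode = "retrain")
  expect_equal(unname(rep_rt$auc_by_m["0"]), 0.5)
  expect_identical(unname(rep_rt$auc_by_m["5"]), full_auc)
  bad_rk <- rk[rk$attribute != "X01", ]
  class(bad_rk) <- class(rk)
  expect_error(incremental_auc(tbl, spec, cv, bad_rk), "missing attributes")
})
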