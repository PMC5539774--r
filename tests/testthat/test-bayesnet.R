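test_that("conditional mutual information matches the brute-force triple sum", {
  # copy channel: X = Y uniform, independent of the class -> 1 bit
  tbl <- toy_table(a = c("0", "0", "1", "1"), b = c("0", "0", "1", "1"),
                   class = c(0, 1, 0, 1))
  expect_equal(conditional_mutual_information(tbl, "a", "b"), 1.0)
  # conditional independence by exact-count construction -> 0
  g <- expand.grid(a = c("u", "v"), b = c("p", "q"), class = c(0, 1))
  tbl2 <- toy_table(a = as.character(g$a), b = as.character(g$b),
                    class = g$class)
  expect_equal(conditional_mutual_information(tbl2, "a", "b"), 0.0)
  # 8-row fixture vs direct summation oracle
  a <- c("u", "u", "v", "v", "u", "v", "v", "u")
  b <- c("p", "q", "p", "q", "q", "q", "p", "p")
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  tbl3 <- toy_table(a = a, b = b, class = y)
  n <- 8
  total <- 0
  for (av in c("u", "v")) for (bv in c("p", "q")) for (cv in c(0, 1)) {
    pabc <- sum(a == av & b == bv & y == cv) / n
    if (pabc == 0) next
    pc <- sum(y == cv) / n
    pac <- sum(a == av & y == cv) / n
    pbc <- sum(b == bv & y == cv) / n
    total <- total + pabc * log2(pabc * pc / (pac * pbc))
  }
  expect_equal(conditional_mutual_information(tbl3, "a", "b"), total)
  expect_error(conditional_mutual_information(tbl3, "a", "a"), "differ")
  expect_error(conditional_mutual_information(tbl3, "a", "class"))
})

test_that("TAN reduces to naive Bayes with one predictor and recovers a planted chain", {
  tbl1 <- toy_table(a = c("u", "v", "u", "v"), class = c(0, 1, 0, 1))
  s1 <- build_tan(tbl1)
  expect_equal(s1$parents$a, "y")
  expect_equal(s1$parents$y, character(0))

  sp <- discrete_spec(n = 2000, n_relevant = 3, seed = 17,
                      parent_effect = 0.4, class_effect = 0.05)
  tbl <- sample_dataset(sp)$table
  st <- build_tan(tbl)
  edges <- tree_edges_chr(st)
  expect_setequal(edges, c("X01|X02", "X02|X03"))
})

test_that("the TAN tree attains the maximum spanning-tree CMI total (<= 5 predictors)", {
  set.seed(9)
  for (rep in 1:6) {
    m <- sample(3:5, 1)
    n <- 120
    y <- rbinom(n, 1, 0.5)
    cols <- list()
    base <- sample(c("u", "v"), n, TRUE)
    for (j in seq_len(m)) {
      noise <- rbinom(n, 1, 0.25)
      cols[[paste0("x", j)]] <-
        ifelse(noise == 1, sample(c("u", "v"), n, TRUE), base)
    }
    cols$class <- y
    tbl <- do.call(toy_table, cols)
    preds <- predictors(tbl)
    W <- matrix(0, m, m)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      W[i, j] <- W[j, i] <-
        conditional_mutual_information(tbl, preds[i], preds[j])
    }
    st <- build_tan(tbl)
    best <- max(vapply(oracle_spanning_trees(m), function(E)
      sum(W[E]), numeric(1)))
    expect_equal(sum(st$edge_weights), best, tolerance = 1e-10)
  }
})

test_that("the K2 score matches hand-evaluated factorials and its identities", {
  tbl <- toy_table(a = c("u", "v"), class = c(0, 1))
  expect_equal(ch_score(tbl, "a"), log(1 / 6))
  # empty table scores 0
  expect_equal(ch_score(slice_table(tbl, integer(0)), "a"), 0)
  # a constant parent leaves the score unchanged
  set.seed(3)
  y <- rbinom(40, 1, 0.5)
  tbl2 <- toy_table(a = sample(c("u", "v"), 40, TRUE),
                    konst = rep("k", 40), class = y)
  expect_equal(ch_score(tbl2, "a", "y"),
               ch_score(tbl2, "a", c("y", "konst")))
})

test_that("K2 with one parent is exactly naive Bayes; extra parents respect the order", {
  sp <- discrete_spec(n = 1000, n_relevant = 2, seed = 23,
                      parent_effect = 0.4, class_effect = 0.1)
  tbl <- sample_dataset(sp)$table
  nb <- k2_search(tbl, max_parents = 1)
  for (v in predictors(tbl)) expect_equal(nb$parents[[v]], "outcome")
  # planted X02 <- X01 dependency is picked up at max_parents = 2
  k2 <- k2_search(tbl, order = c("X01", "X02"), max_parents = 2)
  expect_equal(k2$parents$X02, c("outcome", "X01"))
  # the first predictor in the order can never gain a predictor parent
  expect_equal(k2$parents$X01, "outcome")
  expect_error(k2_search(tbl, order = "X01"), "order")
})

test_that("CPT estimation applies additive smoothing over the full parent grid", {
  # counts (3,1) with pseudocount 0.5 -> (0.7, 0.3)
  tbl <- toy_table(a = c("u", "u", "u", "v", "u", "v"),
                   class = c(0, 0, 0, 0, 1, 1))
  nb <- k2_search(tbl, max_parents = 1)
  m <- fit_cpts(tbl, nb, pseudocount = 0.5)
  expect_equal(as.numeric(m$cpts$a[, "0"]), c(0.7, 0.3))
  # every probability vector sums to 1
  for (arr in m$cpts) {
    sums <- colSums(matrix(arr, nrow = dim(arr)[1]))
    expect_true(all(abs(sums - 1) < 1e-12))
  }
  # unobserved parent configuration -> uniform under smoothing
  tbl2 <- toy_table(a = c("u", "u", "v", "v"), b = c("p", "p", "p", "p"),
                    class = c(0, 0, 1, 1))
  tbl2$data$b <- factor(tbl2$data$b, levels = c("p", "q"))
  st <- bn_structure(c("y", "a", "b"), "y",
                     list(y = character(0), a = c("y", "b"), b = "y"))
  m2 <- fit_cpts(tbl2, st, pseudocount = 0.5)
  expect_equal(as.numeric(m2$cpts$a[, "1", "q"]), c(0.5, 0.5))
  # pseudocount 0: exact empirical frequencies, error on unobserved use
  m0 <- fit_cpts(tbl2, st, pseudocount = 0)
  expect_equal(as.numeric(m0$cpts$a[, "0", "p"]), c(1, 0))
  expect_true(anyNA(m0$cpts$a[, , "q"]))
  expect_error(fit_cpts(tbl, nb, pseudocount = -1))
})

test_that("model json serialization round-trips probabilities bit exact", {
  sp <- discrete_spec(n = 300, n_relevant = 3, seed = 2)
  tbl <- sample_dataset(sp)$table
  model <- fit_cpts(tbl, build_tan(tbl))
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(model, path)
  model2 <- model_from_json(path)
  expect_identical(model2$structure$parents, model$structure$parents)
  for (v in names(model$cpts)) {
    expect_identical(as.numeric(model2$cpts[[v]]),
                     as.numeric(model$cpts[[v]]))
  }
  # and the restored model scores identically
  s1 <- posterior_scores(model, tbl)
  s2 <- posterior_scores(model2, tbl)
  expect_identical(s1, s2)
})
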