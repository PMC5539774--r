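test_that("gain ratio matches brute-force entropy arithmetic", {
  # perfect predictor, balanced classes
  tbl <- toy_table(a = c("u", "u", "v", "v"), class = c(0, 0, 1, 1))
  e <- gain_ratio(tbl, "a")
  expect_equal(e$gain, 1)
  expect_equal(e$split_info, 1)
  expect_equal(e$gain_ratio, 1)
  # exact independence
  tbl2 <- toy_table(a = rep(c("u", "v"), each = 4),
                    class = rep(c(0, 1), 4))
  expect_equal(gain_ratio(tbl2, "a")$gain_ratio, 0)
  # 8-row worked table
  a <- c("u", "u", "u", "v", "v", "v", "w", "w")
  y <- c(1, 1, 0, 0, 0, 1, 0, 0)
  tbl3 <- toy_table(a = a, class = y)
  h_t <- oracle_entropy(as.numeric(table(y)))
  cond <- 3 / 8 * oracle_entropy(c(1, 2)) + 3 / 8 * oracle_entropy(c(2, 1)) +
    2 / 8 * oracle_entropy(c(2, 0))
  split <- oracle_entropy(c(3, 3, 2))
  e3 <- gain_ratio(tbl3, "a")
  expect_equal(e3$gain, h_t - cond)
  expect_equal(e3$split_info, split)
  expect_equal(e3$gain_ratio, (h_t - cond) / split)
  expect_error(gain_ratio(tbl3, "class"))
})

test_that("gain ratio is invariant under relabelling and row permutation", {
  set.seed(5)
  a <- sample(c("u", "v", "w"), 40, replace = TRUE)
  y <- rbinom(40, 1, ifelse(a == "u", 0.8, 0.2))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  tbl <- toy_table(a = a, class = y)
  perm <- sample(40)
  tblp <- toy_table(a = a[perm], class = y[perm])
  tblr <- toy_table(a = chartr("uvw", "pqr", a), class = y)
  expect_equal(gain_ratio(tblp, "a")$gain_ratio,
               gain_ratio(tbl, "a")$gain_ratio)
  expect_equal(gain_ratio(tblr, "a")$gain_ratio,
               gain_ratio(tbl, "a")$gain_ratio)
})

test_that("ranking sorts descending with alphabetical tie-break and alpha = max/2", {
  set.seed(8)
  y <- rep(c(0, 1), each = 10)
  tbl <- toy_table(
    strong = ifelse(y == 1, "a", "b"),
    weak = c(rep("a", 6), rep("b", 4), rep("b", 8), rep("a", 2)),
    # two exact copies -> tied gain ratios
    tie_b = ifelse(y == 1, "x", "z"),
    tie_a = ifelse(y == 1, "x", "z"),
    class = y)
  rk <- rank_attributes(tbl)
  expect_equal(attr(rk, "alpha"), max(rk$gain_ratio) / 2)
  expect_true(all(diff(rk$gain_ratio) <= 0))
  tied <- rk$attribute[rk$gain_ratio == 1]
  expect_equal(tied, sort(tied))  # alphabetical among ties
  # adding a constant attribute changes no other entry
  tbl2 <- tbl
  tbl2$data$const <- factor(rep("k", 20))
  tbl2$kind <- c(tbl$kind, const = "discrete")
  rk2 <- rank_attributes(tbl2)
  expect_equal(rk2[rk2$attribute != "const", ], rk,
               ignore_attr = TRUE)
  expect_equal(rk2$gain_ratio[rk2$attribute == "const"], 0)
})

test_that("the half-maximum filter eliminates strictly-below-alpha attributes", {
  rk <- data.frame(attribute = c("a", "b", "c"),
                   gain = c(0.8, 0.5, 0.3), split_info = 1,
                   gain_ratio = c(0.8, 0.5, 0.3))
  attr(rk, "alpha") <- 0.4
  class(rk) <- c("attribute_ranking", "data.frame")
  expect_equal(gain_ratio_filter(rk), c("a", "b"))
  # equality is kept
  rk$gain_ratio <- c(0.8, 0.4, 0.3)
  expect_equal(gain_ratio_filter(rk), c("a", "b"))
  # all equal -> all kept; singleton -> kept
  rk2 <- rk; rk2$gain_ratio <- rep(0.6, 3); attr(rk2, "alpha") <- 0.3
  expect_equal(gain_ratio_filter(rk2), c("a", "b", "c"))
  # superset-monotone in alpha: lowering alpha never removes a kept attribute
  for (alpha in c(0.9, 0.6, 0.35, 0.1)) {
    hi <- rk; attr(hi, "alpha") <- alpha
    lo <- rk; attr(lo, "alpha") <- alpha / 2
    expect_true(all(gain_ratio_filter(hi) %in% gain_ratio_filter(lo)))
  }
})

test_that("cfs merit follows the formula and its k = 1 reduction", {
  y <- rep(c(0, 1), each = 4)
  tbl <- toy_table(a = ifelse(y == 1, "p", "q"),
                   b = ifelse(y == 1, "p", "q"),
                   c = c("p", "q", "p", "q", "p", "q", "p", "q"),
                   class = y)
  m1 <- cfs_merit(tbl, "a")
  expect_equal(m1$merit, symmetrical_uncertainty(tbl$data$a, tbl$data$y))
  # two copies of the class: r_zi = r_ii = 1 -> merit = 2/sqrt(4) = 1
  m2 <- cfs_merit(tbl, c("a", "b"))
  expect_equal(m2$merit, 1.0)
  # 3-attribute subset against an SU-matrix oracle
  m3 <- cfs_merit(tbl, c("a", "b", "c"))
  su <- function(u, v) symmetrical_uncertainty(tbl$data[[u]], tbl$data[[v]])
  rzi <- mean(c(su("a", "y"), su("b", "y"), su("c", "y")))
  rii <- mean(c(su("a", "b"), su("a", "c"), su("b", "c")))
  expect_equal(m3$merit, 3 * rzi / sqrt(3 + 3 * 2 * rii))
  expect_error(cfs_merit(tbl, character(0)), "empty")
})

test_that("cfs_select attains the exhaustive-enumeration maximum", {
  set.seed(21)
  y <- rbinom(300, 1, 0.4)
  flip <- function(p) ifelse(rbinom(300, 1, p) == 1, 1 - y, y)
  tbl <- toy_table(
    info1 = c("a", "b")[flip(0.1) + 1],
    info2 = c("a", "b")[flip(0.2) + 1],
    noise1 = sample(c("a", "b"), 300, TRUE),
    noise2 = sample(c("a", "b", "c"), 300, TRUE),
    noise3 = sample(c("a", "b"), 300, TRUE),
    class = y)
  sel <- cfs_select(tbl)
  preds <- predictors(tbl)
  all_subsets <- unlist(lapply(seq_along(preds), function(k)
    utils::combn(preds, k, simplify = FALSE)), recursive = FALSE)
  merits <- vapply(all_subsets, function(s) cfs_merit(tbl, s)$merit,
                   numeric(1))
  expect_equal(attr(sel, "merit"), max(merits))
  expect_true("info1" %in% sel)
  expect_false(any(c("noise1", "noise2", "noise3") %in% sel))
})

test_that("cfs_select on pure noise returns a near-zero-merit subset", {
  set.seed(33)
  tbl <- toy_table(n1 = sample(c("a", "b"), 400, TRUE),
                   n2 = sample(c("a", "b"), 400, TRUE),
                   class = rbinom(400, 1, 0.3))
  sel <- suppressMessages(cfs_select(tbl))
  expect_gte(length(sel), 1)
  expect_lt(attr(sel, "merit"), 0.05)
})
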