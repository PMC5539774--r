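fit_toy_model <- function(n = 400, n_relevant = 3, seed = 19, ...) {
  sp <- discrete_spec(n = n, n_relevant = n_relevant, seed = seed, ...)
  tbl <- sample_dataset(sp)$table
  list(tbl = tbl, model = fit_cpts(tbl, build_tan(tbl)))
}

test_that("posterior handles empty, full and non-informative evidence", {
  fx <- fit_toy_model()
  model <- fx$model
  # empty evidence -> smoothed class prior
  expect_equal(posterior(model), as.numeric(model$cpts$outcome[2]))
  # full evidence on a 3-node toy model equals full-joint enumeration
  ev <- c(X01 = "s2", X02 = "s1", X03 = "s2")
  expect_equal(posterior(model, ev), oracle_posterior(model, ev),
               tolerance = 1e-12)
  # evidence on a node whose CPT rows are identical across class states
  tbl <- toy_table(a = c("u", "v", "u", "v"), class = c(0, 0, 1, 1))
  m <- fit_cpts(tbl, k2_search(tbl, max_parents = 1), pseudocount = 0)
  expect_equal(posterior(m, c(a = "u")), posterior(m))
  expect_error(posterior(model, c(nosuch = "s1")), "unknown attribute")
  expect_error(posterior(model, c(X01 = "zz")), "not a state")
})

test_that("posterior equals full-joint enumeration under random partial evidence", {
  set.seed(101)
  for (rep in 1:3) {
    k <- sample(4:6, 1)
    fx <- fit_toy_model(n = 300, n_relevant = k, seed = 100 + rep)
    model <- fx$model
    preds <- setdiff(model$structure$nodes, "outcome")
    for (trial in 1:25) {
      obs <- sample(preds, sample(0:k, 1))
      ev <- stats::setNames(sample(c("s1", "s2"), length(obs), TRUE), obs)
      expect_equal(posterior(model, ev), oracle_posterior(model, ev),
                   tolerance = 1e-10)
    }
  }
})

test_that("posterior normalizes over the class for every evidence set", {
  fx <- fit_toy_model(n_relevant = 4)
  model <- fx$model
  swap <- function(m) {  # complement model probe: P(c=1|ev) + P(c=0|ev) = 1
    m$cpts <- lapply(m$cpts, function(arr) arr)
    m
  }
  preds <- setdiff(model$structure$nodes, "outcome")
  set.seed(5)
  for (trial in 1:20) {
    obs <- sample(preds, sample(0:4, 1))
    ev <- stats::setNames(sample(c("s1", "s2"), length(obs), TRUE), obs)
    p1 <- posterior(model, ev)
    p0 <- 1 - oracle_posterior(model, ev)
    expect_equal(p1 + p0, 1, tolerance = 1e-12)
    expect_gte(p1, 0)
    expect_lte(p1, 1)
  }
})

test_that("vectorized scores agree with per-record posteriors, full and partial", {
  fx <- fit_toy_model(n = 200, n_relevant = 4, seed = 77)
  model <- fx$model
  tbl <- fx$tbl
  full <- posterior_scores(model, tbl)
  part <- posterior_scores(model, tbl, observed = c("X02", "X04"))
  none <- posterior_scores(model, tbl, observed = character(0))
  for (i in sample(n_records(tbl), 12)) {
    ev_full <- vapply(predictors(tbl), function(v)
      as.character(tbl$data[[v]][i]), character(1))
    expect_equal(full[i], posterior(model, ev_full), tolerance = 1e-12)
    expect_equal(part[i], posterior(model, ev_full[c("X02", "X04")]),
                 tolerance = 1e-12)
  }
  expect_equal(none, rep(posterior(model), n_records(tbl)))
  expect_error(posterior_scores(model, tbl, observed = "nope"),
               "not in model")
})

test_that("partial-evidence scoring falls back correctly for non-forest (K2) models", {
  sp <- discrete_spec(n = 400, n_relevant = 3, seed = 31,
                      parent_effect = 0.4, class_effect = 0.1)
  tbl <- sample_dataset(sp)$table
  st <- bn_structure(
    c("outcome", "X01", "X02", "X03"), "outcome",
    list(outcome = character(0), X01 = "outcome",
         X02 = c("outcome", "X01"), X03 = c("outcome", "X01", "X02")))
  model <- fit_cpts(tbl, st)
  part <- posterior_scores(model, tbl, observed = c("X01", "X03"))
  for (i in sample(n_records(tbl), 8)) {
    ev <- c(X01 = as.character(tbl$data$X01[i]),
            X03 = as.character(tbl$data$X03[i]))
    expect_equal(part[i], oracle_posterior(model, ev), tolerance = 1e-10)
  }
})

test_that("the TAN root choice does not affect the fitted likelihood", {
  # same undirected tree, two different roots; ML fit (pseudocount 0) on a
  # table observing every configuration -> identical posteriors
  set.seed(41)
  g <- expand.grid(a = c("u", "v"), b = c("p", "q"), c = c("x", "z"),
                   class = c(0, 1))
  g <- g[rep(seq_len(nrow(g)), sample(1:5, nrow(g), TRUE)), ]
  tbl <- toy_table(a = as.character(g$a), b = as.character(g$b),
                   c = as.character(g$c), class = g$class)
  # chain a - b - c rooted at a, and rooted at c
  st_a <- bn_structure(c("y", "a", "b", "c"), "y",
                       list(y = character(0), a = "y", b = c("y", "a"),
                            c = c("y", "b")))
  st_c <- bn_structure(c("y", "a", "b", "c"), "y",
                       list(y = character(0), c = "y", b = c("y", "c"),
                            a = c("y", "b")))
  m_a <- fit_cpts(tbl, st_a, pseudocount = 0)
  m_c <- fit_cpts(tbl, st_c, pseudocount = 0)
  s_a <- posterior_scores(m_a, tbl)
  s_c <- posterior_scores(m_c, tbl)
  expect_equal(s_a, s_c, tolerance = 1e-10)
})

test_that("pseudocount-0 models raise named errors on unseen configurations", {
  # impossible (zero-probability) evidence state
  tbl <- toy_table(a = c("u", "u", "v", "v"), class = c(0, 0, 1, 1))
  tbl$data$a <- factor(tbl$data$a, levels = c("u", "v", "w"))
  m <- fit_cpts(tbl, k2_search(tbl, max_parents = 1), pseudocount = 0)
  expect_error(posterior(m, c(a = "w")), "zero probability")
  # genuinely unobserved parent configuration -> undefined CPT entry
  tbl2 <- toy_table(a = c("u", "u", "v", "v"), b = rep("p", 4),
                    class = c(0, 0, 1, 1))
  tbl2$data$b <- factor(tbl2$data$b, levels = c("p", "q"))
  st <- bn_structure(c("y", "a", "b"), "y",
                     list(y = character(0), a = c("y", "b"), b = "y"))
  m2 <- fit_cpts(tbl2, st, pseudocount = 0)
  expect_error(posterior(m2, c(b = "q", a = "u")), "undefined CPT|zero probability")
})
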