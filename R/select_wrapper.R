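#' Search configuration for wrapper selection
#'
#' Bundles the knobs of the two subset-search strategies. The stale limit of
#' 5, population of 20 and generation count of 20 are the study defaults;
#' genetic operator rates are conventional values (single-point crossover
#' with probability 0.6, per-bit mutation 1/#attributes) and configurable.
#'
#' @param method `"bestfirst"` or `"genetic"`.
#' @param stale_limit consecutive non-improving best-first expansions before
#'   stopping (>= 1; may be `Inf` for exhaustive search).
#' @param population genetic population size (>= 2).
#' @param generations number of genetic generations.
#' @param crossover_prob probability of single-point crossover per pair.
#' @param mutation_prob per-bit mutation probability; `NULL` means
#'   `1/#attributes`, resolved at search time.
#' @param seed integer seed driving every random draw of the search and its
#'   cross-validation evaluator.
#' @param evaluator_structure classifier fitted inside the evaluator: `"nb"`
#'   (naive Bayes, i.e. K2 with one parent) or `"tan"`.
#' @param folds evaluator cross-validation folds.
#' @return a list of class `search_config`.
#' @export
search_config <- function(method = c("bestfirst", "genetic"), stale_limit = 5,
                          population = 20, generations = 20,
                          crossover_prob = 0.6, mutation_prob = NULL,
                          seed = 1L, evaluator_structure = c("nb", "tan"),
                          folds = 10) {
  method <- match.arg(method)
  evaluator_structure <- match.arg(evaluator_structure)
  stopifnot(stale_limit >= 1, population >= 2,
            crossover_prob >= 0 && crossover_prob <= 1,
            is.null(mutation_prob) ||
              (mutation_prob >= 0 && mutation_prob <= 1))
  structure(list(method = method, stale_limit = stale_limit,
                 population = population, generations = generations,
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob, seed = as.integer(seed),
                 evaluator_structure = evaluator_structure, folds = folds),
            class = "search_config")
}

#' Score one attribute subset by cross-validated AUC
#'
#' Projects the table onto `subset` plus the class, fits the chosen Bayesian
#' classifier structure on each training fold of the supplied stratified
#' cross-validation plan, pools the out-of-fold posteriors, and returns their
#' AUC. Deterministic given the plan; the same plan is reused for every
#' subset inside one search so scores are comparable.
#'
#' @param x a [risk_table()] whose predictors are discrete.
#' @param subset nonempty character vector of predictor names.
#' @param cv a [stratified_folds()] plan.
#' @param structure `"nb"` or `"tan"`.
#' @param pseudocount additive CPT smoothing.
#' @return a list of class `subset_score`: `subset`, `auc`, `evaluations`.
#' @export
evaluate_subset <- function(x, subset, cv, structure = c("nb", "tan"),
                            pseudocount = 0.5) {
  structure <- match.arg(structure)
  if (!length(subset)) stop("empty subset", call. = FALSE)
  enc <- encode_table(x, cols = subset)
  auc <- fast_cv_auc(enc, seq_along(subset), cv$folds, structure, pseudocount)
  out <- list(subset = subset, auc = auc, evaluations = 1L)
  class(out) <- "subset_score"
  out
}

#' @export
print.subset_score <- function(x, ...) {
  cat(sprintf("<subset_score> auc = %.4f, %d evaluation(s)\n  subset: %s\n",
              x$auc, x$evaluations, paste(x$subset, collapse = ", ")))
  invisible(x)
}

# Build a memoized subset -> AUC evaluator over a fixed CV plan.
make_cv_evaluator <- function(x, cv, structure = "nb", pseudocount = 0.5) {
  enc <- encode_table(x)
  idx_of <- stats::setNames(seq_along(enc$cols), enc$cols)
  function(subset) {
    fast_cv_auc(enc, unname(idx_of[subset]), cv$folds, structure, pseudocount)
  }
}

# Shared forward best-first engine over the subset lattice. `score_fn` maps a
# character vector of attributes to a scalar score (bigger is better);
# results are memoized so no subset is scored twice. Ties among open nodes
# break toward smaller subsets, then lexicographic order.
best_first_engine <- function(attrs, score_fn, stale_limit = 5) {
  attrs <- sort(attrs)
  memo <- new.env(parent = emptyenv())
  evaluations <- 0L
  get_score <- function(subset) {
    key <- subset_key(subset)
    if (is.null(memo[[key]])) {
      memo[[key]] <- score_fn(subset)
      evaluations <<- evaluations + 1L
    }
    memo[[key]]
  }
  open_subsets <- list(character(0))
  open_scores <- -Inf
  open_keys <- ""
  expanded <- new.env(parent = emptyenv())
  best_subset <- character(0)
  best_score <- -Inf
  stale <- 0L

  while (stale < stale_limit) {
    avail <- which(!vapply(open_keys, function(k)
      isTRUE(expanded[[paste0("k", k)]]), logical(1)))
    if (!length(avail)) break
    sizes <- lengths(open_subsets[avail])
    ord <- avail[order(-open_scores[avail], sizes, open_keys[avail])]
    i <- ord[1L]
    expanded[[paste0("k", open_keys[i])]] <- TRUE
    parent <- open_subsets[[i]]
    improved <- FALSE
    for (a in setdiff(attrs, parent)) {
      child <- sort(c(parent, a))
      key <- subset_key(child)
      if (key %in% open_keys) next
      s <- get_score(child)
      open_subsets[[length(open_subsets) + 1L]] <- child
      open_scores <- c(open_scores, s)
      open_keys <- c(open_keys, key)
      if (s > best_score) {
        best_score <- s
        best_subset <- child
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  list(subset = best_subset, score = best_score, evaluations = evaluations)
}

#' Wrapper selection by forward best-first search
#'
#' Starts from the empty set and repeatedly expands the best unexpanded
#' subset by single-attribute additions, scoring every new subset with the
#' cross-validated-AUC evaluator; the search stops after
#' `config$stale_limit` consecutive expansions that fail to improve the
#' global best, and returns the best subset ever evaluated. Evaluator results
#' are memoized, so no subset is scored twice.
#'
#' @param x a [risk_table()] with discrete predictors.
#' @param evaluator optional function `subset -> score`; by default a
#'   memoizable cross-validated AUC evaluator is built from `config` (folds,
#'   seed, classifier structure).
#' @param config a [search_config()].
#' @return a `subset_score` (best subset, its AUC/score, evaluator calls).
#' @export
best_first_search <- function(x, evaluator = NULL, config = search_config()) {
  preds <- predictors(x, drop_inert = TRUE)
  if (!length(preds)) stop("no predictors", call. = FALSE)
  if (is.null(evaluator)) {
    cv <- stratified_folds(class_labels(x), k = config$folds,
                           seed = config$seed)
    evaluator <- make_cv_evaluator(x, cv, config$evaluator_structure)
  }
  res <- best_first_engine(preds, evaluator, stale_limit = config$stale_limit)
  rb_log("select", sprintf("best-first: %d evaluations, best score %.4f",
                           res$evaluations, res$score))
  structure(list(subset = intersect(preds, res$subset), auc = res$score,
                 evaluations = res$evaluations), class = "subset_score")
}

#' Wrapper selection by genetic search
#'
#' Individuals are attribute bitmasks. The initial population draws each
#' individual's size uniformly at random; each generation applies
#' rank-proportional reproduction, single-point crossover and per-bit
#' mutation, with fitness the cross-validated AUC of the encoded subset.
#' All-zero offspring are repaired to a random singleton. The best individual
#' ever evaluated is returned. Fully reproducible given `config$seed`;
#' fitness values are memoized across generations.
#'
#' @inheritParams best_first_search
#' @return a `subset_score`.
#' @export
genetic_search <- function(x, evaluator = NULL, config = search_config(method = "genetic")) {
  preds <- sort(predictors(x, drop_inert = TRUE))
  p <- length(preds)
  if (!p) stop("no predictors", call. = FALSE)
  if (is.null(evaluator)) {
    cv <- stratified_folds(class_labels(x), k = config$folds,
                           seed = config$seed)
    evaluator <- make_cv_evaluator(x, cv, config$evaluator_structure)
  }
  mut <- if (is.null(config$mutation_prob)) 1 / p else config$mutation_prob
  memo <- new.env(parent = emptyenv())
  evaluations <- 0L
  fitness <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    if (is.null(memo[[key]])) {
      memo[[key]] <- evaluator(preds[mask])
      evaluations <<- evaluations + 1L
    }
    memo[[key]]
  }
  repair <- function(mask) {
    if (!any(mask)) {
      mask[sample.int(p, 1L)] <- TRUE
      rb_log("select", "genetic: all-zero individual repaired to a random singleton")
    }
    mask
  }

  best_mask <- NULL
  best_fit <- -Inf
  withr::with_seed(config$seed, {
    pop <- lapply(seq_len(config$population), function(i) {
      size <- sample.int(p, 1L)
      mask <- rep(FALSE, p)
      mask[sample.int(p, size)] <- TRUE
      mask
    })
    for (gen in seq_len(config$generations + 1L)) {
      fit <- vapply(pop, fitness, numeric(1))
      gi <- which.max(fit)
      if (fit[gi] > best_fit) {
        best_fit <- fit[gi]
        best_mask <- pop[[gi]]
      }
      if (gen > config$generations) break
      # rank-proportional reproduction (worst rank 1 ... best rank N)
      rk <- rank(fit, ties.method = "first")
      parents_idx <- sample.int(length(pop), 2L * config$population,
                                replace = TRUE, prob = rk / sum(rk))
      newpop <- vector("list", config$population)
      for (i in seq_len(config$population)) {
        m1 <- pop[[parents_idx[2L * i - 1L]]]
        m2 <- pop[[parents_idx[2L * i]]]
        child <- m1
        if (p > 1 && stats::runif(1) < config$crossover_prob) {
          cp <- sample.int(p - 1L, 1L)
          child <- c(m1[seq_len(cp)], m2[(cp + 1L):p])
        }
        flips <- stats::runif(p) < mut
        child <- xor(child, flips)
        newpop[[i]] <- repair(child)
      }
      pop <- newpop
    }
  })
  rb_log("select", sprintf("genetic: %d evaluations, best score %.4f",
                           evaluations, best_fit))
  structure(list(subset = preds[best_mask], auc = best_fit,
                 evaluations = evaluations), class = "subset_score")
}
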