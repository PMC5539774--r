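# Synthetic-data generator: samples tabular learning bases from a planted
# TAN-structured model so that every pipeline stage (discretization,
# selection, structure learning, evaluation) is testable without external
# data.

#' Specification of a planted synthetic learning base
#'
#' The planted model is a chain-shaped TAN over binary relevant attributes:
#' the class (Bernoulli at `prevalence`) is a parent of every relevant
#' attribute, and relevant attribute `j` additionally depends on attribute
#' `j - 1`. Conditional probabilities follow
#' \eqn{P(high) = 0.5 + a\,(2\,pa - 1) + b\,(2\,c - 1)} (clipped to
#' \[0.01, 0.99\]), with `a = parent_effect`, `b = class_effect`; the chain
#' root uses `a + b` as its class effect. The last `relevant_continuous`
#' relevant attributes are emitted as Gaussians conditional on their latent
#' state (means `emission_sep` standard deviations apart, so supervised
#' discretization has a recoverable planted cut). Noise attributes are
#' independent of everything: standard normal (continuous) or uniform over
#' 2-3 states (discrete).
#'
#' The defaults mirror a clinical learning base of roughly 2,000 records and
#' 60 mixed-type predictors, 20 of them continuous, with a minority-class
#' prevalence of 0.15 — a stand-in: the prevalence of the motivating
#' real-world base is not published.
#'
#' @param n record count.
#' @param prevalence positive-class probability in (0, 1).
#' @param n_relevant number of chain (relevant) attributes, named `X01`, ...
#' @param relevant_continuous how many trailing relevant attributes are
#'   emitted as Gaussians.
#' @param n_noise number of irrelevant attributes, named `Z01`, ...
#' @param noise_continuous how many leading noise attributes are continuous.
#' @param parent_effect,class_effect dependence strengths `a`, `b` above.
#' @param root_class_effect class effect of the chain root (defaults to
#'   `parent_effect + class_effect`); setting it separately gives a balanced
#'   root while children keep strong dependencies, which keeps every parent
#'   configuration well populated in finite samples.
#' @param emission_sep,emission_sd Gaussian emission separation (in sd units)
#'   and standard deviation.
#' @param seed integer seed; the sample is byte-identical given the spec.
#' @return a list of class `synthetic_spec`, including the planted
#'   `bayes_classifier` (`$model`).
#' @export
synthetic_spec <- function(n = 2000, prevalence = 0.15, n_relevant = 8,
                           relevant_continuous = 4, n_noise = 52,
                           noise_continuous = 16, parent_effect = 0.3,
                           class_effect = 0.15, root_class_effect = NULL,
                           emission_sep = 3, emission_sd = 1, seed = 1L) {
  stopifnot(prevalence > 0, prevalence < 1, n_relevant >= 1, n_noise >= 0,
            relevant_continuous <= n_relevant, noise_continuous <= n_noise)
  rel <- sprintf("X%02d", seq_len(n_relevant))
  noi <- if (n_noise) sprintf("Z%02d", seq_len(n_noise)) else character(0)
  cls <- "outcome"

  clip <- function(p) pmin(pmax(p, 0.01), 0.99)
  a <- parent_effect
  b <- class_effect
  parents <- stats::setNames(vector("list", n_relevant + 1L), c(cls, rel))
  parents[[cls]] <- character(0)
  parents[[rel[1L]]] <- cls
  if (n_relevant > 1) {
    for (j in 2:n_relevant) parents[[rel[j]]] <- c(cls, rel[j - 1L])
  }
  struct <- bn_structure(c(cls, rel), cls, parents)

  st <- c("s1", "s2")  # s2 = "high"
  cpts <- list()
  cpts[[cls]] <- array(c(1 - prevalence, prevalence), dim = 2L,
                       dimnames = stats::setNames(list(c("0", "1")), cls))
  b_root <- if (is.null(root_class_effect)) a + b else root_class_effect
  ph_root <- clip(0.5 + b_root * (2 * c(0, 1) - 1))
  cpts[[rel[1L]]] <- array(rbind(1 - ph_root, ph_root), dim = c(2L, 2L),
                           dimnames = stats::setNames(
                             list(st, c("0", "1")), c(rel[1L], cls)))
  if (n_relevant > 1) {
    for (j in 2:n_relevant) {
      arr <- array(0, dim = c(2L, 2L, 2L),
                   dimnames = stats::setNames(list(st, c("0", "1"), st),
                                              c(rel[j], cls, rel[j - 1L])))
      for (ci in 1:2) {
        for (pi in 1:2) {
          ph <- clip(0.5 + a * (2 * (pi - 1) - 1) + b * (2 * (ci - 1) - 1))
          arr[, ci, pi] <- c(1 - ph, ph)
        }
      }
      cpts[[rel[j]]] <- arr
    }
  }
  model <- list(structure = struct, cpts = cpts,
                meta = list(n = NA_integer_, pseudocount = 0,
                            levels = c(stats::setNames(list(c("0", "1")), cls),
                                       stats::setNames(rep(list(st),
                                                           n_relevant), rel))))
  class(model) <- "bayes_classifier"

  out <- list(n = n, prevalence = prevalence, relevant = rel, noise = noi,
              class_name = cls, relevant_continuous = relevant_continuous,
              noise_continuous = noise_continuous, model = model,
              emission_sep = emission_sep, emission_sd = emission_sd,
              seed = as.integer(seed))
  class(out) <- "synthetic_spec"
  out
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> n = %d, prevalence = %.2f, %d relevant (%d continuous), %d noise (%d continuous), seed %d\n",
              x$n, x$prevalence, length(x$relevant), x$relevant_continuous,
              length(x$noise), x$noise_continuous, x$seed))
  invisible(x)
}

#' Sample a learning base from a planted model
#'
#' Draws the class, then the relevant attributes in ancestral (chain) order
#' from the planted CPTs, maps emission attributes to conditional Gaussians,
#' and appends independent noise attributes. Also returns the ground truth:
#' the planted structure, the relevant attribute set, and the closed-form
#' AUC of the Bayes-optimal posterior (computed by enumerating every latent
#' configuration of the relevant attributes, weighted by its class-
#' conditional probability).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `table` (a [risk_table()]) and `truth` (class
#'   `ground_truth`: `structure`, `relevant`, `bayes_auc`, `model`).
#' @export
sample_dataset <- function(spec) {
  n <- spec$n
  rel <- spec$relevant
  R <- length(rel)
  cls <- spec$class_name
  model <- spec$model
  for (v in model$structure$nodes) {
    arr <- model$cpts[[v]]
    sums <- colSums(matrix(arr, nrow = dim(arr)[1L]))
    if (any(abs(sums - 1) > 1e-9)) stop("invalid CPTs for node ", v,
                                        call. = FALSE)
  }
  df <- NULL
  withr::with_seed(spec$seed, {
    y <- stats::rbinom(n, 1L, spec$prevalence)
    lat <- matrix(0L, n, R)  # 0 = s1, 1 = s2
    p1 <- model$cpts[[rel[1L]]][2L, y + 1L]
    lat[, 1L] <- stats::rbinom(n, 1L, p1)
    if (R > 1) {
      for (j in 2:R) {
        pj <- model$cpts[[rel[j]]][cbind(2L, y + 1L, lat[, j - 1L] + 1L)]
        lat[, j] <- stats::rbinom(n, 1L, pj)
      }
    }
    df <- data.frame(row.names = seq_len(n))
    cont_rel <- utils::tail(rel, spec$relevant_continuous)
    for (j in seq_len(R)) {
      nm <- rel[j]
      if (nm %in% cont_rel) {
        df[[nm]] <- stats::rnorm(n, mean = lat[, j] * spec$emission_sep *
                                   spec$emission_sd, sd = spec$emission_sd)
      } else {
        df[[nm]] <- factor(c("s1", "s2")[lat[, j] + 1L],
                           levels = c("s1", "s2"))
      }
    }
    for (k in seq_along(spec$noise)) {
      nm <- spec$noise[k]
      if (k <= spec$noise_continuous) {
        df[[nm]] <- stats::rnorm(n)
      } else {
        nstates <- if (k %% 2 == 0) 3L else 2L
        df[[nm]] <- factor(sample(paste0("u", seq_len(nstates)), n,
                                  replace = TRUE),
                           levels = paste0("u", seq_len(nstates)))
      }
    }
    df[[cls]] <- y
  })
  kinds <- stats::setNames(rep("discrete", length(rel) + length(spec$noise)),
                           c(rel, spec$noise))
  kinds[utils::tail(rel, spec$relevant_continuous)] <- "continuous"
  if (spec$noise_continuous > 0) {
    kinds[spec$noise[seq_len(spec$noise_continuous)]] <- "continuous"
  }
  tbl <- risk_table(df, class_name = cls, kinds = kinds, positive = "1")
  truth <- list(structure = model$structure, relevant = rel,
                bayes_auc = planted_bayes_auc(model),
                model = model)
  class(truth) <- "ground_truth"
  rb_log("simulate", sprintf("sampled n = %d (positives %d), bayes AUC %.4f",
                             n, sum(class_labels(tbl)), truth$bayes_auc))
  list(table = tbl, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d relevant attributes, Bayes-optimal AUC = %.4f\n",
              length(x$relevant), x$bayes_auc))
  invisible(x)
}

# Closed-form AUC of the optimal posterior: enumerate all latent
# configurations of the chain, with exact class-conditional weights.
planted_bayes_auc <- function(model) {
  cls <- model$structure$class_name
  rel <- setdiff(model$structure$nodes, cls)
  R <- length(rel)
  configs <- as.matrix(expand.grid(rep(list(1:2), R)))
  lik <- matrix(0, nrow(configs), 2)  # P(config | class)
  for (ci in 1:2) {
    l <- rep(1, nrow(configs))
    l <- l * model$cpts[[rel[1L]]][cbind(configs[, 1L], ci)]
    if (R > 1) {
      for (j in 2:R) {
        l <- l * model$cpts[[rel[j]]][cbind(configs[, j], ci,
                                            configs[, j - 1L])]
      }
    }
    lik[, ci] <- l
  }
  prior <- as.numeric(model$cpts[[cls]])
  score <- prior[2L] * lik[, 2L] /
    (prior[1L] * lik[, 1L] + prior[2L] * lik[, 2L])
  weighted_auc(score, w_pos = lik[, 2L], w_neg = lik[, 1L])
}

# AUC of a score distribution given per-point positive/negative weights.
weighted_auc <- function(score, w_pos, w_neg) {
  ord <- order(score)
  score <- score[ord]
  w_pos <- w_pos[ord] / sum(w_pos)
  w_neg <- w_neg[ord] / sum(w_neg)
  grp <- match(score, unique(score))
  w1 <- tapply(w_pos, grp, sum)
  w0 <- tapply(w_neg, grp, sum)
  cum0 <- cumsum(c(0, utils::head(w0, -1)))
  sum(w1 * (cum0 + 0.5 * w0))
}

#' Fraction of planted tree edges recovered by a learned structure
#'
#' Compares the undirected predictor-predictor edges of the two structures
#' (class edges are always present in both and are not counted).
#'
#' @param learned,truth `bn_structure` objects over the same node set.
#' @return fraction in \[0, 1\] of the truth's tree edges present in
#'   `learned`; 1 when the truth has no tree edges.
#' @export
structure_recovery_rate <- function(learned, truth) {
  if (!setequal(learned$nodes, truth$nodes)) {
    stop("node-set mismatch between learned and true structures",
         call. = FALSE)
  }
  te <- tree_edges(truth)
  if (is.null(te)) return(1)
  le <- tree_edges(learned)
  lkeys <- if (is.null(le)) character(0) else apply(le, 1, paste,
                                                   collapse = "|")
  mean(apply(te, 1, paste, collapse = "|") %in% lkeys)
}
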