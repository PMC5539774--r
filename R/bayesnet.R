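#' Bayesian-network structure over class and predictors
#'
#' A `bn_structure` is an acyclic parent map. The class node never has
#' parents; in TAN form every predictor has the class plus at most one
#' predictor parent; in K2 form each predictor has the class plus up to
#' `max_parents - 1` predictor parents respecting the node order.
#'
#' @param nodes character vector of node names (class included).
#' @param class_name the class node.
#' @param parents named list: node -> ordered character vector of parents.
#' @param edge_weights optional named numeric vector of predictor-tree edge
#'   weights (conditional mutual information, bits), names `"a|b"`.
#' @return an object of class `bn_structure`.
#' @export
bn_structure <- function(nodes, class_name, parents, edge_weights = NULL) {
  stopifnot(class_name %in% nodes, all(names(parents) %in% nodes))
  if (length(parents[[class_name]])) {
    stop("class node must have no parents", call. = FALSE)
  }
  for (v in nodes) if (is.null(parents[[v]])) parents[[v]] <- character(0)
  # cycle check by repeated leaf stripping (Kahn)
  remaining <- nodes
  repeat {
    leaves <- remaining[vapply(remaining, function(v)
      !length(intersect(parents[[v]], remaining)), logical(1))]
    if (!length(leaves)) break
    remaining <- setdiff(remaining, leaves)
  }
  if (length(remaining)) stop("parent map contains a cycle", call. = FALSE)
  structure(list(nodes = nodes, class_name = class_name,
                 parents = parents[nodes], edge_weights = edge_weights),
            class = "bn_structure")
}

#' @export
print.bn_structure <- function(x, ...) {
  preds <- setdiff(x$nodes, x$class_name)
  ntree <- sum(vapply(preds, function(v)
    length(setdiff(x$parents[[v]], x$class_name)), integer(1)))
  cat(sprintf("<bn_structure> class '%s', %d predictors, %d predictor-predictor edge(s)\n",
              x$class_name, length(preds), ntree))
  for (v in preds) {
    extra <- setdiff(x$parents[[v]], x$class_name)
    if (length(extra)) cat(sprintf("  %s <- %s (+ class)\n", v,
                                   paste(extra, collapse = ", ")))
  }
  invisible(x)
}

# Undirected predictor-predictor edges of a structure, as a sorted
# two-column character matrix.
tree_edges <- function(structure) {
  preds <- setdiff(structure$nodes, structure$class_name)
  out <- NULL
  for (v in preds) {
    for (u in setdiff(structure$parents[[v]], structure$class_name)) {
      e <- sort(c(u, v))
      out <- rbind(out, e)
    }
  }
  out
}

#' Conditional mutual information between two predictors given the class
#'
#' \deqn{I(X;Y \mid C) = \sum_{x,y,c} \hat P(x,y,c)
#'   \log_2 \frac{\hat P(x,y \mid c)}{\hat P(x \mid c)\hat P(y \mid c)}}
#' with maximum-likelihood cell frequencies and \eqn{0 \log 0 = 0}. This is
#' the edge weight of the TAN predictor tree.
#'
#' @param x a [risk_table()].
#' @param a,b names of two distinct discrete predictors.
#' @return mutual information in bits (nonnegative up to rounding).
#' @export
conditional_mutual_information <- function(x, a, b) {
  if (a == b) stop("a and b must differ", call. = FALSE)
  if (a == x$class_name || b == x$class_name) {
    stop("a and b must be predictors, not the class", call. = FALSE)
  }
  enc <- encode_table(x, cols = c(a, b))
  cmi_pair(enc$X[, 1L], enc$X[, 2L], enc$y, enc$nlev[1L], enc$nlev[2L])
}

cmi_pair <- function(xa, xb, y, La, Lb) {
  cnt <- array(tabulate(xa + La * (xb - 1L) + La * Lb * y, La * Lb * 2L),
               dim = c(La, Lb, 2L))
  N <- sum(cnt)
  total <- 0
  for (c in 1:2) {
    sl <- cnt[, , c]
    nc <- sum(sl)
    if (nc == 0) next
    pa <- rowSums(sl)
    pb <- colSums(sl)
    nz <- which(sl > 0, arr.ind = TRUE)
    v <- sl[nz]
    total <- total + sum(v / N * log2(v * nc / (pa[nz[, 1]] * pb[nz[, 2]])))
  }
  max(total, 0)
}

# Maximum-weight spanning tree by Prim over a dense weight matrix, started at
# node 1; ties break toward the lexicographically smallest (i, j) pair.
# Returns parent index vector (NA for the start node) in Prim attachment
# order, i.e. the tree directed away from node 1.
prim_mst <- function(W) {
  m <- nrow(W)
  parent <- rep(NA_integer_, m)
  intree <- c(TRUE, rep(FALSE, m - 1L))
  for (step in seq_len(m - 1L)) {
    best <- c(NA_integer_, NA_integer_)
    best_w <- -Inf
    for (u in which(intree)) {
      for (v in which(!intree)) {
        w <- W[u, v]
        e <- c(min(u, v), max(u, v))
        if (w > best_w ||
            (w == best_w && (e[1] < best[1] ||
                             (e[1] == best[1] && e[2] < best[2])))) {
          best_w <- w
          best <- e
          attach_to <- u
          newnode <- v
        }
      }
    }
    parent[newnode] <- attach_to
    intree[newnode] <- TRUE
  }
  parent
}

#' Learn a TAN structure (tree-augmented naive Bayes)
#'
#' Four steps: (1) compute the conditional mutual information for every
#' predictor pair given the class; (2) build the spanning tree over
#' predictors maximizing total CMI; (3) direct the tree away from the root
#' (the first predictor in table column order); (4) add the class as a parent
#' of every predictor. With a single predictor the result is the naive Bayes
#' structure. The root choice affects only edge directions, not the
#' undirected tree or the fitted classifier's likelihood.
#'
#' @param x a [risk_table()] whose (non-inert) predictors are discrete.
#' @return a `bn_structure` with `edge_weights` recording the tree's CMI.
#' @export
build_tan <- function(x) {
  preds <- predictors(x, drop_inert = TRUE)
  if (!length(preds)) stop("no predictors", call. = FALSE)
  cls <- x$class_name
  parents <- stats::setNames(vector("list", length(preds) + 1L),
                             c(cls, preds))
  parents[[cls]] <- character(0)
  for (v in preds) parents[[v]] <- cls
  ew <- NULL
  if (length(preds) > 1L) {
    enc <- encode_table(x, cols = preds)
    m <- length(preds)
    W <- matrix(0, m, m)
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        W[i, j] <- W[j, i] <- cmi_pair(enc$X[, i], enc$X[, j], enc$y,
                                       enc$nlev[i], enc$nlev[j])
      }
    }
    par_idx <- prim_mst(W)
    ew <- numeric(0)
    for (v in which(!is.na(par_idx))) {
      u <- par_idx[v]
      parents[[preds[v]]] <- c(cls, preds[u])
      e <- sort(c(preds[u], preds[v]))
      ew[paste(e, collapse = "|")] <- W[u, v]
    }
  }
  bn_structure(c(cls, preds), cls, parents, edge_weights = ew)
}

#' Cooper-Herskovits (K2) local score of a node given a parent set
#'
#' The marginal likelihood of the node's data under a uniform Dirichlet
#' prior, in natural-log space:
#' \deqn{\sum_j \left[\ln\Gamma(r) - \ln\Gamma(N_{j} + r)
#'   + \sum_k \ln\Gamma(N_{jk} + 1)\right]}
#' where `r` is the node's state count, `j` ranges over observed parent
#' configurations, and \eqn{N_{jk}} counts records with parent configuration
#' `j` and node state `k`. An empty table scores 0; a constant parent leaves
#' the score unchanged.
#'
#' @param x a [risk_table()].
#' @param node a discrete node name (predictor or class).
#' @param parents character vector of discrete parent names (possibly empty).
#' @return log-score (scalar).
#' @export
ch_score <- function(x, node, parents = character(0)) {
  if (n_records(x) == 0L) return(0)
  enc <- encode_table(x, cols = setdiff(c(node, parents), x$class_name))
  code_of <- function(nm) {
    if (nm == x$class_name) list(code = enc$y + 1L, L = 2L)
    else list(code = enc$X[, nm], L = enc$nlev[[nm]])
  }
  nd <- code_of(node)
  r <- nd$L
  config <- rep(1L, enc$n)
  mult <- 1L
  for (pnm in parents) {
    pc <- code_of(pnm)
    config <- config + mult * (pc$code - 1L)
    mult <- mult * pc$L
  }
  cnt <- matrix(tabulate(nd$code + r * (config - 1L), r * mult),
                nrow = r, ncol = mult)
  nj <- colSums(cnt)
  obs <- nj > 0
  sum(lgamma(r) - lgamma(nj[obs] + r)) + sum(lgamma(cnt[, obs, drop = FALSE] + 1))
}

#' K2 structure search
#'
#' Greedy structure learning under a node ordering: every predictor starts
#' with the class as its (first) parent; while the parent count is below
#' `max_parents` (which counts the class), the single predecessor whose
#' addition most improves the [ch_score()] is added; the node is closed when
#' no addition improves the score. `max_parents = 1` therefore yields exactly
#' the naive Bayes structure. A node can never be the parent of a node
#' earlier in the order.
#'
#' @param x a [risk_table()] with discrete predictors.
#' @param order predictor ordering (default: table column order). Use
#'   [k2_random_order()] for a seeded random order.
#' @param max_parents total parent cap per node, counting the class (1-3
#'   typical).
#' @return a `bn_structure`.
#' @export
k2_search <- function(x, order = NULL, max_parents = 1) {
  preds <- predictors(x, drop_inert = TRUE)
  if (is.null(order)) order <- preds
  if (!setequal(order, preds)) {
    stop("order must cover exactly the (non-inert) predictors", call. = FALSE)
  }
  stopifnot(max_parents >= 1)
  cls <- x$class_name
  parents <- stats::setNames(vector("list", length(preds) + 1L),
                             c(cls, preds))
  parents[[cls]] <- character(0)
  for (i in seq_along(order)) {
    v <- order[i]
    pset <- cls
    cur <- ch_score(x, v, pset)
    while (length(pset) < max_parents) {
      cands <- setdiff(order[seq_len(i - 1L)], pset)
      if (!length(cands)) break
      sc <- vapply(cands, function(u) ch_score(x, v, c(pset, u)), numeric(1))
      best <- which.max(sc)
      if (sc[best] > cur) {
        pset <- c(pset, cands[best])
        cur <- sc[best]
      } else break
    }
    parents[[v]] <- pset
  }
  bn_structure(c(cls, preds), cls, parents)
}

#' Seeded random K2 node order
#'
#' @param x a [risk_table()].
#' @param seed integer seed.
#' @return a permutation of the (non-inert) predictors.
#' @export
k2_random_order <- function(x, seed) {
  preds <- predictors(x, drop_inert = TRUE)
  withr::with_seed(as.integer(seed), sample(preds))
}

#' Fit conditional probability tables for a structure
#'
#' For every node and every parent configuration in the full Cartesian
#' product of parent state sets,
#' \deqn{\hat P(v \mid pa) = \frac{N_{v,pa} + s}{N_{pa} + s\,|states(v)|}}
#' with additive smoothing `s = pseudocount`. Configurations unobserved in
#' the training data get the uniform distribution when `pseudocount > 0` and
#' are left undefined (`NA`, a named error on use) when `pseudocount = 0`.
#'
#' @param x a [risk_table()] with discrete predictors.
#' @param structure a `bn_structure` over the table's attributes.
#' @param pseudocount nonnegative smoothing constant (default 0.5).
#' @return an object of class `bayes_classifier`.
#' @export
fit_cpts <- function(x, structure, pseudocount = 0.5) {
  stopifnot(pseudocount >= 0)
  cls <- x$class_name
  stopifnot(structure$class_name == cls)
  levels_of <- function(nm) if (nm == cls) c("0", "1") else attr_states(x, nm)
  code_of <- function(nm) as.integer(x$data[[nm]])
  cpts <- list()
  for (v in structure$nodes) {
    pars <- structure$parents[[v]]
    lv <- levels_of(v)
    Lv <- length(lv)
    plev <- lapply(pars, levels_of)
    dims <- c(Lv, vapply(plev, length, integer(1)))
    code <- code_of(v)
    mult <- Lv
    for (k in seq_along(pars)) {
      code <- code + mult * (code_of(pars[k]) - 1L)
      mult <- mult * dims[k + 1L]
    }
    cnt <- array(tabulate(code, mult), dim = dims)
    cnt_mat <- matrix(cnt, nrow = Lv)
    nj <- colSums(cnt_mat)
    prob <- sweep(cnt_mat + pseudocount, 2, nj + pseudocount * Lv, "/")
    if (pseudocount == 0) prob[, nj == 0] <- NA_real_
    arr <- array(prob, dim = dims,
                 dimnames = c(list(lv), plev))
    names(dimnames(arr)) <- c(v, pars)
    cpts[[v]] <- arr
  }
  model <- list(structure = structure, cpts = cpts,
                meta = list(n = n_records(x), pseudocount = pseudocount,
                            levels = stats::setNames(
                              lapply(structure$nodes, levels_of),
                              structure$nodes)))
  class(model) <- "bayes_classifier"
  model
}

#' @export
print.bayes_classifier <- function(x, ...) {
  cat(sprintf("<bayes_classifier> %d nodes, fitted on n = %d (pseudocount %g)\n",
              length(x$structure$nodes), x$meta$n, x$meta$pseudocount))
  print(x$structure)
  invisible(x)
}

# ---- fast cross-validated AUC used inside wrapper searches -----------------

# enc: encode_table() result; idx: column indices of the subset; folds: list
# of test index vectors. Fits nb or tan per training fold and pools
# out-of-fold posteriors; returns their tie-corrected rank AUC.
fast_cv_auc <- function(enc, idx, folds, structure = "nb", pseudocount = 0.5) {
  idx <- sort(idx)
  n <- enc$n
  y <- enc$y
  scores <- numeric(n)
  for (te in folds) {
    tr <- setdiff(seq_len(n), te)
    scores[te] <- fast_fold_scores(enc, idx, tr, te, structure, pseudocount)
  }
  auc_rank(scores, y)
}

fast_fold_scores <- function(enc, idx, tr, te, structure, pseudocount) {
  y <- enc$y
  ytr <- y[tr]
  n1 <- sum(ytr)
  n0 <- length(ytr) - n1
  lp0 <- rep(log((n0 + pseudocount) / (length(ytr) + 2 * pseudocount)),
             length(te))
  lp1 <- rep(log((n1 + pseudocount) / (length(ytr) + 2 * pseudocount)),
             length(te))
  if (structure == "nb" || length(idx) == 1L) {
    for (j in idx) {
      L <- enc$nlev[j]
      cnt <- matrix(tabulate(enc$X[tr, j] + L * ytr, 2L * L), L, 2L)
      lpr <- log(sweep(cnt + pseudocount, 2, colSums(cnt) + pseudocount * L,
                       "/"))
      xt <- enc$X[te, j]
      lp0 <- lp0 + lpr[xt, 1L]
      lp1 <- lp1 + lpr[xt, 2L]
    }
  } else if (structure == "tan") {
    m <- length(idx)
    W <- matrix(0, m, m)
    for (a in seq_len(m - 1L)) {
      for (b in (a + 1L):m) {
        W[a, b] <- W[b, a] <- cmi_pair(enc$X[tr, idx[a]], enc$X[tr, idx[b]],
                                       ytr, enc$nlev[idx[a]],
                                       enc$nlev[idx[b]])
      }
    }
    par_idx <- prim_mst(W)
    for (v in seq_len(m)) {
      j <- idx[v]
      L <- enc$nlev[j]
      if (is.na(par_idx[v])) {
        cnt <- matrix(tabulate(enc$X[tr, j] + L * ytr, 2L * L), L, 2L)
        lpr <- log(sweep(cnt + pseudocount, 2, colSums(cnt) + pseudocount * L,
                         "/"))
        xt <- enc$X[te, j]
        lp0 <- lp0 + lpr[xt, 1L]
        lp1 <- lp1 + lpr[xt, 2L]
      } else {
        ju <- idx[par_idx[v]]
        Lu <- enc$nlev[ju]
        code <- enc$X[tr, j] + L * (enc$X[tr, ju] - 1L) + L * Lu * ytr
        cnt <- matrix(tabulate(code, 2L * L * Lu), nrow = L)
        lpr <- log(sweep(cnt + pseudocount, 2, colSums(cnt) + pseudocount * L,
                         "/"))
        cfg0 <- enc$X[te, ju]
        cfg1 <- enc$X[te, ju] + Lu
        lp0 <- lp0 + lpr[cbind(enc$X[te, j], cfg0)]
        lp1 <- lp1 + lpr[cbind(enc$X[te, j], cfg1)]
      }
    }
  } else {
    stop("unknown evaluator structure: ", structure, call. = FALSE)
  }
  stats::plogis(lp1 - lp0)
}

# Tie-corrected rank (Mann-Whitney) AUC.
auc_rank <- function(scores, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("single-class input", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
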