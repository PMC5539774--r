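# Independent reference implementations ("oracles") used to check the
# package's algorithms on small inputs. Deliberately naive: plain loops,
# direct formulas, exhaustive enumeration.

oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

# Exhaustive-recursion MDL discretization: at every level enumerate every
# boundary midpoint, score it by direct entropy arithmetic, apply the MDLPC
# inequality, recurse. Independent of the package's incremental code path.
oracle_mdl_cuts <- function(values, labels) {
  labels <- as.character(labels)
  recurse <- function(v, l) {
    ord <- order(v)
    v <- v[ord]; l <- l[ord]
    uv <- unique(v)
    if (length(uv) < 2) return(numeric(0))
    cands <- c()
    for (i in seq_len(length(uv) - 1)) {
      la <- unique(l[v == uv[i]])
      lb <- unique(l[v == uv[i + 1]])
      if (length(la) > 1 || length(lb) > 1 || la != lb) {
        cands <- c(cands, (uv[i] + uv[i + 1]) / 2)
      }
    }
    if (!length(cands)) return(numeric(0))
    n <- length(v)
    ent <- function(lab) oracle_entropy(as.numeric(table(lab)))
    gains <- sapply(cands, function(ct) {
      ent(l) - sum(v < ct) / n * ent(l[v < ct]) -
        sum(v >= ct) / n * ent(l[v >= ct])
    })
    best <- cands[which(gains > max(gains) - 1e-12)[1]]
    lo <- l[v < best]; hi <- l[v >= best]
    k  <- length(unique(l))
    k1 <- length(unique(lo)); k2 <- length(unique(hi))
    gain <- ent(l) - length(lo) / n * ent(lo) - length(hi) / n * ent(hi)
    delta <- log2(3^k - 2) - (k * ent(l) - k1 * ent(lo) - k2 * ent(hi))
    if (gain <= log2(n - 1) / n + delta / n) return(numeric(0))
    c(recurse(v[v < best], lo), best, recurse(v[v >= best], hi))
  }
  sort(recurse(values, labels))
}

# All spanning trees of the complete graph on m >= 2 labelled nodes, via
# Pruefer sequences; returns a list of 2-column edge matrices.
oracle_spanning_trees <- function(m) {
  if (m == 2) return(list(matrix(c(1, 2), ncol = 2)))
  seqs <- expand.grid(rep(list(seq_len(m)), m - 2))
  lapply(seq_len(nrow(seqs)), function(i) {
    pr <- as.integer(seqs[i, ])
    degree <- rep(1L, m)
    for (x in pr) degree[x] <- degree[x] + 1L
    edges <- matrix(0L, m - 1, 2)
    for (k in seq_along(pr)) {
      leaf <- min(which(degree == 1L))
      edges[k, ] <- c(leaf, pr[k])
      degree[leaf] <- degree[leaf] - 1L
      degree[pr[k]] <- degree[pr[k]] - 1L
    }
    edges[m - 1, ] <- which(degree == 1L)
    edges
  })
}

# Full-joint enumeration posterior for a fitted classifier (any structure).
oracle_posterior <- function(model, evidence = character(0)) {
  cls <- model$structure$class_name
  preds <- setdiff(model$structure$nodes, cls)
  levs <- model$meta$levels
  grid <- expand.grid(c(stats::setNames(lapply(preds, function(v) levs[[v]]),
                                        preds),
                        stats::setNames(list(c("0", "1")), cls)),
                      stringsAsFactors = FALSE)
  joint <- rep(1, nrow(grid))
  for (v in model$structure$nodes) {
    arr <- model$cpts[[v]]
    idx <- match(grid[[v]], levs[[v]])
    mult <- dim(arr)[1]
    for (k in seq_along(model$structure$parents[[v]])) {
      p <- model$structure$parents[[v]][k]
      idx <- idx + mult * (match(grid[[p]], levs[[p]]) - 1L)
      mult <- mult * dim(arr)[k + 1]
    }
    joint <- joint * arr[idx]
  }
  keep <- rep(TRUE, nrow(grid))
  for (nm in names(evidence)) keep <- keep & grid[[nm]] == evidence[[nm]]
  sum(joint[keep & grid[[cls]] == "1"]) / sum(joint[keep])
}

# Pairwise-count AUC: P(random positive outscores random negative), ties 0.5.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Undirected predictor-predictor edges of a structure as "a|b" strings.
tree_edges_chr <- function(st) {
  preds <- setdiff(st$nodes, st$class_name)
  out <- character(0)
  for (v in preds) {
    for (u in setdiff(st$parents[[v]], st$class_name)) {
      out <- c(out, paste(sort(c(u, v)), collapse = "|"))
    }
  }
  out
}

# ---- shared fixtures -------------------------------------------------------

# Small fully discrete table built from explicit vectors.
toy_table <- function(..., class, class_name = "y") {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df[[class_name]] <- class
  risk_table(df, class_name = class_name)
}

# A planted all-discrete dataset (no emissions) for model-level checks.
discrete_spec <- function(n, n_relevant = 4, n_noise = 0, seed = 1,
                          parent_effect = 0.3, class_effect = 0.15,
                          prevalence = 0.15) {
  synthetic_spec(n = n, prevalence = prevalence, n_relevant = n_relevant,
                 relevant_continuous = 0, n_noise = n_noise,
                 noise_continuous = 0, parent_effect = parent_effect,
                 class_effect = class_effect, seed = seed)
}
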