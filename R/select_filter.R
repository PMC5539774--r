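#' Gain ratio of one discrete predictor against the class
#'
#' Computes \eqn{Gain(T,A) = H(T) - \sum_v (n_v/n) H(T \mid A = v)},
#' \eqn{SplitInfo(T,A) = -\sum_v (n_v/n)\log_2(n_v/n)} and their ratio, where
#' `T` is the class and `A` the predictor. `SplitInfo` corrects the gain's
#' bias toward many-valued attributes. A single-state attribute has
#' `SplitInfo = 0`; its gain ratio is defined as 0 and the attribute is
#' inert for ranking purposes.
#'
#' @param x a [risk_table()].
#' @param attr name of a discrete predictor.
#' @return a one-row data frame (class `ranking_entry`) with columns
#'   `attribute`, `gain`, `split_info`, `gain_ratio`.
#' @export
gain_ratio <- function(x, attr) {
  if (attr == x$class_name) stop("attr is the class", call. = FALSE)
  if (attr_kind(x, attr) != "discrete") {
    stop("attr '", attr, "' is continuous; discretize first", call. = FALSE)
  }
  a <- x$data[[attr]]
  cl <- x$data[[x$class_name]]
  n <- length(a)
  tab <- table(a, cl)
  nv <- rowSums(tab)
  h_t <- entropy(table(cl))
  cond <- sum(vapply(seq_len(nrow(tab)), function(i) {
    if (nv[i] == 0) 0 else (nv[i] / n) * entropy(tab[i, ])
  }, numeric(1)))
  gain <- max(h_t - cond, 0)
  split_info <- entropy(nv)
  gr <- if (split_info > 0) min(max(gain / split_info, 0), 1) else 0
  out <- data.frame(attribute = attr, gain = gain, split_info = split_info,
                    gain_ratio = gr, stringsAsFactors = FALSE)
  class(out) <- c("ranking_entry", "data.frame")
  out
}

#' Rank all predictors by gain ratio
#'
#' One [gain_ratio()] entry per non-inert discrete predictor, sorted by
#' descending gain ratio (ties broken by attribute name, ascending), together
#' with the elimination threshold `alpha = max(gain_ratio) / 2`.
#'
#' @param x a [risk_table()] whose predictors are all discrete.
#' @return an object of class `attribute_ranking`: a data frame of entries
#'   with attribute `alpha`.
#' @export
rank_attributes <- function(x) {
  preds <- predictors(x, drop_inert = TRUE)
  if (!length(preds)) stop("no predictors to rank", call. = FALSE)
  entries <- do.call(rbind, lapply(preds, function(nm) gain_ratio(x, nm)))
  ord <- order(-entries$gain_ratio, entries$attribute)
  entries <- entries[ord, , drop = FALSE]
  rownames(entries) <- NULL
  attr(entries, "alpha") <- max(entries$gain_ratio) / 2
  class(entries) <- c("attribute_ranking", "data.frame")
  entries
}

#' @export
print.attribute_ranking <- function(x, ...) {
  cat(sprintf("<attribute_ranking> %d attributes, alpha = %.4f\n",
              nrow(x), attr(x, "alpha")))
  print.data.frame(cbind(x), digits = 4)
  invisible(x)
}

#' Eliminate attributes below the half-maximum gain-ratio threshold
#'
#' Keeps every attribute whose gain ratio is at least
#' `alpha = max(gain_ratio)/2`; attributes strictly below alpha are
#' eliminated (equality is kept).
#'
#' @param ranking an `attribute_ranking` from [rank_attributes()].
#' @return character vector of kept attribute names, in ranking order.
#' @export
gain_ratio_filter <- function(ranking) {
  if (!nrow(ranking)) stop("empty ranking", call. = FALSE)
  alpha <- attr(ranking, "alpha")
  ranking$attribute[ranking$gain_ratio >= alpha]
}

#' Merit of an attribute subset (correlation-based feature selection)
#'
#' Hall's CFS heuristic: a good subset contains attributes highly correlated
#' with the class yet uncorrelated with each other,
#' \deqn{merit = \frac{k\,\bar r_{zi}}{\sqrt{k + k(k-1)\bar r_{ii}}}}
#' where `k` is the subset size, \eqn{\bar r_{zi}} the mean attribute-class
#' correlation and \eqn{\bar r_{ii}} the mean attribute-attribute
#' correlation, both instantiated as [symmetrical_uncertainty()] on the
#' discretized data. For `k = 1` the merit reduces to the attribute-class
#' correlation.
#'
#' @param x a [risk_table()] with discrete predictors.
#' @param subset nonempty character vector of predictor names.
#' @return a list (class `cfs_merit`) with `subset`, `k`, `avg_class_corr`,
#'   `avg_inter_corr`, `merit`.
#' @export
cfs_merit <- function(x, subset) {
  if (!length(subset)) stop("empty subset", call. = FALSE)
  cl <- x$data[[x$class_name]]
  k <- length(subset)
  rzi <- mean(vapply(subset, function(nm)
    symmetrical_uncertainty(x$data[[nm]], cl), numeric(1)))
  rii <- 0
  if (k > 1) {
    pairs <- utils::combn(subset, 2)
    rii <- mean(apply(pairs, 2, function(p)
      symmetrical_uncertainty(x$data[[p[1]]], x$data[[p[2]]])))
  }
  denom <- sqrt(k + k * (k - 1) * rii)
  structure(list(subset = subset, k = k, avg_class_corr = rzi,
                 avg_inter_corr = rii,
                 merit = if (denom > 0) k * rzi / denom else 0),
            class = "cfs_merit")
}

#' @export
print.cfs_merit <- function(x, ...) {
  cat(sprintf("<cfs_merit> k = %d, merit = %.4f (r_zi = %.4f, r_ii = %.4f)\n",
              x$k, x$merit, x$avg_class_corr, x$avg_inter_corr))
  cat("  subset: ", paste(x$subset, collapse = ", "), "\n")
  invisible(x)
}

#' CFS subset selection by forward best-first search
#'
#' Searches the subset lattice with the shared forward best-first engine
#' (stale limit 5), scoring each candidate subset by [cfs_merit()], with
#' symmetrical-uncertainty correlations memoized across evaluations.
#'
#' @param x a [risk_table()] with discrete predictors.
#' @param stale_limit consecutive non-improving expansions before stopping.
#' @return character vector: the best subset found (attributes in table
#'   order), with attributes `merit` and `evaluations`.
#' @export
cfs_select <- function(x, stale_limit = 5) {
  preds <- predictors(x, drop_inert = TRUE)
  if (!length(preds)) stop("no discrete predictors", call. = FALSE)
  cl <- x$data[[x$class_name]]
  # memoized SU against class and pairwise
  su_class <- vapply(preds, function(nm)
    symmetrical_uncertainty(x$data[[nm]], cl), numeric(1))
  su_pair <- new.env(parent = emptyenv())
  pair_su <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "\x1f")
    if (is.null(su_pair[[key]])) {
      su_pair[[key]] <- symmetrical_uncertainty(x$data[[a]], x$data[[b]])
    }
    su_pair[[key]]
  }
  score_fn <- function(subset) {
    k <- length(subset)
    rzi <- mean(su_class[subset])
    rii <- 0
    if (k > 1) {
      pairs <- utils::combn(subset, 2)
      rii <- mean(apply(pairs, 2, function(p) pair_su(p[1], p[2])))
    }
    k * rzi / sqrt(k + k * (k - 1) * rii)
  }
  res <- best_first_engine(preds, score_fn, stale_limit = stale_limit)
  if (res$score <= 1e-8) {
    rb_log("select", "CFS: best merit is ~0; predictors look uninformative",
           level = "warn")
  }
  out <- intersect(preds, res$subset)  # table order
  attr(out, "merit") <- res$score
  attr(out, "evaluations") <- res$evaluations
  out
}
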