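#' Candidate cut points for supervised discretization
#'
#' Returns the boundary points of a continuous column with respect to the
#' class: midpoints between consecutive distinct sorted values whose label
#' sets differ. A distinct-value block containing both classes makes both of
#' its flanking midpoints candidates (boundary-point rule of the
#' Fayyad-Irani method, which guarantees no information-gain-optimal cut is
#' lost by skipping interior points).
#'
#' @param values numeric column.
#' @param labels class column (same length).
#' @return numeric vector of candidate thresholds, strictly increasing.
#' @export
candidate_cuts <- function(values, labels) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (length(values) != length(labels)) stop("length mismatch", call. = FALSE)
  ord <- order(values)
  v <- values[ord]
  l <- as.character(labels)[ord]
  uv <- unique(v)
  if (length(uv) < 2) return(numeric(0))
  # label set per distinct-value block: pure single label, or "mixed"
  block <- split(l, match(v, uv))
  pure <- vapply(block, function(s) {
    u <- unique(s)
    if (length(u) == 1L) u else NA_character_
  }, character(1))
  keep <- logical(length(uv) - 1L)
  for (i in seq_len(length(uv) - 1L)) {
    keep[i] <- is.na(pure[i]) || is.na(pure[i + 1L]) || pure[i] != pure[i + 1L]
  }
  (uv[-length(uv)][keep] + uv[-1L][keep]) / 2
}

#' Fayyad-Irani MDLPC stopping criterion
#'
#' Decides whether a candidate binary split of a set `S` of labelled values
#' into `S1`/`S2` is worth encoding. The split is accepted iff
#' \deqn{Gain > \log_2(N-1)/N + \Delta/N}
#' with \eqn{Gain = Ent(S) - (N_1/N)Ent(S_1) - (N_2/N)Ent(S_2)} and
#' \eqn{\Delta = \log_2(3^c-2) - [c\,Ent(S) - c_1 Ent(S_1) - c_2 Ent(S_2)]},
#' where \eqn{c, c_1, c_2} count the classes actually present in each set.
#'
#' @param S,S1,S2 class count vectors with `S = S1 + S2` elementwise.
#' @param N total count of `S` (defaults to `sum(S)`).
#' @return `TRUE` iff the cut is accepted.
#' @export
mdlpc_accepts <- function(S, S1, S2, N = sum(S)) {
  if (!isTRUE(all.equal(as.numeric(S), as.numeric(S1) + as.numeric(S2)))) {
    stop("inconsistent partition: S must equal S1 + S2", call. = FALSE)
  }
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  n1 <- sum(S1); n2 <- sum(S2)
  entS <- entropy(S); ent1 <- entropy(S1); ent2 <- entropy(S2)
  gain <- entS - (n1 / N) * ent1 - (n2 / N) * ent2
  c0 <- sum(S > 0); c1 <- sum(S1 > 0); c2 <- sum(S2 > 0)
  delta <- log2(3^c0 - 2) - (c0 * entS - c1 * ent1 - c2 * ent2)
  gain > log2(N - 1) / N + delta / N
}

#' MDL discretization of one continuous attribute
#'
#' Greedy top-down recursion: at each node the candidate cut maximizing the
#' class-information gain is chosen (ties break toward the smallest
#' threshold), kept iff [mdlpc_accepts()] holds, and both sides are recursed.
#' The result is deterministic given the data.
#'
#' @inheritParams candidate_cuts
#' @param attribute attribute name recorded in the result.
#' @return an object of class `cut_points`: list with `attribute`, `cuts`
#'   (strictly increasing thresholds, possibly empty) and `interval_labels`
#'   (`length(cuts) + 1` half-open interval labels).
#' @export
mdl_discretize_attribute <- function(values, labels, attribute = "x") {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  labels <- as.character(labels)
  states <- sort(unique(labels))
  cuts <- sort(mdl_recurse(values, labels, states))
  cut_points(attribute, cuts)
}

mdl_recurse <- function(values, labels, states) {
  cand <- candidate_cuts(values, labels)
  if (!length(cand)) return(numeric(0))
  cnt <- function(lab) as.numeric(table(factor(lab, levels = states)))
  S <- cnt(labels)
  entS <- entropy(S)
  n <- length(values)
  best_gain <- -Inf
  best_cut <- NA_real_
  for (ct in cand) {  # cand is increasing: first max wins -> smallest threshold
    left <- values < ct
    g <- entS - (sum(left) / n) * entropy(cnt(labels[left])) -
      (sum(!left) / n) * entropy(cnt(labels[!left]))
    if (g > best_gain + 1e-12) {
      best_gain <- g
      best_cut <- ct
    }
  }
  left <- values < best_cut
  if (!mdlpc_accepts(S, cnt(labels[left]), cnt(labels[!left]), n)) {
    return(numeric(0))
  }
  c(mdl_recurse(values[left], labels[left], states), best_cut,
    mdl_recurse(values[!left], labels[!left], states))
}

cut_points <- function(attribute, cuts) {
  stopifnot(!is.unsorted(cuts, strictly = TRUE))
  k <- length(cuts)
  lo <- c(-Inf, cuts)
  hi <- c(cuts, Inf)
  labels <- sprintf("[%g,%g)", lo, hi)
  structure(list(attribute = attribute, cuts = cuts, interval_labels = labels),
            class = "cut_points")
}

#' @export
print.cut_points <- function(x, ...) {
  cat(sprintf("<cut_points> %s: %d cut(s)%s\n", x$attribute, length(x$cuts),
              if (length(x$cuts)) paste0(" at ",
                paste(signif(x$cuts, 6), collapse = ", ")) else " (inert)"))
  invisible(x)
}

#' Learn a discretization scheme for every continuous predictor
#'
#' Applies [mdl_discretize_attribute()] to each continuous predictor of the
#' table against the class, and records each attribute's training range so
#' that out-of-range values at application time can be clamped.
#'
#' @param x a [risk_table()].
#' @return an object of class `discretization_scheme`: named list of
#'   `cut_points` covering every continuous predictor, with a `ranges`
#'   attribute.
#' @export
mdl_discretize <- function(x) {
  cont <- names(x$kind)[x$kind == "continuous"]
  cp <- lapply(cont, function(nm) {
    mdl_discretize_attribute(x$data[[nm]], class_labels(x), attribute = nm)
  })
  names(cp) <- cont
  ranges <- lapply(cont, function(nm) range(x$data[[nm]], na.rm = TRUE))
  names(ranges) <- cont
  n_inert <- sum(vapply(cp, function(p) length(p$cuts) == 0L, logical(1)))
  rb_log("discretize", sprintf("%d continuous attributes, %d inert (no cut)",
                               length(cont), n_inert))
  structure(list(cuts = cp, ranges = ranges), class = "discretization_scheme")
}

#' @export
print.discretization_scheme <- function(x, ...) {
  k <- vapply(x$cuts, function(p) length(p$cuts), integer(1))
  cat(sprintf("<discretization_scheme> %d attributes, %d inert\n",
              length(k), sum(k == 0)))
  for (p in x$cuts) print(p)
  invisible(x)
}

#' Apply a discretization scheme to a table
#'
#' Replaces each continuous predictor by a discrete attribute with
#' `length(cuts) + 1` half-open interval states `[a, b)`; a value equal to a
#' cut belongs to the upper bin. Attributes whose scheme has zero cuts become
#' single-state and are flagged inert (excluded from downstream selection and
#' structure learning). Values outside the training range fall in the terminal
#' intervals, which are unbounded, so application is total.
#'
#' @param x a [risk_table()].
#' @param scheme a `discretization_scheme` covering all continuous predictors
#'   of `x`.
#' @return a `risk_table` in which every predictor is discrete.
#' @export
apply_scheme <- function(x, scheme) {
  cont <- names(x$kind)[x$kind == "continuous"]
  missing_attrs <- setdiff(cont, names(scheme$cuts))
  if (length(missing_attrs)) {
    stop("scheme does not cover: ", paste(missing_attrs, collapse = ", "),
         call. = FALSE)
  }
  y <- x
  for (nm in cont) {
    cp <- scheme$cuts[[nm]]
    rng <- scheme$ranges[[nm]]
    vals <- x$data[[nm]]
    if (!is.null(rng) && any(vals < rng[1] | vals > rng[2], na.rm = TRUE)) {
      rb_log("discretize",
             sprintf("%s: values outside training range [%g, %g] clamped to terminal intervals",
                     nm, rng[1], rng[2]), level = "warn")
    }
    idx <- findInterval(vals, cp$cuts, left.open = FALSE) + 1L  # [a,b)
    y$data[[nm]] <- factor(cp$interval_labels[idx],
                           levels = cp$interval_labels)
    y$kind[[nm]] <- "discrete"
    if (length(cp$cuts) == 0L) y$inert <- union(y$inert, nm)
  }
  y
}
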