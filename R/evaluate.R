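#' Stratified k-fold cross-validation plan
#'
#' Shuffles each class separately under the seed and deals indices round
#' robin, so the folds partition the records and per-fold class counts are
#' within one of perfect stratification. Deterministic given the seed.
#'
#' @param labels 0/1 integer class vector.
#' @param k fold count (default 10).
#' @param seed integer seed.
#' @return an object of class `cv_plan`: list with `k`, `seed`, `folds`
#'   (list of k disjoint index vectors).
#' @export
stratified_folds <- function(labels, k = 10, seed = 1L) {
  stopifnot(k >= 2)
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab < k)) {
    stop(sprintf("class with fewer members (%d) than folds (%d)",
                 min(tab), k), call. = FALSE)
  }
  folds <- rep(list(integer(0)), k)
  withr::with_seed(as.integer(seed), {
    for (cl in c(0, 1)) {
      idx <- sample(which(labels == cl))
      assign_to <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], idx[assign_to == f])
      }
    }
  })
  folds <- lapply(folds, sort)
  out <- list(k = k, seed = as.integer(seed), folds = folds)
  class(out) <- "cv_plan"
  out
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %d folds, seed %d, sizes: %s\n", x$k, x$seed,
              paste(lengths(x$folds), collapse = ", ")))
  invisible(x)
}

#' Out-of-fold posterior scores under cross-validation
#'
#' For each fold, learns the structure (if applicable) and fits the CPTs on
#' the complement, then scores the held-out records with the posterior of
#' the positive class. Every record is scored exactly once; the pooled score
#' vector is returned in record order.
#'
#' @param x a [risk_table()] with discrete predictors.
#' @param model_spec list with elements `structure` (`"nb"`, `"tan"` or
#'   `"k2"`), `smoothing` (pseudocount, default 0.5) and, for K2,
#'   `max_parents` and optional `order`.
#' @param cv a [stratified_folds()] plan.
#' @return numeric vector of length `n_records(x)`.
#' @export
cross_validated_scores <- function(x, model_spec, cv) {
  n <- n_records(x)
  scores <- rep(NA_real_, n)
  for (f in seq_along(cv$folds)) {
    te <- cv$folds[[f]]
    tr <- setdiff(seq_len(n), te)
    res <- tryCatch({
      model <- fit_model_spec(slice_table(x, tr), model_spec)
      posterior_scores(model, slice_table(x, te))
    }, error = function(e) {
      stop(sprintf("fold %d: %s", f, conditionMessage(e)), call. = FALSE)
    })
    scores[te] <- res
  }
  stopifnot(!anyNA(scores))
  scores
}

# Fit a classifier on a training table according to a model_spec list.
fit_model_spec <- function(x, model_spec) {
  struct_kind <- model_spec$structure %||% "tan"
  smoothing <- model_spec$smoothing %||% 0.5
  structure_obj <- switch(
    struct_kind,
    nb = k2_search(x, max_parents = 1),
    k2 = k2_search(x, order = model_spec$order,
                   max_parents = model_spec$max_parents %||% 1),
    tan = build_tan(x),
    stop("unknown model structure: ", struct_kind, call. = FALSE))
  fit_cpts(x, structure_obj, pseudocount = smoothing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ROC curve and AUC
#'
#' Builds the operating points at every distinct score threshold (prediction
#' is positive when `score > threshold`, matching [classify()]), computes the
#' AUC by the trapezoidal rule, and cross-checks it against the tie-corrected
#' Mann-Whitney rank statistic; the two must agree to 1e-12 — a permanent
#' dual-computation assertion, not a test-only device.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 class vector; both classes must be present.
#' @return an object of class `roc_curve`: `points` (data frame of
#'   `threshold`, `sensitivity`, `fpr`, threshold descending), `auc`,
#'   `cutoff` (`NA` until [select_cutoff()]).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.character(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("single-class input", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(t) sum(scores > t & labels == 1) / n1,
                 numeric(1))
  fpr <- vapply(thr, function(t) sum(scores > t & labels == 0) / n0,
                numeric(1))
  auc_trap <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  auc_mw <- auc_rank(scores, labels)
  stopifnot(abs(auc_trap - auc_mw) < 1e-12)
  out <- list(points = data.frame(threshold = thr, sensitivity = sens,
                                  fpr = fpr),
              auc = auc_trap, cutoff = NA_real_)
  class(out) <- "roc_curve"
  out
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f%s\n", nrow(x$points), x$auc,
              if (!is.na(x$cutoff)) sprintf(", cutoff = %.4f", x$cutoff)
              else ""))
  invisible(x)
}

#' Select the operating cutoff nearest the ideal corner
#'
#' Returns the threshold of the ROC point minimizing
#' \eqn{(1-sensitivity)^2 + (1-specificity)^2}, the squared distance to the
#' perfect-classification corner (sensitivity 1, specificity 1). Ties break
#' toward the smaller (more sensitive) threshold.
#'
#' @param roc a [roc_auc()] curve.
#' @return the selected threshold (scalar).
#' @export
select_cutoff <- function(roc) {
  pts <- roc$points
  if (!nrow(pts)) stop("empty ROC curve", call. = FALSE)
  d <- (1 - pts$sensitivity)^2 + pts$fpr^2
  cand <- which(d == min(d))
  pts$threshold[cand[which.min(pts$threshold[cand])]]
}

#' Alert decision at a cutoff
#'
#' Raises an alert iff the posterior probability of the positive class
#' strictly exceeds the cutoff; a posterior exactly equal to the cutoff does
#' not alert.
#'
#' @param model a [fit_cpts()] classifier.
#' @param evidence named evidence as in [posterior()].
#' @param cutoff decision threshold in \[0, 1\].
#' @return `"alert"` or `"no-alert"`.
#' @export
classify <- function(model, evidence, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  if (posterior(model, evidence) > cutoff) "alert" else "no-alert"
}

#' Incremental-observation evaluation in ranking order
#'
#' Emulates observing attributes one at a time in descending gain-ratio
#' order on a deployed model: per fold, the classifier is fitted on all
#' predictors; held-out records are then scored with evidence restricted to
#' the top-`m` attributes of the ranking (the rest marginalized), for each
#' `m` from `start_m` to the full attribute count. At full `m` this
#' reproduces the standard full-evidence cross-validated AUC exactly.
#' A `retrain` mode instead refits a reduced model on the top-`m` attributes
#' for each `m`.
#'
#' @inheritParams cross_validated_scores
#' @param ranking an [rank_attributes()] ranking covering the predictors.
#' @param start_m first evidence budget (default 8; may be 0, giving
#'   constant prior scores and AUC 0.5).
#' @param mode `"partial"` (single model, partial evidence; default) or
#'   `"retrain"` (reduced model per m).
#' @return an object of class `incremental_report`: `ordering` (the
#'   ranking), `auc_by_m` (named numeric, names the m values), `mode`.
#' @export
incremental_auc <- function(x, model_spec, cv, ranking, start_m = 8,
                            mode = c("partial", "retrain")) {
  mode <- match.arg(mode)
  preds <- predictors(x, drop_inert = TRUE)
  if (!all(preds %in% ranking$attribute)) {
    stop("ordering missing attributes: ",
         paste(setdiff(preds, ranking$attribute), collapse = ", "),
         call. = FALSE)
  }
  ordering <- intersect(ranking$attribute, preds)
  M <- length(ordering)
  stopifnot(start_m >= 0, start_m <= M)
  ms <- seq(from = start_m, to = M)
  n <- n_records(x)
  y <- class_labels(x)
  score_mat <- matrix(NA_real_, n, length(ms))
  for (f in seq_along(cv$folds)) {
    te <- cv$folds[[f]]
    tr <- setdiff(seq_len(n), te)
    train <- slice_table(x, tr)
    test <- slice_table(x, te)
    if (mode == "partial") {
      model <- fit_model_spec(train, model_spec)
      for (i in seq_along(ms)) {
        if (ms[i] == 0L) {
          # no observation carries no record-level information: every record
          # gets the same constant (the marginal prevalence), so AUC = 0.5
          score_mat[te, i] <- mean(y)
        } else {
          score_mat[te, i] <- posterior_scores(model, test,
                                               observed = utils::head(ordering,
                                                                      ms[i]))
        }
      }
    } else {
      for (i in seq_along(ms)) {
        # keep table column order so the TAN root convention is unchanged
        top <- intersect(preds, utils::head(ordering, ms[i]))
        if (!length(top)) {
          score_mat[te, i] <- mean(y)
        } else {
          sub_model <- fit_model_spec(project_table(train, top), model_spec)
          score_mat[te, i] <- posterior_scores(sub_model,
                                               project_table(test, top))
        }
      }
    }
  }
  auc_by_m <- apply(score_mat, 2, function(s) {
    if (length(unique(s)) == 1L) 0.5 else roc_auc(s, y)$auc
  })
  names(auc_by_m) <- as.character(ms)
  out <- list(ordering = ranking, auc_by_m = auc_by_m, mode = mode)
  class(out) <- "incremental_report"
  out
}

#' @export
print.incremental_report <- function(x, ...) {
  cat(sprintf("<incremental_report> mode '%s', m = %s..%s\n", x$mode,
              names(x$auc_by_m)[1], utils::tail(names(x$auc_by_m), 1)))
  print(round(x$auc_by_m, 4))
  invisible(x)
}
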