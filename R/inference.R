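# Exact inference: single-query variable elimination and vectorized
# partial-evidence scoring for forest-shaped (NB/TAN) classifiers.

#' Posterior probability of the positive class under partial evidence
#'
#' Computes \eqn{P(class = 1 \mid ev)} by exact variable elimination over the
#' network's joint factorization \eqn{P(V_1,\dots,V_n) = \prod_i
#' P(V_i \mid Pa(V_i))}, marginalizing every unobserved predictor. Evidence
#' may cover any subset of predictors, including none (the result is then the
#' class prior).
#'
#' @param model a [fit_cpts()] classifier.
#' @param evidence named character vector or list mapping predictor names to
#'   observed state labels; may be empty.
#' @return scalar probability in \[0, 1\].
#' @export
posterior <- function(model, evidence = character(0)) {
  evidence <- unlist(evidence)
  cls <- model$structure$class_name
  preds <- setdiff(model$structure$nodes, cls)
  if (length(evidence)) {
    bad <- setdiff(names(evidence), preds)
    if (length(bad)) stop("evidence on unknown attribute: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(evidence)) {
      if (!evidence[[nm]] %in% model$meta$levels[[nm]]) {
        stop(sprintf("evidence state '%s' is not a state of '%s'",
                     evidence[[nm]], nm), call. = FALSE)
      }
    }
  }
  factors <- lapply(model$structure$nodes, function(v) {
    arr <- model$cpts[[v]]
    f <- list(vars = c(v, model$structure$parents[[v]]), arr = arr)
    for (nm in intersect(f$vars, names(evidence))) {
      f <- factor_reduce(f, nm,
                         match(evidence[[nm]], model$meta$levels[[nm]]))
    }
    f
  })
  hidden <- setdiff(preds, names(evidence))
  for (h in order_elimination(factors, hidden)) {
    involved <- vapply(factors, function(f) h %in% f$vars, logical(1))
    prod_f <- Reduce(factor_product, factors[involved])
    factors <- c(factors[!involved],
                 list(factor_marginalize(prod_f, h)))
  }
  final <- Reduce(factor_product, factors)
  stopifnot(identical(final$vars, cls) || length(final$vars) == 1L)
  p <- as.numeric(final$arr)
  if (anyNA(p)) {
    stop("undefined CPT entry used (pseudocount 0 with unobserved parent configuration)",
         call. = FALSE)
  }
  if (sum(p) == 0) {
    stop("evidence has zero probability under the model (unsmoothed estimates)",
         call. = FALSE)
  }
  p[2L] / sum(p)
}

# Greedy min-width elimination order: repeatedly pick the hidden variable
# whose elimination creates the smallest intermediate factor.
order_elimination <- function(factors, hidden) {
  dims <- list()
  for (f in factors) {
    d <- dim(f$arr)
    if (is.null(d)) d <- length(f$arr)
    for (i in seq_along(f$vars)) dims[[f$vars[i]]] <- d[i]
  }
  scopes <- lapply(factors, `[[`, "vars")
  out <- character(0)
  hid <- hidden
  while (length(hid)) {
    width <- vapply(hid, function(h) {
      vars <- unique(unlist(scopes[vapply(scopes, function(s) h %in% s,
                                          logical(1))]))
      prod(unlist(dims[setdiff(vars, h)]))
    }, numeric(1))
    h <- hid[which.min(width)]
    touched <- vapply(scopes, function(s) h %in% s, logical(1))
    newscope <- setdiff(unique(unlist(scopes[touched])), h)
    scopes <- c(scopes[!touched], list(newscope))
    out <- c(out, h)
    hid <- setdiff(hid, h)
  }
  out
}

factor_reduce <- function(f, var, state_idx) {
  i <- match(var, f$vars)
  d <- dim(f$arr)
  if (is.null(d)) d <- length(f$arr)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[i]] <- state_idx
  arr <- do.call(`[`, c(list(f$arr), idx, list(drop = FALSE)))
  newdim <- d[-i]
  vars <- f$vars[-i]
  if (length(newdim)) {
    arr <- array(as.numeric(aperm(arr, c(setdiff(seq_along(d), i), i))),
                 dim = newdim)
  } else {
    arr <- as.numeric(arr)
  }
  list(vars = vars, arr = arr)
}

factor_product <- function(f1, f2) {
  if (!length(f1$vars)) return(list(vars = f2$vars,
                                    arr = f2$arr * as.numeric(f1$arr)))
  if (!length(f2$vars)) return(list(vars = f1$vars,
                                    arr = f1$arr * as.numeric(f2$arr)))
  vu <- union(f1$vars, f2$vars)
  d1 <- dim(f1$arr); if (is.null(d1)) d1 <- length(f1$arr)
  d2 <- dim(f2$arr); if (is.null(d2)) d2 <- length(f2$arr)
  dims <- stats::setNames(rep(NA_integer_, length(vu)), vu)
  dims[f1$vars] <- d1
  dims[f2$vars] <- d2
  expand <- function(f, d) {
    miss <- setdiff(vu, f$vars)
    arr <- f$arr
    if (!is.array(arr)) arr <- array(arr, dim = length(arr))
    if (length(miss)) {
      arr <- array(rep(as.numeric(arr), prod(dims[miss])),
                   dim = c(d, dims[miss]))
    }
    cur <- c(f$vars, miss)
    aperm(arr, match(vu, cur))
  }
  list(vars = vu, arr = expand(f1, d1) * expand(f2, d2))
}

factor_marginalize <- function(f, var) {
  i <- match(var, f$vars)
  d <- dim(f$arr)
  if (is.null(d)) d <- length(f$arr)
  if (length(d) == 1L) {
    return(list(vars = character(0), arr = sum(f$arr)))
  }
  rest <- setdiff(seq_along(d), i)
  ap <- aperm(f$arr, c(rest, i))
  m <- matrix(ap, nrow = prod(d[rest]), ncol = d[i])
  list(vars = f$vars[rest], arr = array(rowSums(m), dim = d[rest]))
}

# Is every predictor's parent set within {class, one predictor}? (NB/TAN.)
is_forest_model <- function(model) {
  cls <- model$structure$class_name
  all(vapply(setdiff(model$structure$nodes, cls), function(v) {
    extra <- setdiff(model$structure$parents[[v]], cls)
    length(extra) <= 1L
  }, logical(1)))
}

#' Vectorized posterior scores under full or partial evidence
#'
#' Scores every record of `x` with \eqn{P(class = 1 \mid ev)} where the
#' evidence per record is its values on the `observed` attributes; all other
#' model predictors are marginalized. Full evidence uses direct product
#' scoring for any structure; partial evidence uses exact upward message
#' passing on the predictor forest for NB/TAN-shaped models and per-record
#' variable elimination otherwise.
#'
#' @param model a [fit_cpts()] classifier.
#' @param x a [risk_table()] containing every model predictor (state sets
#'   matching the training table).
#' @param observed character vector of observed attributes (default: all
#'   model predictors). May be empty, giving the class prior for every row.
#' @return numeric vector of posteriors, one per record.
#' @export
posterior_scores <- function(model, x,
                             observed = setdiff(model$structure$nodes,
                                                model$structure$class_name)) {
  cls <- model$structure$class_name
  preds <- setdiff(model$structure$nodes, cls)
  stopifnot(all(preds %in% names(x$data)))
  bad <- setdiff(observed, preds)
  if (length(bad)) stop("observed attribute not in model: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  n <- n_records(x)
  codes <- lapply(preds, function(v) {
    f <- x$data[[v]]
    stopifnot(is.factor(f), identical(levels(f), model$meta$levels[[v]]))
    as.integer(f)
  })
  names(codes) <- preds

  full_ev <- setequal(observed, preds) &&
    !anyNA(unlist(codes[observed], use.names = FALSE))
  if (full_ev) {
    lp <- matrix(0, n, 2)
    for (c in 1:2) lp[, c] <- log(model$cpts[[cls]][c])
    for (v in preds) {
      arr <- model$cpts[[v]]
      pars <- model$structure$parents[[v]]
      d <- dim(arr)
      for (c in 1:2) {
        idx <- codes[[v]]
        mult <- d[1L]
        for (k in seq_along(pars)) {
          pcode <- if (pars[k] == cls) rep(c, n) else codes[[pars[k]]]
          idx <- idx + mult * (pcode - 1L)
          mult <- mult * d[k + 1L]
        }
        pv <- arr[idx]
        if (anyNA(pv)) stop("undefined CPT entry used (pseudocount 0, unobserved parent configuration) in node ",
                            v, call. = FALSE)
        lp[, c] <- lp[, c] + log(pv)
      }
    }
    return(stats::plogis(lp[, 2L] - lp[, 1L]))
  }

  if (!is_forest_model(model)) {
    ev_cols <- observed
    return(vapply(seq_len(n), function(i) {
      ev <- vapply(ev_cols, function(v) as.character(x$data[[v]][i]),
                   character(1))
      ev <- ev[!is.na(ev)]
      posterior(model, ev)
    }, numeric(1)))
  }

  # upward message passing on the predictor forest, per class state
  children <- stats::setNames(vector("list", length(preds)), preds)
  parent_of <- stats::setNames(rep(NA_character_, length(preds)), preds)
  for (v in preds) {
    u <- setdiff(model$structure$parents[[v]], cls)
    if (length(u)) {
      children[[u]] <- c(children[[u]], v)
      parent_of[[v]] <- u
    }
  }
  depth <- stats::setNames(integer(length(preds)), preds)
  for (v in preds) {
    d <- 0L
    u <- v
    while (!is.na(parent_of[[u]])) {
      u <- parent_of[[u]]
      d <- d + 1L
    }
    depth[[v]] <- d
  }
  proc_order <- names(sort(depth, decreasing = TRUE))

  lik <- matrix(0, n, 2)
  for (c in 1:2) {
    msgs <- list()
    for (v in proc_order) {
      arr <- model$cpts[[v]]
      Lv <- dim(arr)[1L]
      childprod <- matrix(1, n, Lv)
      for (ch in children[[v]]) childprod <- childprod * msgs[[ch]]
      root <- is.na(parent_of[[v]])
      slice <- if (root) as.numeric(arr[, c]) else arr[, c, ]
      if (root) slice <- matrix(slice, ncol = 1L)      # Lv x 1
      if (is.null(dim(slice))) slice <- matrix(slice, nrow = Lv)
      # unobserved variant: sum over own states
      M <- childprod %*% slice                          # n x Lparent (or n x 1)
      if (v %in% observed) {
        o <- codes[[v]]
        ok <- !is.na(o)
        if (any(ok)) {
          cp_row <- childprod[cbind(seq_len(n)[ok], o[ok])]
          M[ok, ] <- slice[o[ok], , drop = FALSE] * cp_row
        }
      }
      msgs[[v]] <- M
    }
    lc <- rep(model$cpts[[cls]][c], n)
    for (v in preds[is.na(parent_of[preds])]) lc <- lc * msgs[[v]][, 1L]
    lik[, c] <- lc
  }
  lik[, 2L] / (lik[, 1L] + lik[, 2L])
}
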