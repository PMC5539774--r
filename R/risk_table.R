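#' Typed rectangular table with a designated binary class
#'
#' `risk_table` is the central data container of the package: a data frame of
#' patient (or generally, record-level) attributes in which exactly one column
#' is the binary class to predict and every predictor is declared either
#' `continuous` or `discrete`. Discrete columns are stored as factors whose
#' levels are the declared state sets; the class is canonicalized to states
#' `"0"`/`"1"` with `"1"` the positive (event) state.
#'
#' Column kinds are inferred when not supplied: numeric columns containing any
#' non-integer value are `continuous`; integer-coded numerics, characters,
#' factors and logicals are `discrete`. Inference is deliberately overridable
#' per attribute via `kinds`, since integer-coded categories are common in
#' clinical exports.
#'
#' @param data a data frame, one row per record.
#' @param class_name name of the class column; it must have exactly two
#'   observed values.
#' @param kinds optional named character vector overriding the inferred kind
#'   (`"continuous"` or `"discrete"`) for some predictors.
#' @param positive optional value of the class column to map to state `"1"`.
#'   Defaults to `1`/`"1"` when present, otherwise the larger of the two
#'   sorted values.
#' @param allow_missing if `FALSE` (default) rows with missing values are
#'   rejected at construction; if `TRUE` missing predictor values are kept and
#'   handled at inference time by marginalization.
#' @return an object of class `risk_table`.
#' @seealso [read_table()], [predictors()], [class_labels()]
#' @export
risk_table <- function(data, class_name, kinds = NULL, positive = NULL,
                       allow_missing = FALSE) {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!class_name %in% names(data)) {
    stop(sprintf("class not found: column '%s' is not in the table", class_name),
         call. = FALSE)
  }
  if (anyNA(data[[class_name]])) {
    stop("missing values in the class column are not allowed", call. = FALSE)
  }
  if (!allow_missing && anyNA(data)) {
    stop("missing values present; rejected at load time (set allow_missing = TRUE to keep them)",
         call. = FALSE)
  }

  cls_vals <- unique(data[[class_name]])
  if (length(cls_vals) != 2L) {
    stop(sprintf("class column '%s' must have exactly 2 observed values, found %d",
                 class_name, length(cls_vals)), call. = FALSE)
  }
  cls_chr <- as.character(data[[class_name]])
  vals <- sort(as.character(cls_vals))
  pos <- if (!is.null(positive)) as.character(positive)
         else if ("1" %in% vals) "1" else vals[2L]
  if (!pos %in% vals) stop("`positive` is not an observed class value", call. = FALSE)
  neg <- setdiff(vals, pos)
  data[[class_name]] <- factor(ifelse(cls_chr == pos, "1", "0"),
                               levels = c("0", "1"))

  pred_names <- setdiff(names(data), class_name)
  kind <- vapply(pred_names, function(nm) infer_kind(data[[nm]]), character(1))
  if (!is.null(kinds)) {
    bad <- setdiff(names(kinds), pred_names)
    if (length(bad)) stop("kind override for unknown attribute: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    stopifnot(all(kinds %in% c("continuous", "discrete")))
    kind[names(kinds)] <- kinds
  }
  for (nm in pred_names) {
    if (kind[[nm]] == "discrete") {
      if (!is.factor(data[[nm]])) {
        data[[nm]] <- factor(as.character(data[[nm]]))
      }
      if (anyDuplicated(levels(data[[nm]]))) {
        stop("duplicate state labels in attribute ", nm, call. = FALSE)
      }
    } else {
      data[[nm]] <- as.numeric(data[[nm]])
    }
  }

  structure(
    list(data = data, class_name = class_name, kind = kind,
         inert = character(0)),
    class = "risk_table"
  )
}

infer_kind <- function(x) {
  if (is.numeric(x)) {
    xx <- x[!is.na(x)]
    if (length(xx) && any(xx != round(xx))) "continuous" else "discrete"
  } else {
    "discrete"
  }
}

#' @export
print.risk_table <- function(x, ...) {
  p <- predictors(x)
  cat(sprintf("<risk_table> %d records, %d predictors (%d continuous, %d discrete), class '%s'\n",
              n_records(x), length(p), sum(x$kind == "continuous"),
              sum(x$kind == "discrete"), x$class_name))
  prev <- mean(class_labels(x))
  cat(sprintf("  positive ('1') prevalence: %.3f\n", prev))
  if (length(x$inert)) {
    cat("  inert attributes: ", paste(x$inert, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Accessors for risk_table objects
#'
#' `predictors()` returns predictor names (optionally excluding attributes
#' flagged inert by discretization), `class_labels()` the 0/1 integer class
#' vector, `n_records()` the record count, `attr_kind()` the declared kind of
#' an attribute, and `attr_states()` the state labels of a discrete attribute.
#'
#' @param x a `risk_table`.
#' @param drop_inert drop attributes flagged inert (single-state after
#'   discretization)?
#' @return see individual descriptions.
#' @export
predictors <- function(x, drop_inert = FALSE) {
  p <- setdiff(names(x$data), x$class_name)
  if (drop_inert) p <- setdiff(p, x$inert)
  p
}

#' @rdname predictors
#' @export
class_labels <- function(x) as.integer(as.character(x$data[[x$class_name]]))

#' @rdname predictors
#' @export
n_records <- function(x) nrow(x$data)

#' @rdname predictors
#' @param name attribute name.
#' @export
attr_kind <- function(x, name) {
  if (name == x$class_name) return("discrete")
  k <- x$kind[[name]]
  if (is.null(k)) stop("unknown attribute: ", name, call. = FALSE)
  k
}

#' @rdname predictors
#' @export
attr_states <- function(x, name) {
  if (attr_kind(x, name) != "discrete") {
    stop("attribute ", name, " is continuous; it has no states", call. = FALSE)
  }
  levels(x$data[[name]])
}

# Project a table onto a subset of predictors (class always kept).
project_table <- function(x, subset) {
  stopifnot(all(subset %in% predictors(x)))
  y <- x
  y$data <- x$data[, c(subset, x$class_name), drop = FALSE]
  y$kind <- x$kind[subset]
  y$inert <- intersect(x$inert, subset)
  y
}

# Row-subset a table (used by cross-validation).
slice_table <- function(x, idx) {
  y <- x
  y$data <- x$data[idx, , drop = FALSE]
  rownames(y$data) <- NULL
  y
}

#' Read a rectangular learning base from CSV or ARFF
#'
#' Reads a header CSV (RFC-4180, UTF-8) or a Weka-dialect ARFF file into a
#' [risk_table()]. ARFF nominal attributes become discrete with their declared
#' state sets; numeric attributes follow the same kind inference as
#' [risk_table()] unless overridden.
#'
#' @param path file path.
#' @param format `"csv"` or `"arff"`; default guesses from the file extension.
#' @param class_name name of the binary class column.
#' @inheritParams risk_table
#' @return a `risk_table`.
#' @export
read_table <- function(path, format = c("auto", "csv", "arff"), class_name,
                       kinds = NULL, positive = NULL, allow_missing = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("unreadable file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  if (format == "csv") {
    df <- tryCatch(
      utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                      fileEncoding = "UTF-8"),
      error = function(e) stop("unreadable file: ", conditionMessage(e),
                               call. = FALSE))
  } else {
    df <- tryCatch(foreign::read.arff(path),
                   error = function(e) stop("unreadable file: ",
                                            conditionMessage(e), call. = FALSE))
    if (is.null(kinds)) {
      # ARFF declares nominal attributes explicitly; honour the declaration.
      kinds <- vapply(setdiff(names(df), class_name), function(nm) {
        if (is.factor(df[[nm]])) "discrete" else infer_kind(df[[nm]])
      }, character(1))
    }
  }
  rb_log("read", sprintf("loaded %d rows x %d cols from %s", nrow(df),
                         ncol(df), path))
  risk_table(df, class_name = class_name, kinds = kinds, positive = positive,
             allow_missing = allow_missing)
}

#' Write a risk_table to CSV or ARFF
#'
#' The written file round-trips through [read_table()]: values, state sets and
#' the class column are preserved.
#'
#' @param x a `risk_table`.
#' @param path output path.
#' @param format `"csv"` or `"arff"` (default from extension).
#' @return invisibly, `path`.
#' @export
write_table <- function(x, path, format = c("auto", "csv", "arff")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  if (format == "csv") {
    utils::write.csv(x$data, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  } else {
    foreign::write.arff(x$data, path)
  }
  invisible(path)
}

#' Shannon entropy of a count vector, in bits
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} with \eqn{0 \cdot \log 0 = 0}, where
#' \eqn{p_i} are the empirical proportions `counts / sum(counts)`. Returns 0
#' for an all-zero vector. All entropies in this package are base-2 (bits),
#' the convention of the MDL and information-gain literature it builds on.
#'
#' @param counts nonnegative numeric vector of per-state counts.
#' @return entropy in bits (nonnegative scalar).
#' @export
entropy <- function(counts) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  total <- sum(counts)
  if (total == 0) return(0)
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Symmetrical uncertainty between two discrete columns
#'
#' \eqn{SU(X,Y) = 2[H(X)+H(Y)-H(X,Y)] / [H(X)+H(Y)]}, a normalized mutual
#' information in \[0, 1\], used as the correlation surrogate in
#' correlation-based feature selection on discretized data. Defined as 0 when
#' both marginal entropies vanish.
#'
#' @param x,y discrete vectors (factors or atomic) of equal length.
#' @return a scalar in \[0, 1\].
#' @export
symmetrical_uncertainty <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  hx <- entropy(table(x))
  hy <- entropy(table(y))
  if (hx + hy == 0) return(0)
  hxy <- entropy(table(x, y))
  su <- 2 * (hx + hy - hxy) / (hx + hy)
  min(max(su, 0), 1)
}

# ---- internal integer encoding (fast path shared by selection / bayesnet) ---

# Encode the discrete columns of a table as a 1-based integer matrix plus the
# 0/1 class; used by every inner loop (CMI, CPT fitting, CV scoring).
encode_table <- function(x, cols = predictors(x, drop_inert = TRUE)) {
  stopifnot(all(vapply(cols, function(nm) attr_kind(x, nm), "") == "discrete"))
  n <- n_records(x)
  X <- matrix(0L, nrow = n, ncol = length(cols),
              dimnames = list(NULL, cols))
  nlev <- integer(length(cols))
  states <- vector("list", length(cols))
  for (j in seq_along(cols)) {
    f <- x$data[[cols[j]]]
    X[, j] <- as.integer(f)
    nlev[j] <- nlevels(f)
    states[[j]] <- levels(f)
  }
  names(nlev) <- cols
  names(states) <- cols
  list(X = X, nlev = nlev, states = states, y = class_labels(x),
       cols = cols, n = n)
}
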