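# JSON persistence for schemes, rankings and fitted classifiers. All writers
# use full-precision numbers so that probabilities round-trip bit exact.

#' Write / read a discretization scheme as JSON
#'
#' The on-disk format is a flat map `{attribute: [cuts...]}` (plus the
#' recorded training ranges under `"_ranges"`).
#'
#' @param scheme a [mdl_discretize()] scheme.
#' @param path output path.
#' @return `write_scheme`: invisibly `path`; `read_scheme`: a
#'   `discretization_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  cuts <- lapply(scheme$cuts, function(p) p$cuts)
  jsonlite::write_json(c(cuts, list(`_ranges` = scheme$ranges)), path,
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ranges <- raw[["_ranges"]]
  raw[["_ranges"]] <- NULL
  cp <- lapply(names(raw), function(nm) cut_points(nm, as.numeric(raw[[nm]])))
  names(cp) <- names(raw)
  out <- list(cuts = cp, ranges = lapply(ranges, as.numeric))
  class(out) <- "discretization_scheme"
  out
}

#' Write / read an attribute ranking as JSON
#'
#' @param ranking an [rank_attributes()] ranking.
#' @param path output path.
#' @return `write_ranking`: invisibly `path`; `read_ranking`: an
#'   `attribute_ranking`.
#' @export
write_ranking <- function(ranking, path) {
  jsonlite::write_json(list(alpha = attr(ranking, "alpha"),
                            entries = as.data.frame(ranking)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- raw$entries
  attr(entries, "alpha") <- raw$alpha
  class(entries) <- c("attribute_ranking", "data.frame")
  entries
}

#' Serialize / restore a fitted classifier
#'
#' The JSON document holds the parent map, every CPT (dimensions, state
#' labels and full-precision probabilities) and the training metadata;
#' probabilities round-trip bit exact.
#'
#' @param model a [fit_cpts()] classifier.
#' @param path output path.
#' @return `model_to_json`: invisibly `path`; `model_from_json`: a
#'   `bayes_classifier`.
#' @export
model_to_json <- function(model, path) {
  # probabilities are written as %.17g strings: IEEE doubles round-trip
  # bit exact through that representation
  cpts <- lapply(model$cpts, function(arr) {
    list(dim = dim(arr), dimnames = dimnames(arr),
         values = sprintf("%.17g", as.numeric(arr)))
  })
  doc <- list(
    format_version = 1L,
    class_name = model$structure$class_name,
    nodes = model$structure$nodes,
    structure = model$structure$parents,
    edge_weights = as.list(model$structure$edge_weights),
    cpts = cpts,
    meta = model$meta)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  parents <- lapply(doc$structure, function(p) as.character(unlist(p)))
  ew <- unlist(doc$edge_weights)
  struct <- bn_structure(as.character(doc$nodes), doc$class_name, parents,
                         edge_weights = ew)
  cpts <- lapply(doc$cpts, function(e) {
    dn <- e$dimnames
    vals <- as.character(e$values)
    vals[vals == "NA"] <- NA_character_
    arr <- array(as.numeric(vals), dim = as.integer(e$dim),
                 dimnames = lapply(dn, as.character))
    names(dimnames(arr)) <- names(dn)
    arr
  })
  model <- list(structure = struct, cpts = cpts[struct$nodes],
                meta = list(n = doc$meta$n,
                            pseudocount = doc$meta$pseudocount,
                            levels = lapply(doc$meta$levels, as.character)))
  class(model) <- "bayes_classifier"
  model
}
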