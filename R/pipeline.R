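#' Pipeline configuration
#'
#' Validates and freezes the choices for one end-to-end run: input, stage
#' order (discretize-then-select is the default, the order found to give
#' the more accurate models), selection and structure methods, evaluation
#' settings and output location. All randomness in the run flows from the
#' single `seed` (per-stage seeds are derived from it); there is no hidden
#' global state.
#'
#' @param input a [risk_table()], or a CSV/ARFF path.
#' @param class_name class column name (required when `input` is a path).
#' @param stage_order `"discretize_first"` (default) or `"select_first"`.
#' @param selection one of `"wrapper-bestfirst"`, `"wrapper-genetic"`,
#'   `"cfs"`, `"gainratio"`, `"none"`.
#' @param structure final classifier structure: `"tan"`, `"k2"` or `"nb"`.
#' @param max_parents K2 parent cap (counting the class).
#' @param evaluator wrapper-evaluator structure, `"nb"` (default; naive
#'   Bayes, i.e. K2 with one parent) or `"tan"`.
#' @param cv_folds stratified cross-validation folds (default 10).
#' @param smoothing CPT pseudocount (default 0.5).
#' @param cutoff_mode `"min-distance"` (distance to the (0, 1) ROC corner).
#' @param start_m first evidence budget of the incremental evaluation
#'   (default 8).
#' @param seed root integer seed.
#' @param output_dir optional directory where artifacts (scheme, ranking,
#'   model, report JSON) are persisted.
#' @param kinds,positive forwarded to [read_table()] for path input.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, class_name = NULL,
                            stage_order = c("discretize_first",
                                            "select_first"),
                            selection = c("wrapper-bestfirst",
                                          "wrapper-genetic", "cfs",
                                          "gainratio", "none"),
                            structure = c("tan", "k2", "nb"),
                            max_parents = 2, evaluator = c("nb", "tan"),
                            cv_folds = 10, smoothing = 0.5,
                            cutoff_mode = "min-distance", start_m = 8,
                            seed = 42L, output_dir = NULL, kinds = NULL,
                            positive = NULL) {
  stage_order <- match.arg(stage_order)
  selection <- match.arg(selection)
  structure <- match.arg(structure)
  evaluator <- match.arg(evaluator)
  if (!identical(cutoff_mode, "min-distance")) {
    stop("unknown cutoff_mode: ", cutoff_mode, call. = FALSE)
  }
  if (is.character(input) && is.null(class_name)) {
    stop("class_name is required when input is a file path", call. = FALSE)
  }
  out <- list(input = input, class_name = class_name,
              stage_order = stage_order, selection = selection,
              structure = structure, max_parents = max_parents,
              evaluator = evaluator, cv_folds = cv_folds,
              smoothing = smoothing, cutoff_mode = cutoff_mode,
              start_m = start_m, seed = as.integer(seed),
              output_dir = output_dir, kinds = kinds, positive = positive)
  class(out) <- "pipeline_config"
  out
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognized keys match the arguments of [pipeline_config()].
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, raw)
}

#' Run the full prediction pipeline
#'
#' Executes discretization, attribute selection, structure learning, CPT
#' fitting, stratified cross-validated ROC/AUC evaluation, cutoff selection,
#' gain-ratio ranking and the incremental-observation evaluation, in the
#' configured stage order, and assembles everything into a reproducible
#' report. Deterministic given `config$seed`; when `config$output_dir` is
#' set, each intermediate artifact is persisted as JSON as soon as its stage
#' completes, so a failed run leaves its partial artifacts behind.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `pipeline_report` with elements `scheme`,
#'   `selected`, `ranking`, `structure`, `model`, `auc`, `roc`, `cutoff`,
#'   `incremental`, `interface_order`, `stage_aucs` and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$output_dir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  persist <- function(fn, obj, name) {
    if (!is.null(outdir)) fn(obj, file.path(outdir, name))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  tbl <- stage("load", {
    if (is.character(config$input)) {
      read_table(config$input, class_name = config$class_name,
                 kinds = config$kinds, positive = config$positive)
    } else {
      stopifnot(inherits(config$input, "risk_table"))
      config$input
    }
  })

  seed_select <- child_seed(config$seed, 1L)
  seed_cv <- child_seed(config$seed, 2L)

  # Supervised discretization is per-attribute, so the learned cuts are
  # identical in both stage orders; the orders differ in which view the
  # selection stage sees (see the methods vignette).
  scheme <- stage("discretize", mdl_discretize(tbl))
  persist(write_scheme, scheme, "scheme.json")
  dtbl <- stage("discretize", apply_scheme(tbl, scheme))
  rb_log("pipeline", sprintf("stage order: %s", config$stage_order))

  selected <- stage("select", {
    preds <- predictors(dtbl, drop_inert = TRUE)
    switch(config$selection,
      none = preds,
      gainratio = gain_ratio_filter(rank_attributes(dtbl)),
      cfs = as.character(cfs_select(dtbl)),
      `wrapper-bestfirst` = best_first_search(
        dtbl, config = search_config("bestfirst", seed = seed_select,
                                     evaluator_structure = config$evaluator,
                                     folds = config$cv_folds))$subset,
      `wrapper-genetic` = genetic_search(
        dtbl, config = search_config("genetic", seed = seed_select,
                                     evaluator_structure = config$evaluator,
                                     folds = config$cv_folds))$subset)
  })
  if (!length(selected)) stop("selection returned no attributes",
                              call. = FALSE)
  seltbl <- project_table(dtbl, selected)
  rb_log("select", sprintf("%d of %d attributes kept (%s)", length(selected),
                           length(predictors(dtbl, drop_inert = TRUE)),
                           config$selection))

  ranking <- stage("rank", rank_attributes(seltbl))
  persist(write_ranking, ranking, "ranking.json")

  model_spec <- list(structure = config$structure,
                     max_parents = config$max_parents,
                     smoothing = config$smoothing)
  model <- stage("learn", fit_model_spec(seltbl, model_spec))
  persist(model_to_json, model, "model.json")

  cv <- stratified_folds(class_labels(seltbl), k = config$cv_folds,
                         seed = seed_cv)
  scores <- stage("evaluate",
                  cross_validated_scores(seltbl, model_spec, cv))
  roc <- roc_auc(scores, class_labels(seltbl))
  roc$cutoff <- min(max(select_cutoff(roc), 0), 1)
  rb_log("evaluate", sprintf("cross-validated AUC %.4f, cutoff %.4f",
                             roc$auc, roc$cutoff))

  incr <- stage("incremental", {
    start_m <- min(config$start_m, nrow(ranking))
    incremental_auc(seltbl, model_spec, cv, ranking, start_m = start_m)
  })

  iface <- arrange_interface_order(ranking,
                                   head = min(8L, nrow(ranking)))

  report <- list(
    scheme = scheme,
    selected = selected,
    ranking = ranking,
    structure = model$structure,
    model = model,
    auc = roc$auc,
    roc = roc,
    cutoff = roc$cutoff,
    incremental = incr,
    interface_order = iface,
    cv = cv,
    provenance = list(
      config = config[setdiff(names(config), c("input", "output_dir"))],
      input = if (is.character(config$input)) config$input else
        sprintf("<in-memory risk_table: %d x %d>", n_records(tbl),
                length(predictors(tbl))),
      seeds = list(root = config$seed, select = seed_select, cv = seed_cv),
      package_version = as.character(utils::packageVersion("riskbn"))))
  class(report) <- "pipeline_report"
  if (!is.null(outdir)) {
    jsonlite::write_json(report_to_list(report),
                         file.path(outdir, "report.json"),
                         digits = NA, auto_unbox = TRUE, null = "null")
  }
  report
}

# Flatten a pipeline_report into plain lists for JSON.
report_to_list <- function(report) {
  list(
    auc = report$auc,
    cutoff = report$cutoff,
    selected_attributes = report$selected,
    ranking = list(alpha = attr(report$ranking, "alpha"),
                   entries = as.data.frame(report$ranking)),
    scheme = lapply(report$scheme$cuts, function(p) p$cuts),
    structure = report$structure$parents,
    roc_points = report$roc$points,
    auc_by_m = as.list(report$incremental$auc_by_m),
    interface_order = unclass(report$interface_order),
    provenance = report$provenance)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  selected attributes (%d): %s\n", length(x$selected),
              paste(x$selected, collapse = ", ")))
  cat(sprintf("  cross-validated AUC: %.4f   cutoff: %.4f\n", x$auc,
              x$cutoff))
  cat(sprintf("  incremental AUC (m = %s..%s): %s\n",
              names(x$incremental$auc_by_m)[1],
              utils::tail(names(x$incremental$auc_by_m), 1),
              paste(sprintf("%.3f", x$incremental$auc_by_m),
                    collapse = " ")))
  invisible(x)
}

#' Split a ranking into primary and secondary interface attributes
#'
#' Orders attributes by descending discrimination capacity (gain ratio) and
#' flags the first `head` of them primary — the ones a monitoring interface
#' shows first — and the remainder secondary. Ties share the ranking's
#' alphabetical tie-break.
#'
#' @param ranking an [rank_attributes()] ranking.
#' @param head number of primary attributes (default 8).
#' @return list of class `interface_order` with `primary` and `secondary`
#'   character vectors.
#' @export
arrange_interface_order <- function(ranking, head = 8) {
  if (!nrow(ranking)) stop("empty ranking", call. = FALSE)
  stopifnot(head <= nrow(ranking))
  out <- list(primary = utils::head(ranking$attribute, head),
              secondary = utils::tail(ranking$attribute,
                                      nrow(ranking) - head))
  class(out) <- "interface_order"
  out
}

#' @export
print.interface_order <- function(x, ...) {
  cat(sprintf("<interface_order> %d primary / %d secondary\n",
              length(x$primary), length(x$secondary)))
  cat("  primary:  ", paste(x$primary, collapse = ", "), "\n")
  if (length(x$secondary)) {
    cat("  secondary:", paste(x$secondary, collapse = ", "), "\n")
  }
  invisible(x)
}
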