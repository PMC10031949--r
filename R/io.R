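# readers/writers for the package's plain-text table formats, plus the
# pipeline driver

.check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(df)
}

.bad_rows <- function(cond, what, msg) {
  if (any(cond))
    stop(sprintf("%s: %s at row(s) %s", what, msg,
                 paste(utils::head(which(cond), 5), collapse = ", ")),
         call. = FALSE)
}

#' Validate a micronucleus table
#'
#' @param table Data frame with columns `animal`, `day`, `bn`, `mn` (an
#'   `anticoagulant` column is optional and added as `"unknown"` if absent).
#' @param allow_mn_gt_bn Permit more micronuclei than binucleate cells
#'   (possible under per-cell Poisson scoring where a cell can carry
#'   several micronuclei).
#' @return The validated table (invisibly usable), with `day`, `bn`, `mn`
#'   coerced to numeric/integer.
#' @export
validate_mn_table <- function(table, allow_mn_gt_bn = TRUE) {
  .check_columns(table, c("animal", "day", "bn", "mn"), "MN table")
  if (!"anticoagulant" %in% names(table)) table$anticoagulant <- "unknown"
  for (col in c("day", "bn", "mn")) {
    v <- suppressWarnings(as.numeric(table[[col]]))
    .bad_rows(is.na(v), "MN table", paste0("non-numeric '", col, "'"))
    table[[col]] <- v
  }
  .bad_rows(table$bn < 1, "MN table", "bn < 1")
  .bad_rows(table$mn < 0, "MN table", "mn < 0")
  if (!allow_mn_gt_bn)
    .bad_rows(table$mn > table$bn, "MN table", "mn > bn")
  table
}

#' Read / write a micronucleus table CSV
#'
#' CSV with header `animal,day,anticoagulant,bn,mn`; pre-irradiation rows
#' may carry negative days (treated as day 0 by the fitting functions).
#'
#' @param path File path.
#' @param allow_mn_gt_bn Passed to [validate_mn_table()]; set `FALSE` to
#'   enforce strict binomial semantics (`mn <= bn`).
#' @return `read_mn_table`: the validated data frame. `write_mn_table`:
#'   `path`, invisibly.
#' @export
read_mn_table <- function(path, allow_mn_gt_bn = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_mn_table(df, allow_mn_gt_bn = allow_mn_gt_bn)
}

#' @rdname read_mn_table
#' @param table The table to write.
#' @export
write_mn_table <- function(table, path) {
  table <- validate_mn_table(table)
  utils::write.csv(table[, c("animal", "day", "anticoagulant", "bn", "mn")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a hematology cell-count table
#'
#' @param table Data frame with columns `animal`, `day`, `cell_type`,
#'   `count` (absolute counts; negative days mark pre-irradiation occasions).
#' @return The validated table.
#' @export
validate_cellcount_table <- function(table) {
  .check_columns(table, c("animal", "day", "cell_type", "count"),
                 "cell-count table")
  for (col in c("day", "count")) {
    v <- suppressWarnings(as.numeric(table[[col]]))
    .bad_rows(is.na(v), "cell-count table", paste0("non-numeric '", col, "'"))
    table[[col]] <- v
  }
  .bad_rows(table$count < 0, "cell-count table", "negative count")
  table
}

#' Read / write a hematology cell-count CSV
#'
#' CSV with header `animal,day,cell_type,count`.
#'
#' @param path File path.
#' @return `read_cellcount_table`: the validated data frame.
#' @export
read_cellcount_table <- function(path) {
  validate_cellcount_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cellcount_table
#' @param table The table to write.
#' @export
write_cellcount_table <- function(table, path) {
  table <- validate_cellcount_table(table)
  utils::write.csv(table[, c("animal", "day", "cell_type", "count")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write molecule lists as TSV
#'
#' Tab-separated with header `molecule,day,modality,log2fc,direction`.
#' Reading returns one data frame per day/modality combination.
#'
#' @param path File path.
#' @return `read_molecule_lists`: a named list of molecule-list data frames,
#'   split by modality and day.
#' @export
read_molecule_lists <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_columns(df, c("molecule", "day", "modality", "log2fc", "direction"),
                 "molecule list")
  v <- suppressWarnings(as.numeric(df$log2fc))
  .bad_rows(is.na(v), "molecule list", "non-numeric 'log2fc'")
  df$log2fc <- v
  split(df, interaction(df$modality, df$day, drop = TRUE, lex.order = TRUE))
}

#' @rdname read_molecule_lists
#' @param lists A molecule-list data frame or list of them.
#' @export
write_molecule_lists <- function(lists, path) {
  if (inherits(lists, "data.frame")) lists <- list(lists)
  df <- do.call(rbind, lists)
  utils::write.table(df[, c("molecule", "day", "modality", "log2fc", "direction")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a multi-stage analysis from a configuration list
#'
#' Executes the requested stages in order — `simulate` (micronucleus table),
#' `fit`, `compare`, `mn_test`, `hema`, `overlap`, `enrich` — writing each
#' stage's outputs under `out_dir` and returning the full result bundle.
#' Stages not named in the config are skipped and produce no output.
#' Unknown configuration keys are an error (fail-fast), and every stage's
#' randomness derives from the single top-level `seed`.
#'
#' Minimal example config:
#' ```
#' list(seed = 1, out_dir = tempdir(),
#'      simulate = list(params = list(C = 0.05, Kprod = 0.2, Kdec1 = 0.1,
#'                                    Kdec2 = 0.001, P = 0.5),
#'                      animals = paste0("A", 1:8),
#'                      days = c(0, 1, 3, 6, 9, 15, 28, 56)),
#'      fit = list(model = "M3_mixture"),
#'      compare = list(models = mn_model_names()))
#' ```
#'
#' @param config A named list (see above). Recognized top-level keys:
#'   `seed`, `out_dir`, `mn_table` (path to an existing MN CSV, used when no
#'   `simulate` stage is given), `simulate`, `fit`, `compare`, `mn_test`,
#'   `hema`, `overlap`, `enrich`.
#' @return A named list of stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  known <- c("seed", "out_dir", "mn_table", "simulate", "fit", "compare",
             "mn_test", "hema", "overlap", "enrich")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- list(seed = seed)
  logf <- function(...) message("[radcourse] ", sprintf(...))

  mn_tab <- NULL
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    params <- do.call(kinetic_params, sc$params)
    design <- mn_design(sc$animals, sc$days,
                        bn_range = sc$bn_range %||% c(200L, 1000L),
                        anticoagulant = sc$anticoagulant %||% "EDTA")
    noise <- dispersion_spec(sc$family %||% "binomial", rho = sc$rho %||% 0)
    mn_tab <- simulate_mn(params, design, noise, seed = seed)
    write_mn_table(mn_tab, file.path(out_dir, "mn_table.csv"))
    res$simulate <- mn_tab
    logf("simulate: wrote %d MN observations (seed %d)", nrow(mn_tab), seed)
  } else if (!is.null(config$mn_table)) {
    mn_tab <- read_mn_table(config$mn_table)
  }

  if (!is.null(config$fit)) {
    if (is.null(mn_tab)) stop("stage 'fit' needs an MN table", call. = FALSE)
    fit <- fit_mn(mn_tab, config$fit$model %||% "M3_mixture", seed = seed)
    jsonlite::write_json(
      list(model = fit$spec, params = as.list(fit$coef), aic = fit$aic,
           loglik = fit$loglik, rse = fit$rse, converged = fit$converged,
           n_obs = fit$n_obs),
      file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
    curve <- predict_curve(fit, sort(unique(pmax(mn_tab$day, 0))))
    utils::write.csv(curve, file.path(out_dir, "curve.csv"), row.names = FALSE)
    res$fit <- fit
    logf("fit: %s AIC=%.3f rse=%.4g", fit$spec, fit$aic, fit$rse)
  }

  if (!is.null(config$compare)) {
    if (is.null(mn_tab)) stop("stage 'compare' needs an MN table", call. = FALSE)
    cmp <- compare_models(mn_tab, config$compare$models %||% mn_model_names(),
                          seed = seed)
    utils::write.csv(attr(cmp, "ranking"),
                     file.path(out_dir, "model_ranking.csv"), row.names = FALSE)
    res$compare <- cmp
    logf("compare: best model %s", attr(cmp, "ranking")$model[1])
  }

  if (!is.null(config$mn_test)) {
    if (is.null(mn_tab)) stop("stage 'mn_test' needs an MN table", call. = FALSE)
    tst <- day56_vs_baseline(mn_tab,
                             day_late = config$mn_test$day_late %||% 56L,
                             alpha = config$mn_test$alpha %||% 0.05)
    jsonlite::write_json(tst, file.path(out_dir, "mn_tests.json"),
                         dataframe = "rows", digits = NA)
    res$mn_test <- tst
  }

  if (!is.null(config$hema)) {
    hc <- config$hema
    tab <- read_cellcount_table(hc$path)
    nr <- nadir_recovery(tab, hc$cell_type, alpha = hc$alpha %||% 0.05)
    jsonlite::write_json(
      list(cell_type = hc$cell_type, nadir_day = nr$nadir_day,
           recovery_day = nr$recovery_day),
      file.path(out_dir, "hema_summary.json"), auto_unbox = TRUE, digits = NA)
    res$hema <- nr
  }

  if (!is.null(config$overlap)) {
    lists <- unlist(lapply(config$overlap$paths, read_molecule_lists),
                    recursive = FALSE)
    ov <- intersect_lists(lists)
    jsonlite::write_json(
      list(union_size = ov$union_size, intersection_size = ov$intersection_size,
           pairwise = ov$pairwise, members = ov$members),
      file.path(out_dir, "overlap.json"), digits = NA, matrix = "rowmajor")
    res$overlap <- ov
  }

  if (!is.null(config$enrich)) {
    ec <- config$enrich
    coll <- read_gmt(ec$gmt)
    hits <- readLines(ec$hits)
    enr <- overrepresentation(hits, coll, alpha = ec$alpha %||% 0.05)
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    res$enrich <- enr
  }

  invisible(res)
}
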