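#' Configure an end-to-end severity re-analysis
#'
#' Bundles every tunable of the screening -> EFA -> pruning -> CFA ->
#' second-order -> scoring pipeline. The configuration round-trips through
#' YAML via [yaml::as.yaml()] unchanged.
#'
#' @param input either a path to a CSV/XLSX table (read with the supplied
#'   `meta`), an [indicator_table()], or a [crisis_generator_config()] to
#'   simulate from.
#' @param meta indicator metadata, required when `input` is a path.
#' @param screen_threshold missingness screening cutoff (0.25).
#' @param factors candidate EFA factor counts (default `3:6`).
#' @param prune_solutions the two factor counts whose solutions drive
#'   indicator pruning (default `c(3, 4)`).
#' @param load_min,cross_gap pruning thresholds (see [efa_prune()]).
#' @param resid_cutoff,budget CFA modification settings (see
#'   [modify_cfa()]).
#' @param second_order add the second-order severity factor and compute
#'   scores (default `TRUE`).
#' @param efa_only stop after the pruning stage.
#' @param seed integer seed used for any simulation input.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, meta = NULL, screen_threshold = 0.25,
                            factors = 3:6, prune_solutions = c(3, 4),
                            load_min = 0.30, cross_gap = 0.20,
                            resid_cutoff = 0.10, budget = 10,
                            second_order = TRUE, efa_only = FALSE,
                            seed = 1L) {
  stopifnot(screen_threshold > 0, screen_threshold < 1,
            all(factors >= 1), all(prune_solutions %in% factors),
            load_min > 0, cross_gap > 0, resid_cutoff > 0, budget >= 0)
  structure(list(input = input, meta = meta,
                 screen_threshold = screen_threshold,
                 factors = factors, prune_solutions = prune_solutions,
                 load_min = load_min, cross_gap = cross_gap,
                 resid_cutoff = resid_cutoff, budget = budget,
                 second_order = second_order, efa_only = efa_only,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full severity re-analysis pipeline
#'
#' Executes, in order: input acquisition (read or simulate), missingness
#' screening, descriptive statistics and Spearman correlations, median
#' imputation, maximum-likelihood EFA over the configured factor range,
#' factor-retention evaluation, indicator pruning, construct assignment
#' from the smallest pruned solution, standardization, FIML CFA with
#' residual-driven modification, the second-order severity factor, and
#' normalized severity scores. Every stage's artifact is kept on the
#' returned report.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `run_report` with elements `table`,
#'   `screen`, `describe`, `correlations`, `efa` (list of fits),
#'   `retention`, `prune`, `cfa_spec`, `cfa_base`, `modification`,
#'   `cfa_final`, `cfa_second_order`, `scores`, `fit_table` and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  types <- NULL
  if (inherits(config$input, "crisis_generator_config")) {
    sim <- simulate_crises(config$input, seed = config$seed)
    table <- sim$table
    truth <- sim$truth
    if (!is.null(truth$type)) types <- truth$type
  } else if (inherits(config$input, "indicator_table")) {
    table <- config$input
  } else {
    if (is.null(config$meta)) stop("meta required to read a file input")
    table <- read_indicator_table(config$input, config$meta)
  }

  screen <- missingness_screen(table, config$screen_threshold)
  desc <- describe_indicators(screen$table)
  corr <- indicator_correlations(screen$table, method = "spearman")

  imputed <- impute_median(screen$table)
  efa_fits <- lapply(config$factors, function(k) efa_ml(imputed, k))
  names(efa_fits) <- paste0("k", config$factors)
  retention <- efa_retention(efa_fits)
  ia <- match(config$prune_solutions[1], config$factors)
  ib <- match(config$prune_solutions[2], config$factors)
  prune <- efa_prune(efa_fits[[ia]], efa_fits[[ib]],
                     load_min = config$load_min,
                     cross_gap = config$cross_gap)

  report <- list(table = table, truth = truth, screen = screen,
                 describe = desc, correlations = corr,
                 efa = efa_fits, retention = retention, prune = prune,
                 config = config)
  if (config$efa_only) {
    return(structure(report, class = "run_report"))
  }

  retained <- attr(prune, "retained")
  if (length(retained) < 6) {
    stop("pipeline: fewer than 6 indicators survive pruning")
  }
  ## assign each retained indicator to its primary factor in the smaller
  ## pruned solution; drop constructs left with < 2 indicators
  sol <- efa_fits[[ia]]
  L <- sol$loadings[retained, , drop = FALSE]
  assignment <- apply(abs(L), 1, which.max)
  constructs <- split(retained, paste0("construct", assignment))
  constructs <- constructs[lengths(constructs) >= 2]
  if (length(constructs) < 2) stop("pipeline: fewer than 2 constructs")
  spec <- cfa_model(constructs)

  keep_table <- indicator_table(
    screen$table$values[, unlist(constructs), drop = FALSE],
    screen$table$meta[match(unlist(constructs), screen$table$meta$id), ,
                      drop = FALSE],
    crisis_ids = screen$table$crisis_ids)
  z <- standardize_indicators(keep_table)
  base_fit <- cfa_fiml(spec, z)
  mod <- modify_cfa(spec, z, cutoff = config$resid_cutoff,
                    budget = config$budget)
  report$cfa_spec <- spec
  report$cfa_base <- base_fit
  report$modification <- mod$log
  report$cfa_final <- mod$fit

  fit_rows <- list(
    data.frame(model = "base", chisq = base_fit$chisq, df = base_fit$df,
               cfi = base_fit$cfi, tli = base_fit$tli,
               rmsea = base_fit$rmsea),
    data.frame(model = "final", chisq = mod$fit$chisq, df = mod$fit$df,
               cfi = mod$fit$cfi, tli = mod$fit$tli,
               rmsea = mod$fit$rmsea))

  if (config$second_order && length(mod$spec$constructs) >= 3) {
    so_spec <- add_second_order(mod$spec)
    so_fit <- cfa_fiml(so_spec, z)
    report$cfa_second_order <- so_fit
    fit_rows[[3]] <- data.frame(
      model = "second_order", chisq = so_fit$chisq, df = so_fit$df,
      cfi = so_fit$cfi, tli = so_fit$tli, rmsea = so_fit$rmsea)
    sc_types <- if (!is.null(types)) {
      types[match(rownames(so_fit$data), table$crisis_ids)]
    } else NULL
    report$scores <- severity_scores(so_fit, types = sc_types)
  } else if (config$second_order) {
    warning("fewer than 3 constructs after modification; ",
            "second-order stage skipped")
  }
  report$fit_table <- do.call(rbind, fit_rows)
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Severity re-analysis run\n")
  cat(sprintf("  input: %d crises x %d indicators; %d removed by screening\n",
              nrow(x$table$values), ncol(x$table$values),
              length(x$screen$report$removed)))
  rec <- attr(x$retention, "recommended")
  cat("  EFA solutions passing per-factor retention: ",
      if (length(rec)) paste(rec, collapse = ", ") else "none", "\n",
      sep = "")
  cat(sprintf("  pruning retained %d indicator(s)\n",
              length(attr(x$prune, "retained"))))
  if (!is.null(x$fit_table)) {
    cat("  fit statistics:\n")
    print(cbind(x$fit_table[1],
                round(x$fit_table[-1], 3)), row.names = FALSE)
  }
  if (!is.null(x$scores)) {
    cat(sprintf("  mean normalized severity: %.2f\n",
                mean(x$scores$normalized, na.rm = TRUE)))
  }
  invisible(x)
}

#' Write pipeline report tables to disk
#'
#' Persists the run's tables as CSV (descriptives, correlations, variance
#' accounting per EFA solution, loadings with sub-threshold entries
#' blanked, prune log, fit statistics, modification log, severity scores),
#' a JSON fit summary, and a plain-text log. Display tables round to the
#' conventional precision (two decimals); the JSON keeps full precision.
#'
#' @param report a `run_report`.
#' @param outdir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put <- function(df, name) {
    f <- file.path(outdir, name)
    utils::write.csv(df, f, row.names = FALSE)
    written <<- c(written, f)
  }
  put(report$describe, "descriptives.csv")
  f <- file.path(outdir, "correlations.csv")
  utils::write.csv(cbind(id = rownames(report$correlations),
                         as.data.frame(round(report$correlations, 4))),
                   f, row.names = FALSE)
  written <- c(written, f)
  var_tab <- do.call(rbind, lapply(report$efa, function(s) {
    data.frame(solution = s$factors, factor = seq_len(s$factors),
               ss_loadings = round(s$ss_loadings, 2),
               proportion = round(s$proportion_var, 2),
               cumulative = round(s$cumulative_var, 2))
  }))
  put(var_tab, "efa_variance.csv")
  for (s in report$efa) {
    L <- round(s$loadings, 2)
    disp <- as.data.frame(ifelse(abs(s$loadings) <
                                   report$config$load_min, "",
                                 format(L)))
    put(cbind(id = rownames(s$loadings), disp),
        sprintf("efa_loadings_k%d.csv", s$factors))
  }
  put(as.data.frame(report$prune), "prune_log.csv")
  log_lines <- c(sprintf("screened out: %s",
                         paste(report$screen$report$removed,
                               collapse = ", ")),
                 sprintf("retained after pruning: %s",
                         paste(attr(report$prune, "retained"),
                               collapse = ", ")))
  if (!is.null(report$fit_table)) {
    disp_fit <- report$fit_table
    disp_fit[-1] <- round(disp_fit[-1], 2)
    put(disp_fit, "fit_statistics.csv")
    put(report$modification, "modification_log.csv")
    summ <- list(fit = report$fit_table,
                 removed_by_screening = report$screen$report$removed,
                 retained_after_pruning = attr(report$prune, "retained"))
    if (!is.null(report$cfa_second_order)) {
      summ$second_order_loadings <-
        as.list(report$cfa_second_order$gamma)
    }
    fj <- file.path(outdir, "fit_summary.json")
    jsonlite::write_json(summ, fj, auto_unbox = TRUE, digits = NA)
    written <- c(written, fj)
  }
  if (!is.null(report$scores)) {
    put(as.data.frame(report$scores), "severity_scores.csv")
  } else {
    log_lines <- c(log_lines, "severity scores not computed")
  }
  fl <- file.path(outdir, "run_log.txt")
  writeLines(log_lines, fl)
  written <- c(written, fl)
  invisible(written)
}

#' Save or load a generator configuration as YAML
#'
#' Serializes a [crisis_generator_config()] to a YAML file and restores it
#' through the validating constructor, so a stored configuration
#' round-trips unchanged.
#'
#' @param config a `crisis_generator_config`.
#' @param path YAML file path.
#' @return `save_generator_config()` returns `path` invisibly;
#'   `load_generator_config()` returns the restored config.
#' @export
save_generator_config <- function(config, path) {
  stopifnot(inherits(config, "crisis_generator_config"))
  obj <- list(
    n_crises = config$n_crises,
    constructs = lapply(config$constructs, as.list),
    first_order_loadings = as.list(config$first_order_loadings),
    second_order_loadings = as.list(config$second_order_loadings),
    pillars = as.list(config$pillars),
    cutpoints = if (is.null(config$cutpoints)) NULL else
      lapply(config$cutpoints, as.numeric),
    scale_min = config$scale_min,
    missing_rates = as.list(config$missing_rates),
    residual_cov_pairs = config$residual_cov_pairs,
    crisis_types = if (is.null(config$crisis_types)) NULL else
      as.list(config$crisis_types))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname save_generator_config
#' @export
load_generator_config <- function(path) {
  obj <- yaml::read_yaml(path)
  unl <- function(x) if (is.null(x)) NULL else unlist(x)
  crisis_generator_config(
    n_crises = obj$n_crises,
    constructs = lapply(obj$constructs, unlist),
    first_order_loadings = unl(obj$first_order_loadings),
    second_order_loadings = unl(obj$second_order_loadings),
    pillars = unl(obj$pillars),
    cutpoints = if (is.null(obj$cutpoints)) NULL else
      lapply(obj$cutpoints, as.numeric),
    scale_min = obj$scale_min,
    missing_rates = unl(obj$missing_rates),
    residual_cov_pairs = obj$residual_cov_pairs,
    crisis_types = if (is.null(obj$crisis_types)) NULL else
      as.data.frame(obj$crisis_types, stringsAsFactors = FALSE))
}

#' Reproduce the published re-analysis from the deposited crisis table
#'
#' Runs the full pipeline with the published settings against a local
#' copy of the deposited 2019 crisis-severity table ("GCSI Database Beta
#' Version - November 2019", available from
#' \url{https://data.humdata.org/dataset/inform-global-crisis-severity-index};
#' not redistributed with this package). The file must contain one row per
#' crisis, a crisis-id first column, and the 35 indicator columns; column
#' names are taken as indicator ids unless `meta` is supplied.
#'
#' @param path path to a local CSV/XLSX copy of the deposited table, or
#'   `NULL` to use `getOption("crisisseverity.gcsi_path")`.
#' @param meta optional [indicator_meta()] for the 35 indicators; by
#'   default every non-id column is treated as an indicator on a 0--5
#'   scale.
#' @return The `run_report` of the pipeline run.
#' @export
reproduce_gcsi_analysis <- function(path = NULL, meta = NULL) {
  if (is.null(path)) path <- getOption("crisisseverity.gcsi_path")
  if (is.null(path) || !file.exists(path)) {
    stop("deposited table not found; download it from ",
         "https://data.humdata.org/dataset/inform-global-crisis-severity-index ",
         "and pass its local path (or set options(crisisseverity.gcsi_path=))")
  }
  if (is.null(meta)) {
    header <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
      colnames(readxl::read_excel(path, n_max = 1))
    } else {
      colnames(utils::read.csv(path, nrows = 1, check.names = FALSE))
    }
    meta <- indicator_meta(id = header[-1], pillar = "complexity",
                           scale_min = 0, scale_max = 5)
  }
  config <- pipeline_config(input = path, meta = meta)
  run_pipeline(config)
}
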