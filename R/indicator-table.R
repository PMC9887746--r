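#' Indicator metadata
#'
#' Builds the per-indicator metadata frame used throughout the package: one
#' row per indicator with its pillar assignment and ordinal scale bounds.
#'
#' @param id character vector of short, unique indicator keys.
#' @param pillar pillar each indicator belongs to; one of `"impact"`,
#'   `"complexity"`, `"conditions"` (recycled if length 1).
#' @param name free-text indicator names; defaults to `id`.
#' @param scale_min,scale_max integer ordinal bounds (typically 0--5 or 1--5).
#' @param crisis_related logical; whether the indicator is collected per
#'   crisis rather than per country.
#' @param collection_frequency free text, or `NA`.
#'
#' @return A `data.frame` with one row per indicator.
#' @export
indicator_meta <- function(id, pillar, name = id, scale_min = 0L,
                           scale_max = 5L, crisis_related = TRUE,
                           collection_frequency = NA_character_) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("indicator ids must be unique")
  pillar <- match.arg(pillar, c("impact", "complexity", "conditions"),
                      several.ok = TRUE)
  meta <- data.frame(
    id = id,
    name = as.character(name),
    pillar = rep_len(pillar, length(id)),
    scale_min = as.numeric(rep_len(scale_min, length(id))),
    scale_max = as.numeric(rep_len(scale_max, length(id))),
    crisis_related = rep_len(as.logical(crisis_related), length(id)),
    collection_frequency = rep_len(collection_frequency, length(id)),
    stringsAsFactors = FALSE
  )
  bad <- meta$scale_min >= meta$scale_max
  if (any(bad)) {
    stop("scale_min must be < scale_max for indicator(s): ",
         paste(meta$id[bad], collapse = ", "))
  }
  meta
}

#' Crisis-by-indicator table
#'
#' The central data container: an ordered set of crises, per-indicator
#' metadata, and a numeric crises x indicators grid of ordinal scores in
#' which cells may be missing. Every non-missing value is validated against
#' its indicator's scale bounds.
#'
#' @param values numeric matrix (crises x indicators); `NA` marks missing.
#' @param meta indicator metadata as built by [indicator_meta()]; row order
#'   must match the column order of `values`.
#' @param crisis_ids character vector of unique crisis identifiers
#'   (e.g. `"SOM001"`); defaults to `rownames(values)`.
#'
#' @return An object of class `indicator_table` with elements `crisis_ids`,
#'   `meta` and `values`.
#' @export
indicator_table <- function(values, meta, crisis_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(crisis_ids)) crisis_ids <- paste0("CRI", seq_len(nrow(values)))
  crisis_ids <- as.character(crisis_ids)
  if (length(crisis_ids) != nrow(values)) {
    stop("crisis_ids length does not match number of rows")
  }
  if (anyDuplicated(crisis_ids)) stop("crisis ids must be unique")
  if (ncol(values) != nrow(meta)) {
    stop("values has ", ncol(values), " columns but meta describes ",
         nrow(meta), " indicators")
  }
  dimnames(values) <- list(crisis_ids, meta$id)
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    bad <- which(!is.na(v) & (v < meta$scale_min[j] | v > meta$scale_max[j]))
    if (length(bad)) {
      stop(sprintf(
        "value %g for indicator '%s' in crisis '%s' is outside scale [%g, %g]",
        v[bad[1]], meta$id[j], crisis_ids[bad[1]],
        meta$scale_min[j], meta$scale_max[j]))
    }
  }
  structure(list(crisis_ids = crisis_ids, meta = meta, values = values),
            class = "indicator_table")
}

#' @export
print.indicator_table <- function(x, ...) {
  cat("Crisis-by-indicator table: ", nrow(x$values), " crises x ",
      ncol(x$values), " indicators\n", sep = "")
  miss <- mean(is.na(x$values))
  cat(sprintf("Missing cells: %.1f%%\n", 100 * miss))
  tab <- table(factor(x$meta$pillar,
                      levels = c("impact", "complexity", "conditions")))
  cat("Pillars: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.indicator_table <- function(x) dim(x$values)

#' Read a crisis-by-indicator table from CSV or XLSX
#'
#' Expects one row per crisis with the crisis identifier in the first
#' column and one column per indicator. Blank cells and non-numeric
#' sentinels (`"N/A"`, `"x"`, ...) are coerced to missing; each such
#' coercion of a non-blank token is reported via `message()`. Values
#' outside an indicator's scale bounds are rejected.
#'
#' @param path path to a `.csv` (or `.xlsx`, requiring the readxl package)
#'   file.
#' @param meta indicator metadata ([indicator_meta()]). Every meta id must
#'   resolve to a column of the file.
#'
#' @return An [indicator_table()].
#' @export
read_indicator_table <- function(path, meta) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the readxl package")
    }
    raw <- as.data.frame(readxl::read_excel(path, col_types = "text"),
                         stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  }
  if (ncol(raw) < 2) stop("table needs a crisis-id column plus indicators")
  crisis_ids <- raw[[1]]
  missing_cols <- setdiff(meta$id, names(raw))
  if (length(missing_cols)) {
    stop("schema error: column(s) not found in file: ",
         paste(missing_cols, collapse = ", "))
  }
  values <- matrix(NA_real_, nrow(raw), nrow(meta))
  for (j in seq_len(nrow(meta))) {
    txt <- trimws(raw[[meta$id[j]]])
    num <- suppressWarnings(as.numeric(txt))
    coerced <- which(is.na(num) & !is.na(txt) & nzchar(txt))
    if (length(coerced)) {
      message(sprintf("indicator '%s': %d non-numeric value(s) (e.g. '%s') treated as missing",
                      meta$id[j], length(coerced), txt[coerced[1]]))
    }
    values[, j] <- num
  }
  indicator_table(values, meta, crisis_ids = crisis_ids)
}

#' Screen indicators by missingness
#'
#' Removes every indicator whose fraction of missing observations strictly
#' exceeds `threshold` (the index re-analysis removed three indicators with
#' more than 25\% missing), and reports the per-indicator missing fractions.
#'
#' @param table an [indicator_table()].
#' @param threshold missing-fraction cutoff in (0, 1); strict inequality,
#'   so an indicator missing exactly 25\% of observations is retained at
#'   the default.
#'
#' @return A list with elements `table` (the screened table) and `report`,
#'   a `missingness_report` containing `fractions` (named, all original
#'   indicators), `removed` and `threshold`.
#' @export
missingness_screen <- function(table, threshold = 0.25) {
  stopifnot(inherits(table, "indicator_table"))
  if (nrow(table$values) == 0L || ncol(table$values) == 0L) {
    stop("empty table")
  }
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0,1)")
  frac <- colMeans(is.na(table$values))
  removed <- names(frac)[frac > threshold]
  keep <- setdiff(colnames(table$values), removed)
  out <- indicator_table(table$values[, keep, drop = FALSE],
                         table$meta[match(keep, table$meta$id), , drop = FALSE],
                         crisis_ids = table$crisis_ids)
  report <- structure(
    list(fractions = frac, removed = removed, threshold = threshold),
    class = "missingness_report")
  list(table = out, report = report)
}

#' @export
print.missingness_report <- function(x, ...) {
  cat(sprintf("Missingness screen (threshold %.0f%%): %d of %d indicators removed\n",
              100 * x$threshold, length(x$removed), length(x$fractions)))
  if (length(x$removed)) {
    for (id in x$removed) {
      cat(sprintf("  - %s (%.0f%% missing)\n", id, 100 * x$fractions[[id]]))
    }
  }
  invisible(x)
}

#' Median-impute missing cells
#'
#' Replaces each missing cell with the median of its indicator's observed
#' values, the preparation used before exploratory factor analysis.
#' Observed cells are never altered; an even count of observed values
#' yields the midpoint of the two central order statistics, kept as-is
#' even when non-integral.
#'
#' @param table an [indicator_table()]; every indicator must have at least
#'   one observed value.
#'
#' @return A `prepared_matrix` with `preparation = "median_imputed"`.
#' @export
impute_median <- function(table) {
  stopifnot(inherits(table, "indicator_table"))
  v <- table$values
  for (j in seq_len(ncol(v))) {
    obs <- v[, j][!is.na(v[, j])]
    if (length(obs) == 0L) {
      stop("indicator '", colnames(v)[j], "' has no observed values")
    }
    v[is.na(v[, j]), j] <- stats::median(obs)
  }
  structure(list(values = v, preparation = "median_imputed",
                 center = NULL, scale = NULL),
            class = "prepared_matrix")
}

#' Standardize indicators to z-scores
#'
#' Centers and scales each indicator to sample mean 0 and sample standard
#' deviation 1 (n - 1 denominator) over its observed values, leaving
#' missing cells missing -- the preparation used before full-information
#' maximum-likelihood confirmatory factor analysis.
#'
#' @param table an [indicator_table()]; every indicator needs at least two
#'   distinct observed values.
#'
#' @return A `prepared_matrix` with `preparation = "standardized"` and the
#'   per-indicator `center` and `scale` used.
#' @export
standardize_indicators <- function(table) {
  stopifnot(inherits(table, "indicator_table"))
  v <- table$values
  ctr <- colMeans(v, na.rm = TRUE)
  scl <- apply(v, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(scl) | scl == 0)) {
    bad <- colnames(v)[!is.finite(scl) | scl == 0]
    stop("constant or empty indicator(s): ", paste(bad, collapse = ", "))
  }
  v <- sweep(sweep(v, 2, ctr), 2, scl, "/")
  structure(list(values = v, preparation = "standardized",
                 center = ctr, scale = scl),
            class = "prepared_matrix")
}

#' @export
print.prepared_matrix <- function(x, ...) {
  cat("Prepared matrix (", x$preparation, "): ", nrow(x$values), " x ",
      ncol(x$values), "\n", sep = "")
  invisible(x)
}

#' Inter-indicator correlation matrix
#'
#' Spearman (default) or Pearson correlations between indicators, using
#' pairwise-complete observations when missing cells are present. Entries
#' with fewer than three complete pairs are returned as `NA`.
#'
#' @param x an [indicator_table()] (raw values, pairwise complete) or a
#'   `prepared_matrix`.
#' @param method `"spearman"` or `"pearson"`.
#'
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
indicator_correlations <- function(x, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  v <- if (inherits(x, "indicator_table")) x$values
       else if (inherits(x, "prepared_matrix")) x$values
       else as.matrix(x)
  if (nrow(v) < 3L) stop("need at least 3 rows")
  r <- suppressWarnings(
    stats::cor(v, use = "pairwise.complete.obs", method = method))
  obs <- !is.na(v)
  npairs <- crossprod(obs)
  r[npairs < 3] <- NA_real_
  diag(r) <- 1
  r
}

#' Fraction of strongly correlated indicator pairs
#'
#' Proportion of off-diagonal indicator pairs whose correlation exceeds
#' `cutoff` in absolute value (the 2019 crisis table has roughly 31\% of
#' pairs with |r| > 0.6).
#'
#' @param r a correlation matrix.
#' @param cutoff absolute correlation cutoff.
#' @return A single fraction in \[0, 1\], computed over non-`NA` pairs.
#' @export
high_correlation_fraction <- function(r, cutoff = 0.6) {
  lo <- r[lower.tri(r)]
  lo <- lo[!is.na(lo)]
  if (!length(lo)) return(NA_real_)
  mean(abs(lo) > cutoff)
}

#' Per-indicator descriptive statistics
#'
#' Mean, standard deviation (n - 1), median, range and number of observed
#' values per indicator, computed over observed values only (never imputed
#' ones).
#'
#' @param table an [indicator_table()].
#' @return A `data.frame` with columns `id`, `pillar`, `mean`, `sd`,
#'   `median`, `min`, `max`, `n`. All-missing indicators get `n = 0` and
#'   `NA` statistics.
#' @export
describe_indicators <- function(table) {
  stopifnot(inherits(table, "indicator_table"))
  v <- table$values
  out <- lapply(seq_len(ncol(v)), function(j) {
    obs <- v[, j][!is.na(v[, j])]
    if (!length(obs)) {
      data.frame(id = colnames(v)[j], pillar = table$meta$pillar[j],
                 mean = NA_real_, sd = NA_real_, median = NA_real_,
                 min = NA_real_, max = NA_real_, n = 0L)
    } else {
      data.frame(id = colnames(v)[j], pillar = table$meta$pillar[j],
                 mean = mean(obs), sd = stats::sd(obs),
                 median = stats::median(obs),
                 min = min(obs), max = max(obs), n = length(obs))
    }
  })
  do.call(rbind, out)
}
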