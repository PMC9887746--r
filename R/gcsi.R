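#' Population distribution over humanitarian-condition levels
#'
#' The conditions pillar classifies a population into five levels of
#' humanitarian conditions, from level 1 (none/minor) to level 5 (extreme).
#' This constructor holds the per-level population shares and, optionally,
#' absolute counts.
#'
#' @param shares numeric length-5 vector of population fractions in levels
#'   1--5; an unclassified remainder is allowed, so the shares may sum to
#'   less than 1.
#' @param counts optional length-5 vector of absolute population counts.
#' @param population_total optional total population count; when given
#'   together with `counts`, the two must agree with `shares` up to 0.5\%.
#'
#' @return An object of class `conditions_distribution`.
#' @export
conditions_distribution <- function(shares = NULL, counts = NULL,
                                    population_total = NULL) {
  if (is.null(shares) && is.null(counts)) {
    stop("provide shares and/or counts")
  }
  if (is.null(shares)) {
    if (is.null(population_total)) population_total <- sum(counts)
    shares <- counts / population_total
  }
  shares <- as.numeric(shares)
  if (length(shares) != 5L) stop("shares must have length 5 (levels 1-5)")
  if (any(shares < 0 | shares > 1)) stop("shares must lie in [0,1]")
  if (sum(shares) > 1 + 1e-9) stop("shares sum to more than 1")
  if (!is.null(counts) && !is.null(population_total)) {
    implied <- counts / population_total
    if (any(abs(implied - shares) > 0.005)) {
      stop("counts inconsistent with shares x population_total")
    }
  }
  structure(list(shares = shares, counts = counts,
                 population_total = population_total),
            class = "conditions_distribution")
}

#' Impact-of-the-crisis pillar
#'
#' The impact pillar is a weighted sum of a human-impact composite
#' (weight 0.7) and a geographical-impact composite (weight 0.3). Each
#' composite is the arithmetic mean of its available sub-indicators;
#' missing sub-indicators are ignored.
#'
#' @param human_subs up to four human-impact sub-indicator values on the
#'   0--5 scale; `NA` allowed.
#' @param geo_subs two geographical-impact sub-indicator values.
#' @param weights weights for (human, geographical); must sum to 1.
#' @return Pillar score on the 0--5 scale.
#' @export
impact_pillar <- function(human_subs, geo_subs, weights = c(0.7, 0.3)) {
  if (all(is.na(human_subs))) stop("no human-impact data available")
  stopifnot(abs(sum(weights) - 1) < 1e-9)
  human <- mean(human_subs, na.rm = TRUE)
  geo <- mean(geo_subs, na.rm = TRUE)
  weights[1] * human + weights[2] * geo
}

#' Complexity-of-the-crisis pillar
#'
#' The complexity pillar is the geometric mean of a society-and-safety
#' composite (mean of its available sub-indicators) and an
#' operating-environment composite (average of a sub-indicator aggregate
#' and a data input). If either composite is zero the geometric mean
#' degenerates to zero, which is returned with a warning.
#'
#' @param society_safety either the composite value itself or a vector of
#'   sub-indicator values to be averaged (missing ignored).
#' @param operating_env the composite value, or a vector whose mean is
#'   taken (use [operating_env_composite()] to build it from raw parts).
#' @return Pillar score on the 0--5 scale.
#' @export
complexity_pillar <- function(society_safety, operating_env) {
  ss <- mean(society_safety, na.rm = TRUE)
  oe <- mean(operating_env, na.rm = TRUE)
  if (is.na(ss) || is.na(oe)) stop("both composites need at least one value")
  if (ss < 0 || oe < 0) stop("composites must be non-negative")
  if (xor(ss == 0, oe == 0)) {
    warning("one complexity composite is zero; geometric mean degenerates to 0")
    return(0)
  }
  sqrt(ss * oe)
}

#' Operating-environment composite
#'
#' Averages the operating-environment sub-indicator aggregate with its
#' data input. The sub-indicator aggregate is the sum of its contributing
#' variables; when more than two variables contribute, the sum is rescaled
#' linearly from its natural range (`k` variables on a 0--`var_max` scale)
#' to 0--5.
#'
#' @param sub_vars contributing sub-indicator variables (missing ignored).
#' @param data_input the accompanying data-input value on the 0--5 scale.
#' @param var_max upper bound of each contributing variable's scale.
#' @return Composite value on the 0--5 scale.
#' @export
operating_env_composite <- function(sub_vars, data_input, var_max = 3) {
  sub_vars <- sub_vars[!is.na(sub_vars)]
  k <- length(sub_vars)
  if (k == 0L) stop("no operating-environment sub-variables available")
  agg <- if (k > 2) sum(sub_vars) / (var_max * k) * 5 else sum(sub_vars)
  mean(c(agg, data_input), na.rm = TRUE)
}

#' Conditions of the affected population: highest level above 5\%
#'
#' Returns the highest humanitarian-conditions level whose share of the
#' affected population strictly exceeds the threshold (default 5\%); if no
#' level exceeds it, level 1 is returned. In the Somalia walkthrough,
#' 11.5\% of the affected population in level 3 (and no higher level above
#' 5\%) yields level 3.
#'
#' @param dist a [conditions_distribution()] for the affected population.
#' @param threshold share that must be strictly exceeded; default 0.05.
#' @return An integer level in 1--5.
#' @export
conditions_affected_level <- function(dist, threshold = 0.05) {
  stopifnot(inherits(dist, "conditions_distribution"))
  if (all(dist$shares == 0)) stop("all level shares are zero")
  above <- which(dist$shares > threshold)
  if (!length(above)) return(1L)
  as.integer(max(above))
}

#' Conditions of the total population: ranked people-in-need count
#'
#' Sums the people in levels 3--5 and maps the sum through an ascending
#' ladder of count thresholds to an ordinal 0--5 score: the score is the
#' number of thresholds the sum strictly exceeds (a sum exactly equal to a
#' threshold stays in the lower bin).
#'
#' @param dist a [conditions_distribution()] for the total population, with
#'   counts (or shares plus `population_total`) for levels 3--5.
#' @param bins strictly ascending numeric vector of five count thresholds.
#' @return Integer score 0--5.
#' @export
conditions_total_score <- function(dist,
                                   bins = c(1e4, 1e5, 1e6, 5e6, 2e7)) {
  stopifnot(inherits(dist, "conditions_distribution"))
  if (length(bins) != 5L || any(diff(bins) <= 0)) {
    stop("bins must be five strictly ascending thresholds")
  }
  counts <- dist$counts
  if (is.null(counts)) {
    if (is.null(dist$population_total)) {
      stop("counts (or shares plus population_total) required for levels 3-5")
    }
    counts <- dist$shares * dist$population_total
  }
  if (any(is.na(counts[3:5]))) stop("counts for levels 3-5 are missing")
  total_in_need <- sum(counts[3:5])
  sum(total_in_need > bins)
}

#' Conditions-of-the-people pillar
#'
#' Arithmetic mean of the two conditions sub-indicators: the ranked
#' people-in-need score for the total population and the
#' highest-level-above-5\% score for the affected population.
#'
#' @param total_dist,affected_dist [conditions_distribution()] objects for
#'   the total and affected populations.
#' @param bins passed to [conditions_total_score()].
#' @param threshold passed to [conditions_affected_level()].
#' @return Pillar score on the 0--5 scale.
#' @export
conditions_pillar <- function(total_dist, affected_dist,
                              bins = c(1e4, 1e5, 1e6, 5e6, 2e7),
                              threshold = 0.05) {
  mean(c(conditions_total_score(total_dist, bins),
         conditions_affected_level(affected_dist, threshold)))
}

#' Final severity score from pillar values
#'
#' The index's headline number: a weighted mean of the three pillar
#' scores, by default 0.2 x impact + 0.3 x complexity + 0.5 x conditions,
#' with an optional categorical label from one-unit severity bands.
#'
#' @param impact,complexity,conditions pillar scores on the 0--5 scale.
#' @param weights weights for (impact, complexity, conditions); must sum
#'   to 1 within 1e-9.
#' @param labels character vector of band labels applied at one-unit steps
#'   (band `i` covers scores in `[i-1, i)`, the top band closed), or
#'   `NULL` for no label.
#' @return An object of class `gcsi_score` with the pillar values, the
#'   weighted `severity` and its `category` label.
#' @export
severity_score <- function(impact, complexity, conditions,
                           weights = c(0.2, 0.3, 0.5),
                           labels = c("Very Low", "Low", "Medium",
                                      "High", "Very High")) {
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  pillars <- c(impact = impact, complexity = complexity,
               conditions = conditions)
  sev <- sum(weights * pillars)
  category <- if (is.null(labels)) NA_character_ else {
    band <- min(max(floor(sev) + 1, 1), length(labels))
    labels[band]
  }
  structure(list(impact = impact, complexity = complexity,
                 conditions = conditions, weights = weights,
                 severity = sev, category = category),
            class = "gcsi_score")
}

#' @export
print.gcsi_score <- function(x, ...) {
  cat(sprintf("Severity %.2f (%s)\n", x$severity,
              ifelse(is.na(x$category), "unlabelled", x$category)))
  cat(sprintf("  impact     %.2f (w = %.1f)\n", x$impact, x$weights[1]))
  cat(sprintf("  complexity %.2f (w = %.1f)\n", x$complexity, x$weights[2]))
  cat(sprintf("  conditions %.2f (w = %.1f)\n", x$conditions, x$weights[3]))
  invisible(x)
}

#' Score a batch of crises
#'
#' Applies [severity_score()] row-wise to a data frame of pillar values.
#'
#' @param pillars data frame with columns `impact`, `complexity`,
#'   `conditions` and optionally a crisis id in the first column.
#' @param weights,labels passed to [severity_score()].
#' @return A data frame with the input columns plus `severity` and
#'   `category`.
#' @export
score_crises <- function(pillars, weights = c(0.2, 0.3, 0.5),
                         labels = c("Very Low", "Low", "Medium",
                                    "High", "Very High")) {
  stopifnot(all(c("impact", "complexity", "conditions") %in% names(pillars)))
  scored <- lapply(seq_len(nrow(pillars)), function(i) {
    s <- severity_score(pillars$impact[i], pillars$complexity[i],
                        pillars$conditions[i], weights, labels)
    data.frame(severity = s$severity, category = s$category,
               stringsAsFactors = FALSE)
  })
  cbind(pillars, do.call(rbind, scored))
}
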