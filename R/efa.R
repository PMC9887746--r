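#' Eigenvalues for a scree inspection
#'
#' Descending eigenvalues of a correlation matrix; their sum equals the
#' number of indicators.
#'
#' @param r symmetric correlation matrix with unit diagonal.
#' @return Numeric vector of eigenvalues, descending.
#' @export
scree_eigenvalues <- function(r) {
  r <- as.matrix(r)
  if (!isSymmetric(unname(r), tol = 1e-8)) stop("matrix is not symmetric")
  sort(eigen(r, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

## Maximum-likelihood factor extraction on a correlation matrix.
## Profiles the loadings out of the likelihood: for fixed uniquenesses psi
## the optimal loadings come from the leading eigenpairs of
## diag(psi)^{-1/2} R diag(psi)^{-1/2}, leaving a k-independent objective
## over psi that is minimized by L-BFGS-B with its analytic gradient.
.efa_objective <- function(psi, r, k) {
  sc <- 1 / sqrt(psi)
  rs <- r * tcrossprod(sc)
  e <- eigen(rs, symmetric = TRUE, only.values = TRUE)$values
  tail_e <- e[-seq_len(k)]
  sum(tail_e - log(tail_e)) - (length(e) - k)
}

.efa_gradient <- function(psi, r, k) {
  sc <- 1 / sqrt(psi)
  rs <- r * tcrossprod(sc)
  e <- eigen(rs, symmetric = TRUE)
  lam <- sqrt(pmax(e$values[seq_len(k)] - 1, 0))
  load <- sqrt(psi) * e$vectors[, seq_len(k), drop = FALSE] %*% diag(lam, k)
  g <- tcrossprod(load) + diag(psi) - r
  diag(g) / psi^2
}

.efa_extract <- function(r, k, psi_floor = 0.005, maxit = 1000) {
  p <- ncol(r)
  if ((p - k)^2 < p + k) {
    stop("k = ", k, " factors exceed the Ledermann bound for p = ", p)
  }
  start <- (1 - 0.5 * k / p) / diag(solve(r))
  start <- pmin(pmax(start, psi_floor + 1e-4), 1)
  run <- function(s, factr) {
    stats::optim(s, .efa_objective, .efa_gradient,
                 r = r, k = k, method = "L-BFGS-B",
                 lower = psi_floor, upper = 1,
                 control = list(maxit = maxit, factr = factr,
                                parscale = rep(0.01, p)))
  }
  opt <- run(start, 100)
  if (opt$convergence != 0) {
    ## retry from the returned point at a looser line-search tolerance
    opt2 <- run(opt$par, 1e7)
    if (opt2$value <= opt$value) opt <- opt2
  }
  converged <- opt$convergence == 0
  if (!converged) {
    ## the line search can stall at a boundary-heavy optimum (common for
    ## overfactored solutions); accept if the KKT conditions hold
    g <- .efa_gradient(opt$par, r, k)
    at_lo <- opt$par <= psi_floor + 1e-8
    at_hi <- opt$par >= 1 - 1e-8
    kkt <- all(abs(g[!at_lo & !at_hi]) < 1e-3) &&
      all(g[at_lo] > -1e-3) && all(g[at_hi] < 1e-3)
    converged <- kkt
  }
  psi <- opt$par
  heywood <- any(psi <= psi_floor + 1e-6)
  sc <- 1 / sqrt(psi)
  e <- eigen(r * tcrossprod(sc), symmetric = TRUE)
  lam <- sqrt(pmax(e$values[seq_len(k)] - 1, 0))
  load <- sqrt(psi) * e$vectors[, seq_len(k), drop = FALSE] %*% diag(lam, k)
  list(loadings = load, uniquenesses = psi, criterion = opt$value,
       converged = converged, heywood = heywood)
}

## Direct quartimin (oblimin with gamma = 0): value and gradient of the
## rotation criterion at a pattern matrix.
.quartimin_vg <- function(L) {
  L2 <- L^2
  k <- ncol(L)
  M <- matrix(1, k, k) - diag(k)
  X <- L2 %*% M
  list(f = sum(L2 * X) / 4, G = L * X)
}

## Gradient-projection algorithm for oblique rotation (quartimin
## criterion). Columns of the rotation matrix are kept at unit length so
## the factor correlation matrix t(T) %*% T has a unit diagonal.
.rotate_quartimin <- function(A, Tmat = diag(ncol(A)),
                              eps = 1e-8, maxit = 2000) {
  if (ncol(A) < 2) {
    return(list(loadings = A, Phi = diag(1), Tmat = diag(1),
                converged = TRUE))
  }
  al <- 1
  L <- A %*% t(solve(Tmat))
  vg <- .quartimin_vg(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$G %*% solve(Tmat))
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(A))
    s <- sqrt(sum(Gp^2))
    if (s < eps) { converged <- TRUE; break }
    al <- 2 * al
    for (half in 0:20) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(A))
      Lt <- A %*% t(solve(Tt))
      vgt <- .quartimin_vg(Lt)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    L <- Lt
    f <- vgt$f
    G <- -t(t(L) %*% vgt$G %*% solve(Tmat))
  }
  list(loadings = L, Phi = crossprod(Tmat), Tmat = Tmat,
       converged = converged)
}

## Canonicalize an oblique solution: order factors by descending
## SS loadings and flip signs so each factor's largest-|loading| indicator
## loads positively. Removes rotation indeterminacy for reporting/tests.
.canonicalize <- function(pattern, Phi) {
  structure_m <- pattern %*% Phi
  ss <- colSums(pattern * structure_m)
  ord <- order(ss, decreasing = TRUE)
  pattern <- pattern[, ord, drop = FALSE]
  Phi <- Phi[ord, ord, drop = FALSE]
  signs <- vapply(seq_len(ncol(pattern)), function(j) {
    v <- pattern[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  signs[signs == 0] <- 1
  pattern <- sweep(pattern, 2, signs, "*")
  Phi <- diag(signs, ncol(Phi)) %*% Phi %*% diag(signs, ncol(Phi))
  list(pattern = pattern, Phi = Phi)
}

#' Maximum-likelihood exploratory factor analysis with oblimin rotation
#'
#' Fits a k-factor maximum-likelihood factor model to the Pearson
#' correlation matrix of a complete (typically median-imputed) indicator
#' matrix and applies a direct-quartimin (oblimin, gamma = 0) oblique
#' rotation, so factors may correlate. Factors are ordered by descending
#' sums of squared loadings and sign-anchored for reproducibility.
#'
#' Variance accounting follows the oblique convention: per-factor sums of
#' squared loadings are column sums of pattern * structure (structure =
#' pattern \%*\% Phi), and proportions are those sums divided by the number
#' of indicators.
#'
#' @param x a `prepared_matrix` (median-imputed), a complete numeric data
#'   matrix, or a correlation matrix (square, symmetric, unit diagonal).
#' @param factors number of factors k (>= 1, below the Ledermann bound).
#' @param rotation `"oblimin"` (direct quartimin) or `"none"`.
#' @param n_obs number of observations; required only when `x` is a
#'   correlation matrix and a solution summary mentioning n is wanted.
#'
#' @return An object of class `efa_ml` with components `loadings`
#'   (pattern), `structure`, `Phi` (factor correlations), `uniquenesses`,
#'   `ss_loadings`, `proportion_var`, `cumulative_var`, `eigenvalues`,
#'   `factors`, `converged` and `heywood`.
#' @export
efa_ml <- function(x, factors, rotation = c("oblimin", "none"),
                   n_obs = NULL) {
  rotation <- match.arg(rotation)
  if (inherits(x, "prepared_matrix")) x <- x$values
  x <- as.matrix(x)
  is_corr <- nrow(x) == ncol(x) &&
    isSymmetric(unname(x), tol = 1e-8) &&
    all(abs(diag(x) - 1) < 1e-8)
  if (is_corr) {
    r <- unname(x)
    dimnames(r) <- dimnames(x)
  } else {
    if (anyNA(x)) stop("data matrix must be complete; impute first")
    n_obs <- nrow(x)
    r <- stats::cor(x)
  }
  p <- ncol(r)
  ext <- .efa_extract(r, factors)
  if (!ext$converged) stop("ML extraction did not converge")
  if (ext$heywood) {
    warning("Heywood case: uniqueness at lower bound for some indicator(s)")
  }
  A <- ext$loadings
  if (rotation == "oblimin" && factors > 1) {
    rot <- .rotate_quartimin(A)
    if (!rot$converged) warning("quartimin rotation did not fully converge")
    pattern <- rot$loadings
    Phi <- rot$Phi
  } else {
    pattern <- A
    Phi <- diag(factors)
  }
  can <- .canonicalize(pattern, Phi)
  pattern <- can$pattern
  Phi <- can$Phi
  rownames(pattern) <- colnames(r)
  colnames(pattern) <- paste0("F", seq_len(factors))
  dimnames(Phi) <- list(colnames(pattern), colnames(pattern))
  structure_m <- pattern %*% Phi
  ss <- colSums(pattern * structure_m)
  structure(list(
    loadings = pattern,
    structure = structure_m,
    Phi = Phi,
    uniquenesses = stats::setNames(ext$uniquenesses, colnames(r)),
    ss_loadings = ss,
    proportion_var = ss / p,
    cumulative_var = cumsum(ss / p),
    eigenvalues = scree_eigenvalues(r),
    correlation = r,
    factors = factors,
    n_obs = n_obs,
    criterion = ext$criterion,
    converged = ext$converged,
    heywood = ext$heywood,
    rotation = rotation,
    call = match.call()
  ), class = "efa_ml")
}

#' Model-implied correlation matrix of an EFA solution
#'
#' @param object an `efa_ml` fit.
#' @param ... unused.
#' @return The implied correlation matrix pattern Phi pattern' + diag(psi).
#' @export
fitted.efa_ml <- function(object, ...) {
  imp <- object$loadings %*% object$Phi %*% t(object$loadings) +
    diag(object$uniquenesses)
  dimnames(imp) <- dimnames(object$correlation)
  imp
}

#' @export
residuals.efa_ml <- function(object, ...) {
  object$correlation - fitted(object)
}

#' @export
coef.efa_ml <- function(object, ...) object$loadings

#' @export
print.efa_ml <- function(x, cutoff = 0.30, digits = 2, ...) {
  cat(sprintf("ML EFA, %d factors, %s rotation%s\n", x$factors, x$rotation,
              if (x$heywood) " (Heywood warning)" else ""))
  L <- round(x$loadings, digits)
  out <- format(L)
  out[abs(x$loadings) < cutoff] <- ""
  print(out, quote = FALSE)
  tab <- rbind(`SS loadings` = x$ss_loadings,
               `Proportion Var` = x$proportion_var,
               `Cumulative Var` = x$cumulative_var)
  print(round(tab, digits))
  if (x$factors > 1) {
    cat("Factor correlations:\n")
    print(round(x$Phi, digits))
  }
  invisible(x)
}

#' @export
summary.efa_ml <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' Scree plot of an EFA's input correlation matrix
#'
#' @param x an `efa_ml` fit.
#' @param ... passed to [plot()].
#' @export
plot.efa_ml <- function(x, ...) {
  plot(seq_along(x$eigenvalues), x$eigenvalues, type = "b",
       xlab = "Component", ylab = "Eigenvalue", main = "Scree", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Factor-retention report across candidate solutions
#'
#' Applies the three retention criteria used in the index re-analysis to a
#' set of solutions with different factor counts: every factor must have
#' sums of squared loadings above `ss_min` (1.0), every factor must
#' explain at least `prop_min` (10\%) of the overall variance, and the
#' factors jointly must explain at least `cum_min` (60\%).
#'
#' @param solutions list of `efa_ml` fits over the same indicators.
#' @param ss_min,prop_min,cum_min criterion cutoffs.
#' @return An object of class `efa_retention`: a data frame with one row
#'   per solution (`factors`, `all_ss_pass`, `all_prop_pass`,
#'   `cumulative`, `cum_pass`), per-factor detail in
#'   `attr(, "per_factor")`, and `attr(, "recommended")` -- the factor
#'   counts whose factors all pass both per-factor rules.
#' @export
efa_retention <- function(solutions, ss_min = 1.0, prop_min = 0.10,
                          cum_min = 0.60) {
  stopifnot(length(solutions) >= 1)
  ids <- lapply(solutions, function(s) rownames(s$loadings))
  if (!all(vapply(ids, identical, logical(1), ids[[1]]))) {
    stop("solutions must share the same indicator set")
  }
  per_factor <- do.call(rbind, lapply(solutions, function(s) {
    data.frame(factors = s$factors, factor = seq_len(s$factors),
               ss_loadings = unname(s$ss_loadings),
               proportion = unname(s$proportion_var),
               ss_pass = unname(s$ss_loadings > ss_min),
               prop_pass = unname(s$proportion_var >= prop_min))
  }))
  tab <- do.call(rbind, lapply(solutions, function(s) {
    data.frame(factors = s$factors,
               all_ss_pass = all(s$ss_loadings > ss_min),
               all_prop_pass = all(s$proportion_var >= prop_min),
               cumulative = max(s$cumulative_var),
               cum_pass = max(s$cumulative_var) >= cum_min)
  }))
  recommended <- tab$factors[tab$all_ss_pass & tab$all_prop_pass]
  structure(tab, per_factor = per_factor, recommended = recommended,
            cutoffs = c(ss_min = ss_min, prop_min = prop_min,
                        cum_min = cum_min),
            class = c("efa_retention", "data.frame"))
}

#' @export
print.efa_retention <- function(x, ...) {
  cat("Factor-retention report\n")
  print.data.frame(x, row.names = FALSE)
  rec <- attr(x, "recommended")
  cat("Solutions passing both per-factor rules:",
      if (length(rec)) paste(rec, collapse = ", ") else "none", "\n")
  invisible(x)
}

.prune_one <- function(sol, load_min, cross_gap) {
  L <- sol$loadings
  reasons <- character(nrow(L))
  names(reasons) <- rownames(L)
  for (i in seq_len(nrow(L))) {
    a <- abs(L[i, ])
    ord <- order(a, decreasing = TRUE)
    primary <- a[ord[1]]
    secondary <- if (ncol(L) > 1) a[ord[2]] else 0
    big <- which(a >= load_min)
    if (primary < load_min) {
      reasons[i] <- "low_loading"
    } else if (length(big) >= 2 &&
               any(sign(L[i, big]) > 0) && any(sign(L[i, big]) < 0)) {
      reasons[i] <- "sign_conflict"
    } else if (secondary >= load_min && (primary - secondary) < cross_gap) {
      reasons[i] <- "cross_loading"
    }
  }
  reasons
}

#' Prune indicators using the cross-solution loading rules
#'
#' Removes indicators that fail the loading rules in either of two
#' exploratory solutions (typically the 3- and 4-factor fits): a maximum
#' absolute pattern loading below `load_min` (0.30); a cross-loading,
#' operationalized as a secondary loading at or above `load_min` within
#' `cross_gap` (0.20) of the primary; or loadings of opposite sign, both
#' at or above `load_min`, on two factors (e.g. 0.37 and -0.33).
#'
#' @param sol_a,sol_b two `efa_ml` fits over the same indicators.
#' @param load_min display/removal loading threshold.
#' @param cross_gap maximum primary-secondary gap that still counts as a
#'   cross-loading.
#' @return An object of class `efa_prune`: data frame of removals with
#'   columns `id`, `reason`, `solution`; retained ids in
#'   `attr(, "retained")`.
#' @export
efa_prune <- function(sol_a, sol_b, load_min = 0.30, cross_gap = 0.20) {
  if (!identical(rownames(sol_a$loadings), rownames(sol_b$loadings))) {
    stop("solutions cover different indicator sets")
  }
  ra <- .prune_one(sol_a, load_min, cross_gap)
  rb <- .prune_one(sol_b, load_min, cross_gap)
  ids <- rownames(sol_a$loadings)
  rows <- list()
  for (id in ids) {
    if (nzchar(ra[[id]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, reason = ra[[id]], solution = sol_a$factors)
    }
    if (nzchar(rb[[id]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, reason = rb[[id]], solution = sol_b$factors)
    }
  }
  removed <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), reason = character(),
               solution = integer())
  retained <- setdiff(ids, removed$id)
  structure(removed, retained = retained,
            load_min = load_min, cross_gap = cross_gap,
            class = c("efa_prune", "data.frame"))
}

#' @export
print.efa_prune <- function(x, ...) {
  cat(sprintf("Indicator pruning (|loading| >= %.2f, cross-loading gap < %.2f)\n",
              attr(x, "load_min"), attr(x, "cross_gap")))
  if (nrow(x)) print.data.frame(x, row.names = FALSE) else
    cat("  no removals\n")
  cat("Retained:", length(attr(x, "retained")), "indicator(s)\n")
  invisible(x)
}
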