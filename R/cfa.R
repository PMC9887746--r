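#' Specify a confirmatory factor model
#'
#' Declares the measurement model fitted by [cfa_fiml()]: a partition of
#' indicators into latent constructs (simple structure -- each indicator
#' loads on exactly one construct), optional within-construct residual
#' covariances, and optionally a second-order factor that loads on every
#' first-order construct.
#'
#' Identification: all first-order construct variances are fixed to 1, so
#' loadings are reported on the correlation metric directly. With a
#' second-order factor its variance is fixed to 1 and the first-order
#' disturbance variances are constrained so each first-order construct
#' keeps unit total variance; with exactly three first-order constructs
#' the second-order structure is just-identified.
#'
#' @param constructs named list mapping construct names to character
#'   vectors of indicator ids.
#' @param residual_covariances list of length-2 character vectors; each
#'   pair must be two distinct indicators of the same construct.
#' @param second_order `FALSE`, or the name of the second-order factor
#'   (e.g. `"severity"`); requires at least three first-order constructs.
#'
#' @return An object of class `cfa_model`.
#' @export
cfa_model <- function(constructs, residual_covariances = list(),
                      second_order = FALSE) {
  stopifnot(is.list(constructs), length(constructs) >= 1,
            !is.null(names(constructs)))
  indicators <- unlist(constructs, use.names = FALSE)
  if (anyDuplicated(indicators)) {
    stop("each indicator must appear in exactly one construct")
  }
  membership <- rep(names(constructs), lengths(constructs))
  names(membership) <- indicators
  for (pr in residual_covariances) {
    if (length(pr) != 2 || pr[1] == pr[2]) {
      stop("residual covariance pairs must be two distinct indicators")
    }
    if (!all(pr %in% indicators)) {
      stop("residual covariance names unknown indicator: ",
           paste(setdiff(pr, indicators), collapse = ", "))
    }
    if (membership[[pr[1]]] != membership[[pr[2]]]) {
      stop("residual covariances must link indicators of the same construct")
    }
  }
  so_name <- FALSE
  if (!isFALSE(second_order)) {
    if (isTRUE(second_order)) second_order <- "severity"
    if (length(constructs) < 3) {
      stop("a second-order factor needs at least 3 first-order constructs ",
           "to be identified")
    }
    so_name <- second_order
  }
  structure(list(constructs = constructs,
                 residual_covariances = residual_covariances,
                 second_order = so_name,
                 indicators = indicators,
                 membership = membership),
            class = "cfa_model")
}

#' @export
print.cfa_model <- function(x, ...) {
  cat("CFA model:", length(x$indicators), "indicators,",
      length(x$constructs), "construct(s)\n")
  for (nm in names(x$constructs)) {
    cat("  ", nm, ": ", paste(x$constructs[[nm]], collapse = ", "), "\n",
        sep = "")
  }
  if (length(x$residual_covariances)) {
    cat("  residual covariances: ",
        paste(vapply(x$residual_covariances,
                     function(p) paste(p, collapse = "~~"), ""),
              collapse = ", "), "\n", sep = "")
  }
  if (!isFALSE(x$second_order)) {
    cat("  second-order factor:", x$second_order, "\n")
  }
  invisible(x)
}

#' Add a second-order factor to a model specification
#'
#' Replaces the free first-order construct correlations by a single
#' second-order factor loading on every first-order construct. With three
#' first-order constructs this structure is just-identified, so the
#' second-order fit statistics equal those of the correlated first-order
#' model.
#'
#' @param spec a [cfa_model()] without a second-order factor.
#' @param name name of the second-order factor.
#' @return A new `cfa_model`.
#' @export
add_second_order <- function(spec, name = "severity") {
  stopifnot(inherits(spec, "cfa_model"))
  cfa_model(spec$constructs, spec$residual_covariances, second_order = name)
}

#' Parameter and degrees-of-freedom accounting for a model specification
#'
#' Counts observed moments (means plus unique covariances), free
#' parameters (loadings, residual variances, residual covariances,
#' construct correlations or second-order loadings, and indicator means)
#' and the resulting model degrees of freedom.
#'
#' @param spec a [cfa_model()].
#' @return Named numeric vector with `moments`, `free` and `df`.
#' @export
cfa_df <- function(spec) {
  stopifnot(inherits(spec, "cfa_model"))
  p <- length(spec$indicators)
  k <- length(spec$constructs)
  r <- length(spec$residual_covariances)
  structural <- if (isFALSE(spec$second_order)) k * (k - 1) / 2 else k
  moments <- p * (p + 3) / 2
  free <- p + p + r + structural + p
  c(moments = moments, free = free, df = moments - free)
}

## --- internal likelihood machinery ------------------------------------

## Group rows of a (possibly incomplete) matrix by missingness pattern and
## store per-pattern sufficient statistics: observed column set, count,
## mean vector and ML scatter matrix. The observed-data log-likelihood is
## then a sum of pattern-wise multivariate-normal terms, which makes each
## likelihood evaluation O(#patterns * p^3) rather than O(n * p^3).
.pattern_stats <- function(x) {
  obs <- !is.na(x)
  key <- apply(obs, 1, function(z) paste(as.integer(z), collapse = ""))
  lapply(split(seq_len(nrow(x)), key), function(idx) {
    o <- which(obs[idx[1], ])
    xo <- x[idx, o, drop = FALSE]
    n <- length(idx)
    m <- colMeans(xo)
    cen <- sweep(xo, 2, m)
    list(obs = o, n = n, m = m, S = crossprod(cen) / n, rows = idx)
  })
}

.fiml_loglik <- function(mu, Sigma, stats) {
  ll <- 0
  for (g in stats) {
    o <- g$obs
    ch <- tryCatch(chol(Sigma[o, o, drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    inv <- chol2inv(ch)
    d <- g$m - mu[o]
    quad <- sum(inv * g$S) + drop(crossprod(d, inv %*% d))
    ll <- ll - g$n / 2 *
      (length(o) * log(2 * pi) + 2 * sum(log(diag(ch))) + quad)
  }
  ll
}

## ML fit of the unrestricted (saturated) multivariate normal. Complete
## data: closed form. Missing data: EM iterations on pattern groups.
.saturated_mvn <- function(x, tol = 1e-9, maxit = 5000) {
  n <- nrow(x)
  p <- ncol(x)
  stats <- .pattern_stats(x)
  if (!anyNA(x)) {
    mu <- colMeans(x)
    Sigma <- crossprod(sweep(x, 2, mu)) / n
    return(list(mu = mu, Sigma = Sigma,
                loglik = .fiml_loglik(mu, Sigma, stats), iter = 0))
  }
  mu <- colMeans(x, na.rm = TRUE)
  v <- apply(x, 2, stats::var, na.rm = TRUE) * (n - 1) / n
  Sigma <- diag(v, p)
  ll_old <- .fiml_loglik(mu, Sigma, stats)
  for (it in seq_len(maxit)) {
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    for (g in stats) {
      o <- g$obs
      mis <- setdiff(seq_len(p), o)
      Xo <- x[g$rows, o, drop = FALSE]
      Xhat <- matrix(0, g$n, p)
      Xhat[, o] <- Xo
      Cadd <- matrix(0, p, p)
      if (length(mis)) {
        So_inv <- solve(Sigma[o, o, drop = FALSE])
        B <- Sigma[mis, o, drop = FALSE] %*% So_inv
        cond_cov <- Sigma[mis, mis, drop = FALSE] -
          B %*% Sigma[o, mis, drop = FALSE]
        Xhat[, mis] <- matrix(mu[mis], g$n, length(mis), byrow = TRUE) +
          sweep(Xo, 2, mu[o]) %*% t(B)
        Cadd[mis, mis] <- g$n * cond_cov
      }
      T1 <- T1 + colSums(Xhat)
      T2 <- T2 + crossprod(Xhat) + Cadd
    }
    mu_new <- T1 / n
    Sigma_new <- T2 / n - tcrossprod(mu_new)
    Sigma_new <- (Sigma_new + t(Sigma_new)) / 2
    ll <- .fiml_loglik(mu_new, Sigma_new, stats)
    mu <- mu_new
    Sigma <- Sigma_new
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sigma, loglik = ll_old, iter = it)
}

## Independence (baseline) model under FIML: with a diagonal covariance
## the likelihood factorizes, so each column's MLE is its observed-value
## mean and ML variance.
.baseline_mvn <- function(x) {
  ll <- 0
  for (j in seq_len(ncol(x))) {
    v <- x[, j][!is.na(x[, j])]
    m <- mean(v)
    s2 <- mean((v - m)^2)
    ll <- ll - length(v) / 2 * (log(2 * pi) + log(s2) + 1)
  }
  ll
}

## Map a construct-correlation matrix to/from the unconstrained
## row-normalized-Cholesky parameterization (guaranteed positive
## definite, unit diagonal).
.phi_from_z <- function(z, k) {
  L <- diag(k)
  idx <- 0
  for (i in seq_len(k)[-1]) {
    row <- c(z[idx + seq_len(i - 1)], 1)
    idx <- idx + i - 1
    L[i, seq_len(i)] <- row / sqrt(sum(row^2))
  }
  tcrossprod(L)
}

.z_from_phi <- function(Phi) {
  k <- ncol(Phi)
  if (k == 1) return(numeric(0))
  L <- t(chol(Phi))
  z <- numeric(0)
  for (i in seq_len(k)[-1]) {
    z <- c(z, L[i, seq_len(i - 1)] / L[i, i])
  }
  z
}

## Assemble the model-implied covariance and mean from the parameter
## vector. Layout: loadings (p), log residual variances (p), residual
## covariances (r), structural block (k(k-1)/2 correlations or k
## second-order atanh-loadings), then means (p, unless profiled).
.cfa_build <- function(par, layout) {
  p <- layout$p
  k <- layout$k
  lambda <- par[layout$i_lambda]
  psi <- exp(par[layout$i_logpsi])
  Lambda <- matrix(0, p, k)
  Lambda[cbind(seq_len(p), layout$construct_of)] <- lambda
  if (layout$second_order) {
    gamma <- tanh(par[layout$i_struct])
    Phi <- tcrossprod(gamma)
    diag(Phi) <- 1
  } else {
    gamma <- NULL
    Phi <- .phi_from_z(par[layout$i_struct], k)
  }
  Theta <- diag(psi, p)
  if (length(layout$i_rescov)) {
    rc <- par[layout$i_rescov]
    for (q in seq_along(rc)) {
      ij <- layout$rescov_idx[[q]]
      Theta[ij[1], ij[2]] <- Theta[ij[2], ij[1]] <- rc[q]
    }
  }
  Sigma <- Lambda %*% Phi %*% t(Lambda) + Theta
  mu <- if (is.null(layout$i_mu)) layout$mu_fixed else par[layout$i_mu]
  list(Lambda = Lambda, Phi = Phi, Theta = Theta, Sigma = Sigma,
       mu = mu, gamma = gamma, psi = psi)
}

.cfa_layout <- function(spec, x, profile_means) {
  p <- length(spec$indicators)
  k <- length(spec$constructs)
  construct_of <- match(spec$membership[spec$indicators],
                        names(spec$constructs))
  r <- length(spec$residual_covariances)
  rescov_idx <- lapply(spec$residual_covariances, function(pr) {
    sort(match(pr, spec$indicators))
  })
  n_struct <- if (isFALSE(spec$second_order)) k * (k - 1) / 2 else k
  i <- 0
  i_lambda <- i + seq_len(p); i <- i + p
  i_logpsi <- i + seq_len(p); i <- i + p
  i_rescov <- if (r) i + seq_len(r) else integer(0); i <- i + r
  i_struct <- if (n_struct) i + seq_len(n_struct) else integer(0)
  i <- i + n_struct
  i_mu <- NULL
  mu_fixed <- colMeans(x, na.rm = TRUE)
  if (!profile_means) { i_mu <- i + seq_len(p); i <- i + p }
  list(p = p, k = k, construct_of = construct_of,
       rescov_idx = rescov_idx,
       second_order = !isFALSE(spec$second_order),
       i_lambda = i_lambda, i_logpsi = i_logpsi, i_rescov = i_rescov,
       i_struct = i_struct, i_mu = i_mu, mu_fixed = mu_fixed,
       n_par = i)
}

.cfa_start <- function(layout, x) {
  par <- numeric(layout$n_par)
  par[layout$i_lambda] <- 0.5
  par[layout$i_logpsi] <- log(0.5)
  if (length(layout$i_rescov)) par[layout$i_rescov] <- 0
  if (length(layout$i_struct)) {
    if (layout$second_order) {
      par[layout$i_struct] <- atanh(0.5)
    } else {
      Phi0 <- matrix(0.2, layout$k, layout$k)
      diag(Phi0) <- 1
      par[layout$i_struct] <- .z_from_phi(Phi0)
    }
  }
  if (!is.null(layout$i_mu)) par[layout$i_mu] <- colMeans(x, na.rm = TRUE)
  par
}

#' Fit a confirmatory factor model by full-information maximum likelihood
#'
#' Maximizes the casewise observed-data log-likelihood: each crisis
#' contributes a multivariate-normal density over its observed indicators,
#' with model-implied mean and covariance, so missing cells are handled
#' without imputation. With complete data this reduces exactly to
#' complete-data maximum likelihood. The chi-square statistic is twice the
#' log-likelihood gap to the saturated model (fitted by EM when cells are
#' missing), the baseline for CFI/TLI is the independence model with free
#' means and variances, and RMSEA uses n - 1 scaling.
#'
#' @param spec a [cfa_model()].
#' @param data a `prepared_matrix` (typically standardized, missing cells
#'   allowed) or numeric matrix/data frame containing every indicator in
#'   `spec`; rows with no observed model indicator are dropped with a
#'   warning.
#' @param control list: `reltol` (default 1e-12), `maxit` (1000),
#'   `restarts` (5), `ndeps` (1e-5).
#'
#' @return An object of class `cfa_fiml` with the parameter estimates
#'   (`lambda`, `Phi`, `gamma`, `Theta`, `mu`), the standardized solution,
#'   log-likelihoods, `chisq`, `df`, baseline `chisq_b`/`df_b`, `cfi`,
#'   `tli`, `rmsea`, `n` and convergence/Heywood flags.
#' @export
cfa_fiml <- function(spec, data, control = list()) {
  stopifnot(inherits(spec, "cfa_model"))
  ctrl <- utils::modifyList(
    list(reltol = 1e-12, maxit = 1000, restarts = 5, ndeps = 1e-5),
    control)
  x <- if (inherits(data, "prepared_matrix")) data$values else
    as.matrix(data)
  missing_cols <- setdiff(spec$indicators, colnames(x))
  if (length(missing_cols)) {
    stop("data lacks indicator(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- x[, spec$indicators, drop = FALSE]
  empty <- rowSums(!is.na(x)) == 0
  if (any(empty)) {
    warning(sum(empty), " crisis(es) with no observed model indicator dropped")
    x <- x[!empty, , drop = FALSE]
  }
  n <- nrow(x)
  stats <- .pattern_stats(x)
  complete <- !anyNA(x)
  layout <- .cfa_layout(spec, x, profile_means = complete)
  negll <- function(par) {
    mod <- .cfa_build(par, layout)
    ll <- .fiml_loglik(mod$mu, mod$Sigma, stats)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  par <- .cfa_start(layout, x)
  val <- negll(par)
  converged <- FALSE
  for (round in seq_len(ctrl$restarts)) {
    opt <- stats::optim(par, negll, method = "BFGS",
                        control = list(maxit = ctrl$maxit,
                                       reltol = ctrl$reltol,
                                       ndeps = rep(ctrl$ndeps,
                                                   layout$n_par)))
    improved <- val - opt$value
    par <- opt$par
    val <- opt$value
    if (opt$convergence == 0 && improved < 1e-9) { converged <- TRUE; break }
    if (opt$convergence == 0 && round > 1 && improved < 1e-7) {
      converged <- TRUE; break
    }
  }
  if (!is.finite(val) || val >= 1e10) {
    stop("FIML optimization failed: implied covariance not positive ",
         "definite at the returned solution")
  }
  mod <- .cfa_build(par, layout)

  ## canonicalize construct signs: each construct's loadings sum positive
  for (c_idx in seq_len(layout$k)) {
    rows <- which(layout$construct_of == c_idx)
    if (sum(mod$Lambda[rows, c_idx]) < 0) {
      mod$Lambda[rows, c_idx] <- -mod$Lambda[rows, c_idx]
      if (layout$second_order) {
        mod$gamma[c_idx] <- -mod$gamma[c_idx]
      } else {
        mod$Phi[c_idx, -c_idx] <- -mod$Phi[c_idx, -c_idx]
        mod$Phi[-c_idx, c_idx] <- -mod$Phi[-c_idx, c_idx]
      }
    }
  }
  if (layout$second_order && sum(mod$gamma) < 0) mod$gamma <- -mod$gamma
  if (layout$second_order) {
    mod$Phi <- tcrossprod(mod$gamma)
    diag(mod$Phi) <- 1
  }

  loglik <- -val
  sat <- .saturated_mvn(x)
  ll_base <- .baseline_mvn(x)
  counts <- cfa_df(spec)
  p <- layout$p
  df_b <- p * (p + 3) / 2 - 2 * p
  chisq <- max(2 * (sat$loglik - loglik), 0)
  if (2 * (sat$loglik - loglik) < -1e-4) {
    stop("model log-likelihood exceeds the saturated log-likelihood; ",
         "numerical error")
  }
  chisq_b <- max(2 * (sat$loglik - ll_base), 0)
  idx <- cfa_fit_indices(chisq, counts[["df"]], chisq_b, df_b, n)

  lambda <- mod$Lambda[cbind(seq_len(p), layout$construct_of)]
  names(lambda) <- spec$indicators
  sd_ind <- sqrt(diag(mod$Sigma))
  std_lambda <- lambda / sd_ind
  dimnames(mod$Phi) <- list(names(spec$constructs), names(spec$constructs))
  dimnames(mod$Theta) <- list(spec$indicators, spec$indicators)
  if (layout$second_order) names(mod$gamma) <- names(spec$constructs)
  heywood <- any(mod$psi < 1e-4) || any(abs(std_lambda) > 1)

  structure(list(
    spec = spec,
    lambda = lambda,
    Lambda = mod$Lambda,
    Phi = mod$Phi,
    gamma = mod$gamma,
    Theta = mod$Theta,
    mu = stats::setNames(mod$mu, spec$indicators),
    Sigma = mod$Sigma,
    std_lambda = std_lambda,
    std_gamma = mod$gamma,
    loglik = loglik,
    loglik_sat = sat$loglik,
    loglik_base = ll_base,
    chisq = chisq, df = unname(counts[["df"]]),
    chisq_b = chisq_b, df_b = df_b,
    n_free = unname(counts[["free"]]),
    cfi = idx[["cfi"]], tli = idx[["tli"]], rmsea = idx[["rmsea"]],
    n = n,
    data = x,
    converged = converged,
    heywood = heywood,
    call = match.call()
  ), class = "cfa_fiml")
}

#' Incremental and absolute fit indices
#'
#' Computes CFI, TLI and RMSEA from model and baseline chi-square
#' statistics:
#' CFI = 1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, 0);
#' TLI = ((chisq_b/df_b) - (chisq/df)) / ((chisq_b/df_b) - 1);
#' RMSEA = sqrt(max(chisq - df, 0) / (df (n - 1))).
#'
#' @param chisq,df model chi-square and degrees of freedom.
#' @param chisq_b,df_b baseline (independence) model chi-square and df.
#' @param n number of observations entering the likelihood.
#' @return Named vector `cfi`, `tli`, `rmsea`.
#' @export
cfa_fit_indices <- function(chisq, df, chisq_b, df_b, n) {
  if (df_b <= df) warning("baseline df not larger than model df")
  d <- max(chisq - df, 0)
  db <- max(chisq_b - df_b, d, 0)
  cfi <- if (db == 0) 1 else 1 - d / db
  tli <- if (df == 0 || df_b == 0) NA_real_ else
    ((chisq_b / df_b) - (chisq / df)) / ((chisq_b / df_b) - 1)
  rmsea <- if (df == 0) 0 else sqrt(d / (df * (n - 1)))
  c(cfi = cfi, tli = tli, rmsea = rmsea)
}

#' @export
print.cfa_fiml <- function(x, digits = 3, ...) {
  so <- !isFALSE(x$spec$second_order)
  cat(sprintf("FIML CFA (%s): %d indicators, %d construct(s), n = %d\n",
              if (so) "second-order" else "first-order",
              length(x$lambda), length(x$spec$constructs), x$n))
  cat(sprintf("  chi-square %.2f on %d df (baseline %.2f on %d df)\n",
              x$chisq, x$df, x$chisq_b, x$df_b))
  cat(sprintf("  CFI %.3f  TLI %.3f  RMSEA %.3f\n", x$cfi, x$tli, x$rmsea))
  if (!x$converged) cat("  WARNING: optimizer not converged\n")
  if (x$heywood) cat("  WARNING: Heywood case\n")
  invisible(x)
}

#' @export
summary.cfa_fiml <- function(object, digits = 3, ...) {
  print(object, digits = digits)
  cat("Standardized loadings:\n")
  for (nm in names(object$spec$constructs)) {
    ids <- object$spec$constructs[[nm]]
    cat("  ", nm, "\n", sep = "")
    for (id in ids) {
      cat(sprintf("    %-30s %6.3f\n", id, object$std_lambda[[id]]))
    }
  }
  if (!is.null(object$gamma)) {
    cat("Second-order loadings on", object$spec$second_order, ":\n")
    for (nm in names(object$gamma)) {
      cat(sprintf("    %-30s %6.3f\n", nm, object$gamma[[nm]]))
    }
  } else {
    cat("Construct correlations:\n")
    print(round(object$Phi, digits))
  }
  invisible(object)
}

#' @export
coef.cfa_fiml <- function(object, standardized = FALSE, ...) {
  if (standardized) object$std_lambda else object$lambda
}

#' @export
logLik.cfa_fiml <- function(object, ...) {
  structure(object$loglik, df = object$n_free, nobs = object$n,
            class = "logLik")
}

#' @export
fitted.cfa_fiml <- function(object, ...) object$Sigma

#' Residual correlations of a fitted CFA
#'
#' Observed pairwise-complete Pearson correlations minus the model-implied
#' correlations, with pairs exceeding the modification cutoff flagged and
#' classified as within- or cross-construct. These flags drive
#' [modify_cfa()]: cross-construct offenders are removed, within-construct
#' offenders get a residual covariance.
#'
#' @param object a `cfa_fiml` fit.
#' @param cutoff absolute residual-correlation flag threshold.
#' @param ... unused.
#' @return An object of class `cfa_residuals`: the residual matrix with
#'   `attr(, "flags")`, a data frame of flagged pairs (`a`, `b`,
#'   `residual`, `scope`).
#' @export
residuals.cfa_fiml <- function(object, cutoff = 0.10, ...) {
  obs <- suppressWarnings(
    stats::cor(object$data, use = "pairwise.complete.obs"))
  imp <- stats::cov2cor(object$Sigma)
  dimnames(imp) <- dimnames(obs)
  res <- obs - imp
  ids <- colnames(res)
  flags <- list()
  for (i in seq_len(ncol(res) - 1)) {
    for (j in seq((i + 1), ncol(res))) {
      if (!is.na(res[i, j]) && abs(res[i, j]) > cutoff) {
        same <- object$spec$membership[[ids[i]]] ==
          object$spec$membership[[ids[j]]]
        flags[[length(flags) + 1L]] <- data.frame(
          a = ids[i], b = ids[j], residual = res[i, j],
          scope = if (same) "within" else "cross")
      }
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(a = character(), b = character(),
               residual = numeric(), scope = character())
  structure(res, flags = flags, cutoff = cutoff, class = "cfa_residuals")
}

#' @export
print.cfa_residuals <- function(x, ...) {
  fl <- attr(x, "flags")
  cat(sprintf("Residual correlations (flag cutoff %.2f): %d flagged pair(s)\n",
              attr(x, "cutoff"), nrow(fl)))
  if (nrow(fl)) print.data.frame(fl, row.names = FALSE)
  invisible(x)
}

#' Residual-driven model modification
#'
#' Iteratively refines a first-order measurement model using the residual
#' correlations of successive fits: at each step, if any cross-construct
#' pair has |residual| above `cutoff`, the more implicated indicator of
#' the worst pair is removed; otherwise, if any within-construct pair is
#' flagged, a residual covariance is added for the worst pair. One change
#' per refit; the loop stops when no pair is flagged, the budget is
#' exhausted, or a removal would leave a construct with fewer than two
#' indicators (warning).
#'
#' @param spec starting [cfa_model()].
#' @param data data passed to [cfa_fiml()].
#' @param cutoff residual-correlation threshold (0.10).
#' @param budget maximum number of modifications.
#' @param control passed to [cfa_fiml()].
#' @return A list with the final `spec`, final `fit`, and `log` -- a data
#'   frame recording each step (`step`, `action`, `target`, `residual`,
#'   `chisq`, `df`).
#' @export
modify_cfa <- function(spec, data, cutoff = 0.10, budget = 10,
                       control = list()) {
  stopifnot(inherits(spec, "cfa_model"))
  log_rows <- list()
  fit <- cfa_fiml(spec, data, control = control)
  for (step in seq_len(budget)) {
    fl <- attr(residuals(fit, cutoff = cutoff), "flags")
    if (!nrow(fl)) break
    cross <- fl[fl$scope == "cross", , drop = FALSE]
    if (nrow(cross)) {
      worst <- cross[which.max(abs(cross$residual)), ]
      ## remove whichever endpoint is more implicated across all
      ## cross-construct flags (ties: the one in the worst pair's 'a')
      load_a <- sum(abs(cross$residual[cross$a == worst$a |
                                         cross$b == worst$a]))
      load_b <- sum(abs(cross$residual[cross$a == worst$b |
                                         cross$b == worst$b]))
      target <- if (load_b > load_a) worst$b else worst$a
      constructs <- lapply(spec$constructs, setdiff, y = target)
      if (any(lengths(constructs) < 2)) {
        warning("removal of '", target,
                "' would leave a construct with < 2 indicators; stopping")
        break
      }
      rescov <- Filter(function(pr) !(target %in% pr),
                       spec$residual_covariances)
      spec <- cfa_model(constructs, rescov, spec$second_order)
      action <- "remove_indicator"
      detail <- target
    } else {
      worst <- fl[which.max(abs(fl$residual)), ]
      spec <- cfa_model(spec$constructs,
                        c(spec$residual_covariances,
                          list(c(worst$a, worst$b))),
                        spec$second_order)
      action <- "add_residual_covariance"
      detail <- paste(worst$a, worst$b, sep = "~~")
    }
    fit <- cfa_fiml(spec, data, control = control)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      step = step, action = action, target = detail,
      residual = worst$residual, chisq = fit$chisq, df = fit$df)
  }
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(step = integer(), action = character(),
               target = character(), residual = numeric(),
               chisq = numeric(), df = numeric())
  list(spec = spec, fit = fit, log = log_df)
}

#' Factor scores from a fitted CFA
#'
#' Regression-method (conditional expectation) scores: for each crisis the
#' expectation of the latent variable(s) given that crisis's observed
#' indicators, so missing cells are handled by conditioning on the
#' observed subset. Bartlett scores are available for the first-order
#' factors of complete rows.
#'
#' @param object a `cfa_fiml` fit.
#' @param newdata optional matrix/`prepared_matrix` with the model's
#'   indicator columns; defaults to the fitting data.
#' @param what `"factors"` for first-order construct scores, or
#'   `"severity"` for the second-order factor (requires a second-order
#'   fit).
#' @param method `"regression"` (default) or `"bartlett"` (first-order,
#'   complete rows only).
#' @param ... unused.
#' @return A matrix (crises x latent variables) of scores; rows with no
#'   observed indicator are `NA`.
#' @export
predict.cfa_fiml <- function(object, newdata = NULL,
                             what = c("factors", "severity"),
                             method = c("regression", "bartlett"), ...) {
  what <- match.arg(what)
  method <- match.arg(method)
  x <- if (is.null(newdata)) object$data else {
    v <- if (inherits(newdata, "prepared_matrix")) newdata$values else
      as.matrix(newdata)
    v[, object$spec$indicators, drop = FALSE]
  }
  if (what == "severity" && is.null(object$gamma)) {
    stop("severity scores require a second-order fit")
  }
  p <- ncol(x)
  if (method == "bartlett") {
    if (what != "factors") stop("Bartlett scores are first-order only")
    if (anyNA(x)) stop("Bartlett scores require complete rows")
    Ti <- solve(object$Theta)
    M <- solve(t(object$Lambda) %*% Ti %*% object$Lambda) %*%
      t(object$Lambda) %*% Ti
    out <- t(M %*% t(sweep(x, 2, object$mu)))
    colnames(out) <- names(object$spec$constructs)
    return(out)
  }
  cov_xl <- if (what == "factors") {
    object$Lambda %*% object$Phi            # p x k
  } else {
    object$Lambda %*% cbind(object$gamma)   # p x 1
  }
  q <- ncol(cov_xl)
  out <- matrix(NA_real_, nrow(x), q)
  obs_mask <- !is.na(x)
  key <- apply(obs_mask, 1, function(z) paste(as.integer(z), collapse = ""))
  for (grp in split(seq_len(nrow(x)), key)) {
    o <- which(obs_mask[grp[1], ])
    if (!length(o)) next
    W <- solve(object$Sigma[o, o, drop = FALSE],
               cov_xl[o, , drop = FALSE])      # p_o x q
    cen <- sweep(x[grp, o, drop = FALSE], 2, object$mu[o])
    out[grp, ] <- cen %*% W
  }
  colnames(out) <- if (what == "factors") names(object$spec$constructs)
    else object$spec$second_order
  rownames(out) <- rownames(x)
  out
}

#' Normalized latent severity scores
#'
#' Computes per-crisis regression scores of the second-order severity
#' factor and min--max normalizes them to the \[0, 1\] range over the
#' scored set (minimum exactly 0, maximum exactly 1). Optionally
#' summarizes by crisis type.
#'
#' @param fit a second-order `cfa_fiml` fit.
#' @param newdata optional data (see [predict.cfa_fiml()]).
#' @param types optional factor/character vector of crisis types, one per
#'   scored crisis.
#' @return An object of class `severity_scores`: data frame with
#'   `crisis_id`, `raw`, `normalized`, `n_observed` and optional `type`;
#'   per-type summaries in `attr(, "by_type")`.
#' @export
severity_scores <- function(fit, newdata = NULL, types = NULL) {
  raw <- predict(fit, newdata = newdata, what = "severity")[, 1]
  x <- if (is.null(newdata)) fit$data else {
    v <- if (inherits(newdata, "prepared_matrix")) newdata$values else
      as.matrix(newdata)
    v[, fit$spec$indicators, drop = FALSE]
  }
  n_obs <- rowSums(!is.na(x))
  rng <- range(raw, na.rm = TRUE)
  if (diff(rng) == 0) {
    warning("all severity scores identical; normalization degenerate")
    normalized <- rep(NA_real_, length(raw))
  } else {
    normalized <- (raw - rng[1]) / diff(rng)
  }
  out <- data.frame(
    crisis_id = if (!is.null(rownames(x))) rownames(x) else
      as.character(seq_along(raw)),
    raw = raw, normalized = normalized, n_observed = n_obs,
    stringsAsFactors = FALSE)
  by_type <- NULL
  if (!is.null(types)) {
    stopifnot(length(types) == nrow(out))
    out$type <- as.character(types)
    by_type <- do.call(rbind, lapply(split(out$normalized, out$type),
      function(v) data.frame(mean = mean(v, na.rm = TRUE),
                             median = stats::median(v, na.rm = TRUE),
                             n = sum(!is.na(v)))))
    by_type <- cbind(type = rownames(by_type), by_type)
    rownames(by_type) <- NULL
  }
  structure(out, by_type = by_type, class = c("severity_scores",
                                              "data.frame"))
}

#' @export
print.severity_scores <- function(x, ...) {
  cat(sprintf("Normalized latent severity scores: %d crises, mean %.2f, median %.2f\n",
              nrow(x), mean(x$normalized, na.rm = TRUE),
              stats::median(x$normalized, na.rm = TRUE)))
  bt <- attr(x, "by_type")
  if (!is.null(bt)) {
    cat("By crisis type:\n")
    print.data.frame(bt, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Histogram of normalized severity scores
#'
#' @param x a `severity_scores` object.
#' @param ... passed to [graphics::hist()].
#' @export
plot.severity_scores <- function(x, ...) {
  graphics::hist(x$normalized, breaks = 20, xlab = "Normalized severity",
                 main = "Latent severity scores", ...)
  invisible(x)
}
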