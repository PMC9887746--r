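# Shared fixtures and independent oracle implementations. Everything here
# is deliberately naive (loops, direct formulas) so it stays independent
# of the package's vectorized/optimized code paths.

make_table <- function(values, pillar = "impact", scale_min = 0,
                       scale_max = 5) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("ind", seq_len(ncol(values)))
  }
  meta <- indicator_meta(colnames(values), pillar = pillar,
                         scale_min = scale_min, scale_max = scale_max)
  indicator_table(values, meta)
}

# brute-force Pearson correlation: double loop over pairwise-complete rows
brute_cor <- function(x) {
  p <- ncol(x)
  r <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    ok <- !is.na(x[, i]) & !is.na(x[, j])
    xi <- x[ok, i]; xj <- x[ok, j]
    num <- sum((xi - mean(xi)) * (xj - mean(xj)))
    den <- sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    r[i, j] <- num / den
  }
  r
}

# simulate a two-block oblique factor structure (continuous)
two_block_data <- function(n = 2000, lam = c(.8, .7, .6, .75, .65, .8),
                           rho = 0.3, seed = 99) {
  set.seed(seed)
  f1 <- rnorm(n)
  f2 <- rho * f1 + sqrt(1 - rho^2) * rnorm(n)
  x <- cbind(
    sapply(1:3, function(j) lam[j] * f1 + sqrt(1 - lam[j]^2) * rnorm(n)),
    sapply(4:6, function(j) lam[j] * f2 + sqrt(1 - lam[j]^2) * rnorm(n)))
  colnames(x) <- paste0("v", 1:6)
  x
}

# single-factor generating system used across the CFA tests
one_factor_data <- function(n = 400, lam = c(.8, .7, .6, .75), seed = 2) {
  set.seed(seed)
  f <- rnorm(n)
  x <- sapply(lam, function(l) l * f + sqrt(1 - l^2) * rnorm(n))
  colnames(x) <- paste0("y", seq_along(lam))
  x
}

# --- independent complete-data CFA oracle ------------------------------
# Direct formula evaluation on the sample moments: saturated and baseline
# log-likelihoods in closed form, the model log-likelihood by nlminb over
# a naive parameter vector, and the fit indices from their definitions.

oracle_loglik_complete <- function(x, mu, Sigma) {
  n <- nrow(x); p <- ncol(x)
  xb <- colMeans(x)
  S <- crossprod(sweep(x, 2, xb)) / n
  d <- xb - mu
  -n / 2 * (p * log(2 * pi) + determinant(Sigma)$modulus[1] +
              sum(diag(solve(Sigma) %*% S)) +
              drop(t(d) %*% solve(Sigma) %*% d))
}

# constructs: list(name -> indicator ids); single optional correlation
# between first two constructs handled for k <= 2; k = 3 uses three rhos.
oracle_cfa_complete <- function(x, constructs) {
  n <- nrow(x); p <- ncol(x)
  k <- length(constructs)
  construct_of <- match(rep(names(constructs), lengths(constructs)),
                        names(constructs))
  stopifnot(identical(unlist(constructs, use.names = FALSE), colnames(x)))
  nrho <- k * (k - 1) / 2
  xb <- colMeans(x)
  build_sigma <- function(par) {
    lam <- par[1:p]
    psi <- exp(par[p + 1:p])
    rho <- if (nrho) par[2 * p + 1:nrho] else numeric(0)
    Phi <- diag(k)
    Phi[lower.tri(Phi)] <- rho
    Phi[upper.tri(Phi)] <- t(Phi)[upper.tri(Phi)]
    L <- matrix(0, p, k)
    L[cbind(1:p, construct_of)] <- lam
    L %*% Phi %*% t(L) + diag(psi, p)
  }
  nll <- function(par) {
    Sigma <- build_sigma(par)
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) return(1e10)
    -oracle_loglik_complete(x, xb, Sigma)
  }
  start <- c(rep(0.5, p), rep(log(0.5), p), rep(0.2, nrho))
  lower <- c(rep(-10, p), rep(-15, p), rep(-0.99, nrho))
  upper <- c(rep(10, p), rep(5, p), rep(0.99, nrho))
  opt <- nlminb(start, nll, lower = lower, upper = upper,
                control = list(rel.tol = 1e-14, iter.max = 2000,
                               eval.max = 5000))
  S <- crossprod(sweep(x, 2, xb)) / n
  ll_sat <- -n / 2 * (p * log(2 * pi) + determinant(S)$modulus[1] + p)
  ll_base <- 0
  for (j in 1:p) {
    v <- mean((x[, j] - mean(x[, j]))^2)
    ll_base <- ll_base - n / 2 * (log(2 * pi) + log(v) + 1)
  }
  free <- p + p + nrho + p
  df <- p * (p + 3) / 2 - free
  df_b <- p * (p + 3) / 2 - 2 * p
  chisq <- 2 * (ll_sat - (-opt$objective))
  chisq_b <- 2 * (ll_sat - ll_base)
  d <- max(chisq - df, 0)
  db <- max(chisq_b - df_b, d)
  list(loglik = -opt$objective, chisq = chisq, df = df,
       chisq_b = chisq_b, df_b = df_b,
       cfi = if (db == 0) 1 else 1 - d / db,
       tli = ((chisq_b / df_b) - (chisq / df)) /
         ((chisq_b / df_b) - 1),
       rmsea = sqrt(max(chisq - df, 0) / (df * (n - 1))))
}
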