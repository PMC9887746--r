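test_that("scree eigenvalues match closed forms", {
  expect_equal(scree_eigenvalues(diag(5)), rep(1, 5), tolerance = 1e-10)
  r2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(scree_eigenvalues(r2), c(1.4, 0.6), tolerance = 1e-10)
  # equicorrelation p = 4, r = 0.5: 1 + (p-1)r then (1-r) repeated
  r4 <- matrix(0.5, 4, 4); diag(r4) <- 1
  expect_equal(scree_eigenvalues(r4), c(2.5, 0.5, 0.5, 0.5),
               tolerance = 1e-10)
  expect_equal(sum(scree_eigenvalues(r4)), 4, tolerance = 1e-8)
  expect_error(scree_eigenvalues(matrix(1:4, 2)), "symmetric")
})

test_that("one-factor ML extraction recovers loadings and uniquenesses", {
  set.seed(12)
  n <- 2000
  f <- rnorm(n)
  x <- sapply(1:5, function(j) 0.8 * f + 0.6 * rnorm(n))
  colnames(x) <- paste0("v", 1:5)
  fit <- efa_ml(x, 1)
  expect_true(all(abs(abs(fit$loadings[, 1]) - 0.8) < 0.05))
  expect_true(all(abs(fit$uniquenesses - 0.36) < 0.05))
})

test_that("independent columns carry no common structure", {
  set.seed(13)
  x <- matrix(rnorm(2000 * 6), 2000, 6)
  colnames(x) <- paste0("v", 1:6)
  fit <- suppressWarnings(efa_ml(x, 1))
  # ML extraction on null data can park the factor on a single variable
  # (boundary uniqueness); factanal behaves identically, so check the
  # two agree, and that no *common* structure is claimed: every other
  # indicator's loading is tiny
  fa <- suppressWarnings(
    stats::factanal(covmat = cor(x), factors = 1, rotation = "none"))
  expect_equal(unname(fit$uniquenesses), unname(fa$uniquenesses),
               tolerance = 1e-3)
  small <- abs(fit$loadings[, 1]) < 0.15
  expect_gte(sum(small), 5)
})

test_that("two disjoint blocks are recovered with small cross-loadings", {
  x <- two_block_data(n = 2000, rho = 0.3)
  fit <- efa_ml(x, 2)
  primary <- unname(apply(abs(fit$loadings), 1, which.max))
  expect_equal(primary, c(rep(primary[1], 3), rep(primary[4], 3)))
  expect_true(primary[1] != primary[4])
  cross <- sapply(1:6, function(i)
    min(abs(fit$loadings[i, ])))
  expect_true(all(cross < 0.1))
  expect_lt(abs(fit$Phi[1, 2] - 0.3), 0.07)
})

test_that("unrotated extraction agrees with factanal (independent check)", {
  x <- two_block_data(n = 800, seed = 7)
  r <- cor(x)
  fit <- efa_ml(r, 2, rotation = "none")
  fa <- stats::factanal(covmat = r, factors = 2, rotation = "none")
  expect_equal(unname(fit$uniquenesses), unname(fa$uniquenesses),
               tolerance = 1e-4)
  # model-implied correlation agrees even though rotations may differ
  imp_fa <- fa$loadings %*% t(fa$loadings) + diag(fa$uniquenesses)
  expect_equal(unname(fitted(fit)), unname(imp_fa), tolerance = 1e-4)
})

test_that("oblimin rotation preserves the model-implied correlation", {
  x <- two_block_data(n = 1000, seed = 21)
  un <- efa_ml(x, 2, rotation = "none")
  ob <- efa_ml(x, 2, rotation = "oblimin")
  expect_lt(max(abs(fitted(un) - fitted(ob))), 1e-8)
  # communality + uniqueness ~ 1 for standardized indicators
  comm <- diag(ob$loadings %*% ob$Phi %*% t(ob$loadings))
  expect_true(all(abs(comm + ob$uniquenesses - 1) < 0.05))
  # Phi symmetric with unit diagonal
  expect_true(isSymmetric(ob$Phi))
  expect_equal(unname(diag(ob$Phi)), rep(1, 2))
})

test_that("residual RMSR decreases with more factors on the same data", {
  set.seed(17)
  cfg <- paperlike_preset(n_crises = 400, ordinal = FALSE,
                          missingness = FALSE, crisis_types = FALSE)
  sim <- simulate_crises(cfg, seed = 17)
  r <- cor(sim$table$values)
  rmsr <- sapply(1:3, function(k) {
    res <- residuals(suppressWarnings(efa_ml(r, k, rotation = "none")))
    sqrt(mean(res[lower.tri(res)]^2))
  })
  expect_true(all(diff(rmsr) < 0))
})

test_that("indicator order only permutes the loading rows", {
  x <- two_block_data(n = 600, seed = 31)
  fit <- efa_ml(x, 2)
  perm <- c(4, 1, 6, 2, 3, 5)
  fit_p <- efa_ml(x[, perm], 2)
  expect_equal(unname(fit_p$loadings), unname(fit$loadings[perm, ]),
               tolerance = 1e-5)
  expect_equal(unname(fit_p$Phi), unname(fit$Phi), tolerance = 1e-5)
})

test_that("variance accounting is internally consistent", {
  x <- two_block_data(n = 700, seed = 41)
  fit <- efa_ml(x, 2)
  expect_equal(fit$cumulative_var, cumsum(fit$proportion_var))
  expect_equal(fit$proportion_var, fit$ss_loadings / nrow(fit$loadings))
  expect_true(all(diff(fit$ss_loadings) <= 0))  # canonical order
})

# minimal hand-built solution object for rule-logic tests
fake_sol <- function(L, Phi = diag(ncol(L)), factors = ncol(L)) {
  structure_m <- L %*% Phi
  ss <- colSums(L * structure_m)
  structure(list(loadings = L, structure = structure_m, Phi = Phi,
                 ss_loadings = ss, proportion_var = ss / nrow(L),
                 cumulative_var = cumsum(ss / nrow(L)),
                 factors = factors),
            class = "efa_ml")
}

test_that("retention criteria flag weak factors and low cumulative variance", {
  p <- 32
  mk <- function(props) {
    L <- matrix(0, p, length(props))
    rownames(L) <- paste0("v", 1:p)
    for (j in seq_along(props)) {
      L[j, j] <- sqrt(props[j] * p)   # ss_loadings = props * p
    }
    fake_sol(L)
  }
  sol3 <- mk(c(0.20, 0.15, 0.11))
  sol4 <- mk(c(0.21, 0.14, 0.12, 0.06))
  rep <- efa_retention(list(sol3, sol4))
  expect_true(rep$all_prop_pass[rep$factors == 3])
  expect_false(rep$all_prop_pass[rep$factors == 4])
  expect_equal(attr(rep, "recommended"), 3)
  # cumulative 0.46 < 0.60 fails the collective criterion
  expect_false(rep$cum_pass[rep$factors == 3])
  pf <- attr(rep, "per_factor")
  expect_false(pf$prop_pass[pf$factors == 4 & pf$factor == 4])
  expect_true(pf$ss_pass[pf$factors == 4 & pf$factor == 4])  # 1.97 > 1
})

test_that("pruning applies the loading, cross-loading and sign rules", {
  L <- rbind(
    clean      = c(0.86, 0.05, 0.02),
    weak       = c(0.12, 0.08, 0.05),
    signs      = c(0.37, -0.33, 0.00),
    crossload  = c(0.50, 0.40, 0.00),
    gap_ok     = c(0.80, 0.40, 0.00))
  colnames(L) <- paste0("F", 1:3)
  sol <- fake_sol(L)
  pr <- efa_prune(sol, sol)
  expect_false("clean" %in% pr$id)
  expect_false("gap_ok" %in% pr$id)
  expect_equal(unique(pr$reason[pr$id == "weak"]), "low_loading")
  expect_equal(unique(pr$reason[pr$id == "signs"]), "sign_conflict")
  expect_equal(unique(pr$reason[pr$id == "crossload"]), "cross_loading")
  expect_setequal(attr(pr, "retained"), c("clean", "gap_ok"))
  # removal in either solution suffices
  L2 <- L; L2["gap_ok", ] <- c(0.45, 0.40, 0)
  pr2 <- efa_prune(sol, fake_sol(L2))
  expect_true("gap_ok" %in% pr2$id)
})
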