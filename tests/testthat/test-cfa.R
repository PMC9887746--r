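test_that("model specification is validated", {
  expect_error(cfa_model(list(a = c("x", "y"), b = c("y", "z"))),
               "exactly one construct")
  expect_error(cfa_model(list(a = c("x", "y"), b = c("z", "w")),
                         residual_covariances = list(c("x", "z"))),
               "same construct")
  expect_error(cfa_model(list(a = c("x", "y"), b = c("z", "w")),
                         second_order = TRUE),
               "at least 3")
})

test_that("free-parameter counting gives the reported degrees of freedom", {
  # final reported topology: 11 indicators, 3 unit-variance constructs,
  # 3 construct correlations, 1 residual covariance -> df 40
  spec <- cfa_model(
    list(gov = paste0("g", 1:5), access = paste0("a", 1:3),
         impact = paste0("i", 1:3)),
    residual_covariances = list(c("g1", "g2")))
  counts <- cfa_df(spec)
  expect_equal(unname(counts["moments"]), 77)
  expect_equal(unname(counts["free"]), 37)
  expect_equal(unname(counts["df"]), 40)
  # second-order over 3 constructs has identical df
  expect_equal(unname(cfa_df(add_second_order(spec))["df"]), 40)
  # a 3-indicator single construct is just-identified
  spec0 <- cfa_model(list(f = c("y1", "y2", "y3")))
  expect_equal(unname(cfa_df(spec0)["df"]), 0)
})

test_that("a just-identified model reproduces the data exactly", {
  x <- one_factor_data(n = 300, lam = c(.8, .7, .6))
  fit <- cfa_fiml(cfa_model(list(f = colnames(x))), x)
  expect_equal(fit$df, 0)
  expect_lt(fit$chisq, 1e-4)
  expect_equal(fit$rmsea, 0)
})

test_that("complete-data fit agrees with a brute-force oracle", {
  x <- one_factor_data(n = 250, lam = c(.8, .7, .6, .75))
  constructs <- list(f = colnames(x))
  fit <- cfa_fiml(cfa_model(constructs), x)
  oracle <- oracle_cfa_complete(x, constructs)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  expect_equal(fit$chisq, oracle$chisq, tolerance = 1e-6)
  expect_equal(fit$df, oracle$df)
  expect_equal(fit$chisq_b, oracle$chisq_b, tolerance = 1e-6)
  expect_equal(fit$df_b, oracle$df_b)
  expect_equal(fit$cfi, oracle$cfi, tolerance = 1e-6)
  expect_equal(fit$tli, oracle$tli, tolerance = 1e-6)
  expect_equal(fit$rmsea, oracle$rmsea, tolerance = 1e-6)
})

test_that("two-construct complete-data fit matches the oracle", {
  set.seed(9)
  n <- 300
  f1 <- rnorm(n); f2 <- 0.5 * f1 + sqrt(0.75) * rnorm(n)
  x <- cbind(
    sapply(c(.8, .7, .6), function(l) l * f1 + sqrt(1 - l^2) * rnorm(n)),
    sapply(c(.75, .65), function(l) l * f2 + sqrt(1 - l^2) * rnorm(n)))
  colnames(x) <- paste0("y", 1:5)
  constructs <- list(a = c("y1", "y2", "y3"), b = c("y4", "y5"))
  fit <- cfa_fiml(cfa_model(constructs), x)
  oracle <- oracle_cfa_complete(x, constructs)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  expect_equal(fit$chisq, oracle$chisq, tolerance = 1e-6)
  expect_equal(fit$cfi, oracle$cfi, tolerance = 1e-6)
  expect_equal(fit$tli, oracle$tli, tolerance = 1e-6)
  expect_equal(fit$rmsea, oracle$rmsea, tolerance = 1e-6)
})

test_that("FIML equals complete-data ML when nothing is missing", {
  x <- one_factor_data(n = 200)
  fit <- cfa_fiml(cfa_model(list(f = colnames(x))), x)
  # casewise log-density sum at the fitted parameters (independent loop)
  Sinv <- solve(fit$Sigma)
  ld <- determinant(fit$Sigma)$modulus[1]
  ll <- 0
  for (i in seq_len(nrow(x))) {
    d <- x[i, ] - fit$mu
    ll <- ll - 0.5 * (ncol(x) * log(2 * pi) + ld +
                        drop(t(d) %*% Sinv %*% d))
  }
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
})

test_that("FIML under MCAR stays close to the complete-data estimates", {
  set.seed(23)
  cfg <- paperlike_preset(n_crises = 1000, ordinal = FALSE,
                          missingness = FALSE, crisis_types = FALSE)
  sim <- simulate_crises(cfg, seed = 23)
  spec <- cfa_model(cfg$constructs)
  x <- sim$table$values
  fit_complete <- cfa_fiml(spec, x)
  x_mcar <- x
  x_mcar[matrix(runif(length(x)) < 0.2, nrow(x))] <- NA
  fit_mcar <- cfa_fiml(spec, x_mcar)
  expect_lt(max(abs(fit_mcar$std_lambda - fit_complete$std_lambda)), 0.08)
})

test_that("chi-square is invariant to reordering and sign flips", {
  x <- one_factor_data(n = 250, lam = c(.8, .7, .6, .75))
  spec <- cfa_model(list(f = colnames(x)))
  fit <- cfa_fiml(spec, x)
  perm <- c(3, 1, 4, 2)
  fit_p <- cfa_fiml(cfa_model(list(f = colnames(x)[perm])), x[, perm])
  expect_equal(fit_p$chisq, fit$chisq, tolerance = 1e-6)
  x_flip <- x; x_flip[, 2] <- -x_flip[, 2]
  fit_f <- cfa_fiml(spec, x_flip)
  expect_equal(fit_f$chisq, fit$chisq, tolerance = 1e-6)
  expect_equal(abs(fit_f$lambda), abs(fit$lambda), tolerance = 1e-4)
})

test_that("second-order and correlated-first-order fits coincide for 3 constructs", {
  cfg <- paperlike_preset(n_crises = 400, ordinal = FALSE,
                          missingness = FALSE, crisis_types = FALSE)
  sim <- simulate_crises(cfg, seed = 31)
  z <- standardize_indicators(sim$table)
  spec <- cfa_model(cfg$constructs)
  first <- cfa_fiml(spec, z)
  second <- cfa_fiml(add_second_order(spec), z)
  expect_equal(second$chisq, first$chisq, tolerance = 1e-6)
  expect_equal(second$df, first$df)
  expect_true(all(abs(second$gamma) <= 1))
})

test_that("parameter recovery on a known 3-construct model", {
  cfg <- paperlike_preset(n_crises = 1000, ordinal = FALSE,
                          missingness = FALSE, crisis_types = FALSE)
  sim <- simulate_crises(cfg, seed = 41)
  fit <- cfa_fiml(cfa_model(cfg$constructs), sim$table$values)
  expect_lt(max(abs(fit$std_lambda - cfg$first_order_loadings)), 0.05)
})

test_that("residual correlations vanish for model-generated data and flag injected structure", {
  cfg <- paperlike_preset(n_crises = 2000, ordinal = FALSE,
                          missingness = FALSE, crisis_types = FALSE)
  sim <- simulate_crises(cfg, seed = 51)
  fit <- cfa_fiml(cfa_model(cfg$constructs), sim$table$values)
  res <- residuals(fit)
  expect_equal(nrow(attr(res, "flags")), 0)
  expect_true(all(abs(diag(res)) < 1e-6))

  # inject an extra shared component between two indicators whose
  # construct is pinned down by three stronger siblings
  cfg2 <- paperlike_preset(n_crises = 2000, ordinal = FALSE,
                           missingness = FALSE, crisis_types = FALSE)
  cfg2$residual_cov_pairs <- list(
    list(pair = c("gender_inequality", "empowerment"), r = 0.3))
  sim2 <- simulate_crises(cfg2, seed = 52)
  fit2 <- cfa_fiml(cfa_model(cfg2$constructs),
                   standardize_indicators(sim2$table))
  fl <- attr(residuals(fit2), "flags")
  expect_true(any(fl$scope == "within" &
                    (fl$a == "gender_inequality" |
                       fl$b == "gender_inequality") &
                    (fl$a == "empowerment" | fl$b == "empowerment")))
})

test_that("modification adds exactly the injected residual covariance", {
  cfg <- paperlike_preset(n_crises = 1500, ordinal = FALSE,
                          missingness = FALSE, crisis_types = FALSE)
  cfg$residual_cov_pairs <- list(
    list(pair = c("gender_inequality", "empowerment"), r = 0.3))
  sim <- simulate_crises(cfg, seed = 61)
  z <- standardize_indicators(sim$table)
  out <- modify_cfa(cfa_model(cfg$constructs), z, budget = 4)
  added <- out$log[out$log$action == "add_residual_covariance", ]
  expect_equal(nrow(added), 1L)
  expect_true(grepl("gender_inequality", added$target) &&
                grepl("empowerment", added$target))
  expect_equal(length(out$spec$residual_covariances), nrow(added))
  # fixed point: a clean fit is left unchanged
  sim0 <- simulate_crises(paperlike_preset(n_crises = 1500,
                                           ordinal = FALSE,
                                           missingness = FALSE,
                                           crisis_types = FALSE),
                          seed = 62)
  out0 <- modify_cfa(cfa_model(cfg$constructs),
                     standardize_indicators(sim0$table), budget = 4)
  expect_equal(nrow(out0$log), 0)
})

test_that("modification removes a cross-construct offender", {
  cfg <- paperlike_preset(n_crises = 1500, ordinal = FALSE,
                          missingness = FALSE, crisis_types = FALSE)
  sim <- simulate_crises(cfg, seed = 71)
  x <- sim$table$values
  # contaminate one governance indicator with the impact factor
  x[, "empowerment"] <- x[, "empowerment"] +
    0.9 * sim$truth$impact
  z <- standardize_indicators(make_table(x, scale_min = -100,
                                         scale_max = 100))
  out <- modify_cfa(cfa_model(cfg$constructs), z, budget = 5)
  expect_true("empowerment" %in%
                out$log$target[out$log$action == "remove_indicator"])
  expect_false("empowerment" %in% out$spec$indicators)
})

test_that("severity scores are normalized to [0,1] and recover the truth", {
  cfg <- paperlike_preset(n_crises = 1000, ordinal = FALSE,
                          missingness = FALSE, crisis_types = FALSE)
  # strong measurement: high second-order loadings
  cfg$second_order_loadings[] <- 0.9
  sim <- simulate_crises(cfg, seed = 81)
  fit <- cfa_fiml(add_second_order(cfa_model(cfg$constructs)),
                  standardize_indicators(sim$table))
  sc <- severity_scores(fit, types = rep(c("complex", "regional"), 500))
  expect_equal(min(sc$normalized), 0)
  expect_equal(max(sc$normalized), 1)
  expect_gt(cor(sc$raw, sim$truth$severity), 0.9)
  expect_equal(nrow(attr(sc, "by_type")), 2)
  # normalization is a monotone transform of the raw scores
  expect_equal(order(sc$raw), order(sc$normalized))
})

test_that("degenerate score sets are flagged", {
  cfg <- paperlike_preset(n_crises = 200, ordinal = FALSE,
                          missingness = FALSE, crisis_types = FALSE)
  sim <- simulate_crises(cfg, seed = 91)
  fit <- cfa_fiml(add_second_order(cfa_model(cfg$constructs)),
                  standardize_indicators(sim$table))
  x0 <- fit$data; x0[] <- 0   # all crises identical
  sc <- expect_warning(severity_scores(fit, newdata = x0), "degenerate")
  expect_true(all(is.na(sc$normalized)))
})
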