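# ML confirmatory factor analysis: discrepancy function, fit indices,
# RMSEA interval inversion, factor scores.

# Implied covariance for a standardized two-level model, built directly
# from the population parameters (independent of the fitting code).
population_sigma <- function(l, g) {
  item_fac <- c(1, 1, 1, 2, 2, 2, 3, 3)
  Phi <- outer(g, g); diag(Phi) <- 1
  Lam <- matrix(0, 8, 3)
  Lam[cbind(1:8, item_fac)] <- l
  S <- Lam %*% Phi %*% t(Lam)
  diag(S) <- 1
  dimnames(S) <- rep(list(c("tobacco_14", "tobacco_16", "tobacco_18",
                            "cannabis_14", "cannabis_16", "cannabis_18",
                            "alcohol_16", "alcohol_18")), 2)
  S
}

test_that("fitting the population covariance gives a saturated fit", {
  S <- population_sigma(c(0.75, 0.85, 0.8, 0.7, 0.9, 0.85, 0.65, 0.8),
                        c(0.85, 0.8, 0.75))
  fit <- fit_cfa(sample_cov = S, n_obs = 244)
  expect_true(fit$converged)
  expect_lt(fit$F_ML, 1e-6)
  expect_lt(fit$chi_square, 1e-3)
  expect_equal(fit$CFI, 1)
  expect_equal(fit$RMSEA, 0)
  ## standardized loadings recover the population values
  expect_lt(max(abs(fit$loadings$std -
                      c(0.75, 0.85, 0.8, 0.7, 0.9, 0.85, 0.65, 0.8))), 1e-3)
})

test_that("the printed fit statistics reproduce RMSEA = 0.08", {
  rmsea <- sqrt(max(49.55 - 18, 0) / (18 * (244 - 1)))
  expect_equal(round(rmsea, 2), 0.08)
  ## N instead of N-1 rounds identically at this sample size
  expect_equal(round(sqrt((49.55 - 18) / (18 * 244)), 2), 0.08)
})

test_that("RMSEA interval matches an independent CDF-inversion oracle", {
  ## oracle: plain bisection on the noncentral chi-square CDF, written
  ## separately from the uniroot-based implementation
  bisect_ncp <- function(chi, df, target, hi = 1000) {
    lo <- 0
    if (pchisq(chi, df, ncp = 0) < target) return(0)
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (pchisq(chi, df, ncp = mid) > target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  chi <- 49.55; df <- 18; N <- 244
  lam_lo <- bisect_ncp(chi, df, 0.95)
  lam_hi <- bisect_ncp(chi, df, 0.05)
  oracle <- c(sqrt(lam_lo / (df * (N - 1))), sqrt(lam_hi / (df * (N - 1))))
  got <- rmsea_ci(chi, df, N)
  expect_equal(unname(got), oracle, tolerance = 1e-6)
  expect_lte(got[1], got[2])
})

test_that("RMSEA interval degenerate cases", {
  ## chi-square equal to df: zero lower noncentrality
  expect_equal(unname(rmsea_ci(18, 18, 244)[1]), 0)
  ## level 0 collapses to a single point
  ci0 <- rmsea_ci(49.55, 18, 244, level = 0)
  expect_equal(unname(ci0[1]), unname(ci0[2]), tolerance = 1e-8)
})

test_that("factor scores equal the indicator mean in the error-free limit", {
  L <- rnorm(60)
  out <- simulate_substance_items(
    L, list(first_order = rep(1, 8), second_order = rep(1, 3)), seed = 4)
  ## hand-built fit at the deterministic limit (loadings 1, no unique error)
  ly <- methrisk:::.cfa_layout(liability_model_spec(), colnames(out$items))
  est <- list(Lambda = matrix(0, 8, 3), Gamma = c(1, 1, 1), phi = 1,
              Psi = rep(1e-12, 3), Theta = rep(1e-12, 8),
              mu = colMeans(out$items))
  est$Lambda[cbind(1:8, ly$item_fac)] <- 1
  fake <- list(est = est, layout = ly, spec = liability_model_spec(),
               converged = TRUE)
  sc <- factor_scores(fake, out$items)
  m <- rowMeans(out$items)
  expect_equal(sc$liability, unname((m - mean(m)) / sd(m)), tolerance = 1e-6)
})

test_that("factor scores track the generating liability and are equivariant", {
  loadings <- list(first_order = c(0.75, 0.85, 0.8, 0.7, 0.9, 0.85, 0.65, 0.8),
                   second_order = c(0.85, 0.8, 0.75))
  set.seed(9)
  L <- rnorm(2000)
  out <- simulate_substance_items(L, loadings)
  fit <- fit_cfa(as.data.frame(out$items))
  ## population ceiling for the regression-score correlation with the true
  ## liability: sqrt(psi' Sigma^-1 psi) with psi = Cov(y, xi) = l * g
  psi <- loadings$first_order * loadings$second_order[c(1, 1, 1, 2, 2, 2, 3, 3)]
  Sig <- population_sigma(loadings$first_order, loadings$second_order)
  ceiling_r <- sqrt(drop(psi %*% solve(Sig, psi)))
  expect_gt(cor(fit$scores$liability, L), ceiling_r - 0.05)
  expect_lt(cor(fit$scores$liability, L), ceiling_r + 0.05)
  ## permuting samples permutes scores identically
  perm <- sample(nrow(out$items))
  sc_perm <- factor_scores(fit, out$items[perm, ])
  expect_equal(sc_perm$liability, fit$scores$liability[perm],
               tolerance = 1e-10)
})

test_that("chi-square is invariant to sample order and indicator rescaling", {
  d <- small_cohort()
  items <- d$cohort[, c("tobacco_14", "tobacco_16", "tobacco_18",
                        "cannabis_14", "cannabis_16", "cannabis_18",
                        "alcohol_16", "alcohol_18")]
  f1 <- fit_cfa(items)
  f2 <- fit_cfa(items[sample(nrow(items)), ])
  expect_equal(f1$chi_square, f2$chi_square, tolerance = 1e-4)
  ## linear rescaling of an indicator leaves the standardized solution alone
  items2 <- items
  items2$tobacco_16 <- items2$tobacco_16 * 10 + 3
  f3 <- fit_cfa(items2)
  expect_equal(f3$chi_square, f1$chi_square, tolerance = 1e-3)
  expect_equal(f3$loadings$std, f1$loadings$std, tolerance = 1e-3)
})

test_that("degenerate inputs error clearly", {
  d <- matrix(rnorm(40), 5, 8,
              dimnames = list(NULL, c("tobacco_14", "tobacco_16", "tobacco_18",
                                      "cannabis_14", "cannabis_16",
                                      "cannabis_18", "alcohol_16",
                                      "alcohol_18")))
  expect_error(fit_cfa(as.data.frame(d)), "more observations")
  S <- diag(8); S[1, 2] <- S[2, 1] <- 1  # singular
  dimnames(S) <- dimnames(population_sigma(rep(0.8, 8), rep(0.8, 3)))
  expect_error(fit_cfa(sample_cov = S, n_obs = 100), "singular")
})
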