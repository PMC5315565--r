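# Synthetic cohort generator: determinism, bounds, planted structure.

test_that("identical configs produce byte-identical cohorts", {
  cfg <- sim_config(n_samples = 50, n_probes = 300, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- sim_config(n_samples = 50, n_probes = 300, seed = 100)
  expect_false(identical(simulate_cohort(cfg2)$birth$beta, a$birth$beta))
})

test_that("beta values are bounded in (0,1) with no missingness", {
  d <- small_cohort()
  for (tp in c("birth", "age7")) {
    expect_false(anyNA(d[[tp]]$beta))
    expect_true(all(d[[tp]]$beta > 0 & d[[tp]]$beta < 1))
  }
})

test_that("study-scale config yields matching shapes and both sexes", {
  cfg <- sim_config(n_samples = 244, n_probes = 2000, seed = 3)
  d <- simulate_cohort(cfg)
  expect_equal(dim(d$birth$beta), c(244, 2000))
  expect_equal(dim(d$age7$beta), c(244, 2000))
  expect_equal(nrow(d$cohort), 244)
  expect_setequal(unique(d$cohort$sex), c(0, 1))
  expect_equal(ncol(d$truth$cell_proportions$birth), 5)
  expect_equal(length(d$truth$dmp_ids), 65)
})

test_that("every planted id exists in the probe annotation", {
  d <- small_cohort()
  ann_ids <- d$birth$annotation$probe_id
  expect_true(all(d$truth$dmp_ids %in% ann_ids))
  expect_true(all(d$truth$mqtl_probe_ids %in% d$truth$dmp_ids))
  expect_true(all(unlist(d$truth$exposure_probe_ids) %in% ann_ids))
  expect_true(all(d$panel$probe_id %in% ann_ids))
})

test_that("cross-time autocorrelation of non-mQTL probes matches the target", {
  cfg <- sim_config(n_samples = 1000, n_probes = 3000,
                    cross_time_autocorr = 0.3, seed = 5)
  d <- simulate_cohort(cfg)
  keep <- setdiff(colnames(d$birth$beta), d$truth$mqtl_probe_ids)
  r <- vapply(keep, function(j) cor(d$birth$beta[, j], d$age7$beta[, j]), 0)
  expect_lt(abs(mean(r) - 0.3), 0.05)
  ## mQTL probes stay notably more stable than the background
  r_mqtl <- vapply(d$truth$mqtl_probe_ids, function(j)
    cor(d$birth$beta[, j], d$age7$beta[, j]), 0)
  expect_gt(min(r_mqtl), mean(r) + 0.2)
})

test_that("substance items collapse to the liability in the error-free limit", {
  L <- rnorm(100)
  out <- simulate_substance_items(
    L, list(first_order = rep(1, 8), second_order = rep(1, 3)), seed = 1)
  for (j in 1:8) expect_equal(unname(out$items[, j]), L)
})

test_that("zero second-order loadings give uncorrelated first-order factors", {
  L <- rnorm(5000)
  out <- simulate_substance_items(
    L, list(first_order = c(0.75, 0.85, 0.8, 0.7, 0.9, 0.85, 0.65, 0.8),
            second_order = rep(0, 3)), seed = 2)
  cc <- cor(out$first_order)
  expect_lt(max(abs(cc[lower.tri(cc)])), 0.05)
})

test_that("CFA refit on large simulated items recovers the loadings", {
  loadings <- list(first_order = c(0.75, 0.85, 0.8, 0.7, 0.9, 0.85, 0.65, 0.8),
                   second_order = c(0.85, 0.8, 0.75))
  out <- simulate_substance_items(rnorm(5000), loadings, seed = 7)
  fit <- fit_cfa(as.data.frame(out$items))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$loadings$std - loadings$first_order)), 0.05)
  expect_lt(max(abs(fit$second_order$std - loadings$second_order)), 0.05)
})

test_that("loading count mismatches are rejected", {
  expect_error(simulate_substance_items(
    rnorm(10), list(first_order = rep(0.8, 7), second_order = rep(0.8, 3))),
    "8 first-order")
})

test_that("fixtures round-trip through disk with stable checksums", {
  cfg <- sim_config(n_samples = 30, n_probes = 120, n_dmps = 10,
                    n_mqtl_dmps = 2, n_panel_probes = 20, seed = 21)
  d <- simulate_cohort(cfg)
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  p1 <- write_fixture(d, d1)
  p2 <- write_fixture(simulate_cohort(cfg), d2)
  for (k in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[k]])),
                     unname(tools::md5sum(p2[[k]])), label = k)
  }
  back <- read_fixture(d1)
  expect_equal(back$birth$beta, d$birth$beta, tolerance = 1e-12)
  expect_equal(back$age7$beta, d$age7$beta, tolerance = 1e-12)
  expect_identical(back$mqtl_table$probe_id, d$mqtl_table$probe_id)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("flagged probes written to a fixture are dropped downstream", {
  cfg <- sim_config(n_samples = 20, n_probes = 10, n_dmps = 0,
                    n_mqtl_dmps = 0, n_panel_probes = 4,
                    exposure_effects = list(),
                    n_flagged = c(1L, 1L, 1L), seed = 8)
  d <- simulate_cohort(cfg)
  expect_length(filter_probes(d$birth$annotation), 7)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_dmps = 50, n_probes = 40))
  expect_error(sim_config(n_mqtl_dmps = 10, n_dmps = 5))
  expect_error(sim_config(dirichlet_alpha = c(-1, 1, 1, 1, 1)))
  expect_error(sim_config(noise_sd = 0))
})
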