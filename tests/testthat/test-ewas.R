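# Probe-wise association engine: OLS vs normal equations, BH step-up vs
# brute force, selection, follow-forward, temporal correlation structure.

test_that("probe filtering drops exactly the flagged probes, keeping order", {
  ann <- data.frame(probe_id = sprintf("cg%02d", 1:10),
                    cross_reactive = c(TRUE, rep(FALSE, 9)),
                    control_probe = c(rep(FALSE, 4), TRUE, rep(FALSE, 5)),
                    snp_at_sbe = c(rep(FALSE, 9), TRUE))
  kept <- filter_probes(ann)
  expect_length(kept, 7)
  expect_identical(kept, sprintf("cg%02d", c(2:4, 6:9)))
  ann$cross_reactive <- ann$control_probe <- ann$snp_at_sbe <- FALSE
  expect_identical(filter_probes(ann), ann$probe_id)
  expect_error(filter_probes(ann[, 1, drop = FALSE]), "flag columns")
})

test_that("coefficients, SE, t and p match a normal-equations oracle", {
  set.seed(1)
  n <- 6
  x <- rnorm(n); z <- rnorm(n)
  Y <- matrix(runif(n * 4, 0.2, 0.8), n,
              dimnames = list(paste0("s", 1:n), paste0("cg", 1:4)))
  tab <- run_ewas(Y, x, data.frame(z = z))
  X <- cbind(1, x, z)
  XtXi <- solve(t(X) %*% X)
  for (j in 1:4) {
    bhat <- XtXi %*% t(X) %*% Y[, j]
    res <- Y[, j] - X %*% bhat
    s2 <- sum(res^2) / (n - 3)
    se <- sqrt(s2 * XtXi[2, 2])
    tt <- bhat[2] / se
    expect_equal(tab$std_beta[j], bhat[2] * sd(x) / sd(Y[, j]),
                 tolerance = 1e-10)
    expect_equal(tab$se[j], se, tolerance = 1e-10)
    expect_equal(tab$t[j], unname(tt), tolerance = 1e-10)
    expect_equal(tab$p[j], 2 * pt(-abs(tt), n - 3), tolerance = 1e-10)
  }
})

test_that("ewas agrees with an independent linear-model implementation", {
  d <- small_cohort()
  sub <- d$birth$beta[, 1:50]
  x <- d$truth$liability
  covars <- data.frame(sex = d$cohort$sex)
  tab <- run_ewas(sub, x, covars)
  design <- model.matrix(~ x + sex, data = cbind(covars, x = x))
  lf <- limma::lmFit(t(sub), design)
  ## ordinary (non-moderated) statistics from the limma fit
  se <- lf$stdev.unscaled[, "x"] * lf$sigma
  tt <- lf$coefficients[, "x"] / se
  expect_equal(unname(tab$t), unname(tt), tolerance = 1e-8)
  expect_equal(unname(tab$p),
               unname(2 * pt(-abs(tt), lf$df.residual)), tolerance = 1e-8)
})

test_that("degenerate probes are flagged and a constant predictor errors", {
  Y <- matrix(c(rep(0.5, 6), runif(6, 0.3, 0.7)), 6,
              dimnames = list(paste0("s", 1:6), c("cgA", "cgB")))
  tab <- run_ewas(Y, rnorm(6))
  expect_equal(tab$flag, c("zero_variance", ""))
  expect_true(is.na(tab$p[1]) && is.na(tab$q[1]))
  expect_false(is.na(tab$p[2]))
  expect_error(run_ewas(Y, rep(1, 6)), "zero variance")
})

test_that("direction labels follow the sign of the standardized beta", {
  d <- small_cohort()
  tab <- run_ewas(d$birth$beta[, d$truth$dmp_ids], d$truth$liability)
  expect_identical(tab$direction[tab$std_beta < 0],
                   rep("hypomethylated", sum(tab$std_beta < 0)))
  expect_identical(tab$direction[tab$std_beta > 0],
                   rep("hypermethylated", sum(tab$std_beta > 0)))
})

test_that("bh_adjust equals the brute-force step-up on random short vectors", {
  set.seed(42)
  for (i in 1:200) {
    k <- sample(1:10, 1)
    p <- round(runif(k), 3)
    expect_equal(bh_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
    m <- k + sample(0:20, 1)
    expect_equal(bh_adjust(p, m_total = m), bh_bruteforce(p, m),
                 tolerance = 1e-12)
  }
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               bh_bruteforce(c(0.01, 0.02, 0.03, 0.04)))
  expect_error(bh_adjust(c(0.5, 1.2)), "0,1")
  expect_error(bh_adjust(c(0.5, 0.6), m_total = 1), "m_total")
})

test_that("q-values are monotone in p-rank", {
  set.seed(7)
  p <- runif(1000)
  q <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  expect_true(all(q >= 0 & q <= 1))
})

test_that("DMP selection sorts by p with lexicographic ties and respects the
          threshold", {
  tab <- data.frame(probe_id = c("cgB", "cgA", "cgC", "cgD"),
                    std_beta = c(0.3, -0.2, 0.1, 0.4),
                    p = c(0.001, 0.001, 0.5, 0.02),
                    q = c(0.01, 0.01, 0.6, 0.04))
  attr(tab, "m_total") <- 4
  class(tab) <- c("ewas_table", "data.frame")
  d <- select_dmps(tab, 0.05)
  expect_identical(d$probe_id, c("cgA", "cgB", "cgD"))
  expect_identical(select_dmps(tab, 1.0)$probe_id, c("cgA", "cgB", "cgD", "cgC"))
  tab$q <- rep(0.9, 4)
  expect_equal(nrow(select_dmps(tab, 0.05)), 0)
})

test_that("planted DMPs are recovered at scale and mostly missed at null", {
  d <- small_cohort()
  pr <- estimate_proportions(d$birth, d$panel)
  covars <- data.frame(sex = d$cohort$sex, pr)
  fit <- fit_cfa(d$cohort)
  tab <- run_ewas(d$birth, fit$scores$liability, covars,
                  probes = filter_probes(d$birth$annotation))
  dm <- select_dmps(tab)
  expect_gt(sum(dm$probe_id %in% d$truth$dmp_ids), 40)  # n = 300 cohort
})

test_that("follow-forward on the identical matrix replicates everything", {
  d <- small_cohort()
  x <- d$truth$liability
  tab <- run_ewas(d$birth, x, probes = colnames(d$birth$beta)[1:200])
  ## force a few probes through as a DmpSet regardless of significance
  dm <- tab[1:20, c("probe_id", "std_beta", "p", "q")]
  class(dm) <- c("dmp_set", "data.frame")
  ff <- follow_forward(dm, d$birth, x, q_threshold = 0.05)
  m <- match(dm$probe_id, ff$probe_id)
  expect_equal(ff$std_beta[m], dm$std_beta, tolerance = 1e-12)
  expect_equal(ff$p[m], dm$p, tolerance = 1e-12)
  expect_length(attr(ff, "missing_probes"), 0)
})

test_that("birth-specific effects do not replicate at the later timepoint", {
  ## the generator plants liability effects at birth only; with weak
  ## cross-time carry-over, essentially nothing should survive FDR at t2
  cfg <- sim_config(n_samples = 500, n_probes = 2000, seed = 23)
  d <- simulate_cohort(cfg)
  x <- d$truth$liability
  tab <- run_ewas(d$birth, x, data.frame(sex = d$cohort$sex),
                  probes = filter_probes(d$birth$annotation))
  dm <- select_dmps(tab)
  ff <- follow_forward(dm, d$age7, x, data.frame(sex = d$cohort$sex))
  expect_lte(attr(ff, "n_replicated"), 1)
  expect_true(all(attr(ff, "nominal") %in% ff$probe_id))
})

test_that("autocorrelation summaries behave at the identity and at target", {
  d <- small_cohort()
  ids <- d$truth$dmp_ids[1:20]
  same <- probe_autocorrelation(d$birth, d$birth, ids)
  expect_true(all(abs(same$per_probe$r - 1) < 1e-12))
  expect_named(same$summary, c("r_max", "r_min", "mean_abs_r", "n_sig"))
  expect_error(probe_autocorrelation(d$birth$beta[1:2, ], d$age7$beta[1:2, ],
                                     ids), "3 shared")
})

test_that("co-methylation structure: identity similarity, null pair rate", {
  d <- small_cohort()
  cm <- comethylation_structure(d$birth, d$truth$dmp_ids)
  expect_equal(dim(cm$R), c(65, 65))
  expect_named(cm$summary, c("pct_sig", "r_max", "r_min"))
  cmp <- compare_structures(cm$R, cm$R)
  expect_equal(cmp$similarity, 1)
  ## independent probes: at most ~5% of pairs reach q < 0.05
  set.seed(31)
  X <- matrix(runif(1000 * 30, 0.2, 0.8), 1000, 30,
              dimnames = list(NULL, paste0("cg", 1:30)))
  cm0 <- comethylation_structure(X, colnames(X))
  expect_lte(cm0$summary[["pct_sig"]], 5)
  expect_error(comethylation_structure(cbind(X, cgZ = rep(0.5, 1000)),
                                       c(colnames(X), "cgZ")), "constant")
})
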