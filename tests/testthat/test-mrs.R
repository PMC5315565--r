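# Cumulative weighted methylation risk score and downstream correlations.

make_dmps <- function(ids, w) {
  d <- data.frame(probe_id = ids, std_beta = w,
                  p = rep(1e-6, length(ids)), q = rep(0.01, length(ids)))
  class(d) <- c("dmp_set", "data.frame")
  d
}

test_that("score arithmetic: zero weights, published-weight example,
          exact weighted sum", {
  B <- matrix(0.5, 3, 2, dimnames = list(paste0("s", 1:3), c("cgA", "cgB")))
  expect_equal(compute_mrs(B, make_dmps(c("cgA", "cgB"), c(0, 0)))$score,
               c(0, 0, 0))
  ## the two largest published discovery weights applied to betas of 0.5
  s <- compute_mrs(B, make_dmps(c("cgA", "cgB"), c(-0.34, 0.31)))
  expect_equal(s$score, rep(-0.015, 3), tolerance = 1e-12)
  ## and the same numbers straight from the published table
  tab <- published_dmp_stats()
  expect_equal(0.5 * tab$std_beta[1] + 0.5 * tab$std_beta[2], -0.015)
  ## exact weighted sum on arbitrary matrices
  set.seed(3)
  B2 <- matrix(runif(50 * 4, 0.1, 0.9), 50,
               dimnames = list(sprintf("s%02d", 1:50), paste0("cg", 1:4)))
  w <- rnorm(4)
  s2 <- compute_mrs(B2, make_dmps(colnames(B2), w))
  expect_equal(s2$score, as.numeric(B2 %*% w), tolerance = 1e-12)
  expect_error(compute_mrs(B2, make_dmps("cgX", 1)), "missing")
})

test_that("score is linear in the weights and equivariant to sample order", {
  set.seed(4)
  B <- matrix(runif(40 * 5, 0.1, 0.9), 40,
              dimnames = list(sprintf("s%02d", 1:40), paste0("cg", 1:5)))
  w1 <- rnorm(5); w2 <- rnorm(5)
  s12 <- compute_mrs(B, make_dmps(colnames(B), w1 + w2))$score
  expect_equal(s12, compute_mrs(B, make_dmps(colnames(B), w1))$score +
                 compute_mrs(B, make_dmps(colnames(B), w2))$score,
               tolerance = 1e-12)
  perm <- sample(40)
  expect_equal(compute_mrs(B[perm, ], make_dmps(colnames(B), w1))$score,
               compute_mrs(B, make_dmps(colnames(B), w1))$score[perm])
})

test_that("risk score tracks the generating liability on a planted cohort", {
  cfg <- sim_config(n_samples = 1000, n_probes = 2000, seed = 15)
  d <- simulate_cohort(cfg)
  tab <- run_ewas(d$birth, d$truth$liability,
                  data.frame(sex = d$cohort$sex))
  dm <- select_dmps(tab)
  s <- compute_mrs(d$birth, dm)
  expect_gt(cor(s$score, d$truth$liability), 0.3)
})

test_that("weighted scores beat unweighted means under heterogeneous effects", {
  ## planted effects have mixed signs, so the unweighted mean cancels
  wins <- 0
  for (i in 1:10) {
    cfg <- sim_config(n_samples = 200, n_probes = 500, n_dmps = 30,
                      n_mqtl_dmps = 0, n_panel_probes = 50, seed = 400 + i)
    d <- simulate_cohort(cfg)
    tab <- run_ewas(d$birth, d$truth$liability)
    dm <- make_dmps(d$truth$dmp_ids,
                    tab$std_beta[match(d$truth$dmp_ids, tab$probe_id)])
    weighted <- compute_mrs(d$birth, dm)$score
    unweighted <- rowMeans(d$birth$beta[, d$truth$dmp_ids])
    if (abs(cor(weighted, d$truth$liability)) >=
        abs(cor(unweighted, d$truth$liability))) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("mQTL exclusion removes listed probes with a cis/trans split", {
  dm <- make_dmps(sprintf("cg%02d", 1:65), rep(0.3, 65))
  ## empty table is the identity
  empty <- data.frame(probe_id = character(0), type = character(0))
  expect_equal(nrow(exclude_mqtl_probes(dm, empty)), 65)
  mq <- data.frame(probe_id = sprintf("cg%02d", 1:5),
                   type = c("cis", "cis", "cis", "cis", "trans"))
  red <- exclude_mqtl_probes(dm, mq)
  expect_equal(nrow(red), 60)
  expect_equal(attr(red, "n_removed"), 5)
  expect_equal(attr(red, "n_cis"), 4)
  expect_equal(attr(red, "n_trans"), 1)
})

test_that("full and mQTL-excluded scores are nearly interchangeable", {
  d <- small_cohort()
  tab <- run_ewas(d$birth, d$truth$liability, data.frame(sex = d$cohort$sex))
  dm <- select_dmps(tab)
  red <- exclude_mqtl_probes(dm, d$mqtl_table)
  expect_lt(nrow(red), nrow(dm) + 1)
  s_full <- compute_mrs(d$birth, dm)
  s_red <- compute_mrs(d$birth, red, variant = "mqtl_excluded")
  expect_gt(cor(s_full$score, s_red$score), 0.95)
})

test_that("exposure screen: layout, perfect correlation, BH family per row", {
  set.seed(5)
  n <- 200
  score <- rnorm(n)
  outcome <- rnorm(n)
  expos <- data.frame(maternal_smoking = score,  # identical to the score
                      maternal_alcohol = rnorm(n),
                      maternal_risks = rnorm(n),
                      family_risks = rnorm(n),
                      contextual_risks = rnorm(n),
                      life_events = rnorm(n))
  out <- screen_exposures(score, outcome, expos)
  expect_equal(nrow(out), 12)
  expect_setequal(unique(out$variable), c("dnam_risk", "substance_use"))
  r11 <- out$r[out$variable == "dnam_risk" &
                 out$exposure == "maternal_smoking"]
  expect_equal(r11, 1)
  ## q-values computed within each row's 6-exposure family
  for (v in unique(out$variable)) {
    sub <- out[out$variable == v, ]
    expect_equal(sub$q, bh_bruteforce(sub$p), tolerance = 1e-12)
  }
  expos$maternal_alcohol <- rep(1, n)
  expect_error(screen_exposures(score, outcome, expos), "constant")
})

test_that("only a truly associated exposure survives the screen", {
  hits_ok <- 0
  for (i in 1:50) {
    set.seed(500 + i)
    n <- 500
    smoke <- rbinom(n, 1, 0.2)
    smoke_std <- (smoke - mean(smoke)) / sd(smoke)
    score <- 0.25 * smoke_std + sqrt(1 - 0.25^2) * rnorm(n)
    expos <- data.frame(maternal_smoking = smoke,
                        maternal_alcohol = sample(0:3, n, TRUE),
                        maternal_risks = rnorm(n), family_risks = rnorm(n),
                        contextual_risks = rnorm(n), life_events = rnorm(n))
    out <- screen_exposures(score, rnorm(n), expos)
    sub <- out[out$variable == "dnam_risk", ]
    sig <- sub$exposure[sub$q < 0.05]
    if (identical(sig, "maternal_smoking")) hits_ok <- hits_ok + 1
  }
  ## the exact "smoking and nothing else" event has population rate
  ## ~0.90 (smoking is always detected; some null exposure slips through
  ## the q<0.05 screen in ~10% of cohorts), so the empirical count over 50
  ## replicates is tested with its binomial sampling error allowed for
  expect_gte(hits_ok, 42)
})

test_that("onset correlations: subgroup restriction, planted negative trend,
          degenerate subgroups", {
  ## degenerate: constant onset in the subgroup is flagged
  out <- onset_correlation(rnorm(10),
                           data.frame(onset_age_cigarette = rep(15, 10)))
  expect_equal(out$flag, "constant_onset")
  out2 <- onset_correlation(rnorm(10),
                            data.frame(onset_age_cigarette =
                                         c(15, 16, rep(NA, 8))))
  expect_equal(out2$flag, "too_few_endorsers")
  ## planted r = -0.3 among 100 endorsers lands in [-0.45, -0.15] mostly
  inside <- 0
  for (i in 1:50) {
    set.seed(600 + i)
    L <- rnorm(100)
    age <- 15 - 0.3 * L + sqrt(1 - 0.09) * rnorm(100)
    res <- onset_correlation(L, data.frame(onset_age_cigarette = age))
    if (res$r > -0.45 && res$r < -0.15) inside <- inside + 1
  }
  expect_gte(inside, 40)
  ## reporting shape: (substance, n, r, p)
  expect_named(res, c("substance", "n", "r", "p", "flag"))
  expect_equal(res$n, 100)
})
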