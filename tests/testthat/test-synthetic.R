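test_that("trial simulation is a pure function of (config, seed)", {
  d <- two_stage_design(3, 17, 10, 37, p0 = 0.2, p1 = 0.4)
  a <- simulate_trial(d, 0.3, reps = 500, seed = 42)
  b <- simulate_trial(d, 0.3, reps = 500, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, simulate_trial(d, 0.3, reps = 500, seed = 43)))
})

test_that("trial simulation respects the decision rule", {
  d <- two_stage_design(3, 17, 10, 37, p0 = 0.2, p1 = 0.4)
  expect_equal(sum(simulate_trial(d, 0, reps = 2000, seed = 1)$reject), 0)
  sim <- simulate_trial(d, 0.3, reps = 5000, seed = 2)
  expect_true(all(sim$s_total[sim$reject] >= d$r + 1))
  expect_true(all(!sim$reject[!sim$continued]))
  expect_true(all(sim$s_total[!sim$continued] <= d$r1))
  # under-enrolment: rejections follow the recalibrated per-s1 threshold
  sim36 <- simulate_trial(d, 0.3, n_attained = 36, reps = 5000, seed = 3)
  thr <- vapply((d$r1 + 1):d$n1,
                function(s) suppressWarnings(recalibrate_threshold(d, s, 19)),
                integer(1))
  names(thr) <- (d$r1 + 1):d$n1
  cont <- sim36$continued
  expect_equal(sim36$reject[cont],
               sim36$s_total[cont] >= thr[as.character(sim36$s1[cont])],
               ignore_attr = TRUE)
})

test_that("simulated rejection frequency matches the exact calculation", {
  d <- two_stage_design(3, 17, 10, 37, p0 = 0.2, p1 = 0.4)
  for (p in c(0.2, 0.4)) {
    sim <- simulate_trial(d, p, reps = 20000, seed = 11)
    exact <- reject_prob(d, p)
    se <- sqrt(exact * (1 - exact) / 20000)
    expect_lt(abs(mean(sim$reject) - exact), 3 * se)
  }
})

test_that("simulated counts match the negative-binomial moments", {
  cfg <- cohort_config(n_cb = 5000, n_ncb = 5000, n_genes = 6,
                       planted_sets = list(p = list(genes = 1:2, lfc = 1,
                                                    up_in = "NCB")),
                       seed = 7)
  coh <- simulate_expression_cohort(cfg)
  gp <- coh$truth$gene_params
  sf <- coh$truth$size_factor
  cb <- coh$clinical$benefit == "CB"
  for (i in 3:6) {  # unplanted genes: no group shift
    mu_g <- exp(gp$base_log_mean[i])
    x <- coh$counts[i, cb]
    mu_i <- mu_g * sf[cb]              # per-sample conditional means
    expect_lt(abs(mean(x) - mean(mu_i)),
              3 * sqrt(sum(mu_i + gp$dispersion[i] * mu_i^2)) / sum(cb))
    v_theory <- mean(mu_i + gp$dispersion[i] * mu_i^2) + var(mu_i)
    expect_lt(abs(var(x) / v_theory - 1), 0.15)
  }
  # planted genes: 2^lfc shift in the NCB group only
  mu_ncb <- exp(gp$base_log_mean[1]) * 2 * sf[!cb]
  expect_lt(abs(mean(coh$counts[1, !cb]) - mean(mu_ncb)) / mean(mu_ncb), 0.05)
})

test_that("survival generator: event fraction under a flat hazard", {
  cfg <- cohort_config(n_cb = 500, n_ncb = 500, n_genes = 10,
                       planted_sets = list(p = list(genes = 1:3, lfc = 0,
                                                    up_in = "NCB")),
                       hazard_theta = 0, lambda0 = 0.2, censor_time = 24,
                       seed = 19)
  coh <- simulate_expression_cohort(cfg)
  p_event <- 1 - exp(-0.2 * 24)
  se <- sqrt(p_event * (1 - p_event) / 1000)
  expect_lt(abs(mean(coh$clinical$event) - p_event), 3 * se)
  expect_true(all(coh$clinical$pfs_months <= 24))
})

test_that("cohort generation is deterministic and respects its config checks", {
  cfg <- cohort_config(n_genes = 50,
                       planted_sets = list(p = list(genes = 1:5, lfc = 1,
                                                    up_in = "NCB")),
                       seed = 4)
  a <- simulate_expression_cohort(cfg)
  b <- simulate_expression_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$clinical, b$clinical)
  expect_error(cohort_config(n_genes = 10,
                             planted_sets = list(p = list(genes = 1:20,
                                                          lfc = 1,
                                                          up_in = "NCB")),
                             seed = 1),
               "beyond n_genes")
  expect_error(cohort_config(seed = 1, censor_time = -1), "censor_time")
})

test_that("derived benefit labels reproduce the planted groups", {
  cfg <- cohort_config(n_genes = 100, seed = 23)
  coh <- simulate_expression_cohort(cfg)
  derived <- label_benefit(coh$clinical$response, coh$clinical$pfs_months)
  expect_equal(as.character(derived$benefit),
               as.character(coh$clinical$benefit))
})

test_that("null cohorts carry no signal: planted-set AUC near 1/2", {
  aucs <- vapply(1:50, function(i) {
    cfg <- cohort_config(n_cb = 10, n_ncb = 10, n_genes = 100,
                         planted_sets = list(p = list(genes = 1:10, lfc = 0,
                                                      up_in = "NCB")),
                         hazard_theta = 0, seed = 1000 + i)
    coh <- simulate_expression_cohort(cfg)
    sc <- singscore_up(normalize_logcpm(coh$counts),
                       coh$truth$planted_genes$p)
    auc_benefit(sc[coh$clinical$sample], coh$clinical$benefit)$auc
  }, numeric(1))
  se <- sd(aucs) / sqrt(50)
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.01)
})

test_that("hazard-linked scores recover the survival direction", {
  neg <- vapply(1:20, function(i) {
    cfg <- cohort_config(n_cb = 15, n_ncb = 15, n_genes = 200,
                         planted_sets = list(p = list(genes = 1:20, lfc = 1,
                                                      up_in = "NCB")),
                         hazard_theta = 0.8, lambda0 = 0.2, censor_time = 24,
                         seed = 3000 + i)
    coh <- simulate_expression_cohort(cfg)
    sc <- singscore_up(normalize_logcpm(coh$counts),
                       coh$truth$planted_genes$p)
    spearman_pfs(sc[coh$clinical$sample], coh$clinical$pfs_months)$rho < 0
  }, logical(1))
  expect_gte(mean(neg), 0.9)
})

test_that("association p-values are uniform under fully null data", {
  ps <- vapply(1:2000, function(i) {
    cfg <- cohort_config(n_cb = 15, n_ncb = 15, n_genes = 20,
                         planted_sets = list(p = list(genes = 1:5, lfc = 0,
                                                      up_in = "NCB")),
                         hazard_theta = 0, seed = 10000 + i)
    coh <- simulate_expression_cohort(cfg)
    sc <- singscore_up(normalize_logcpm(coh$counts),
                       coh$truth$planted_genes$p)
    spearman_pfs(sc[coh$clinical$sample], coh$clinical$pfs_months)$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("median-split survival comparison recovers a planted hazard link", {
  hits <- vapply(1:50, function(i) {
    cfg <- cohort_config(n_cb = 30, n_ncb = 30, n_genes = 100,
                         planted_sets = list(p = list(genes = 1:20, lfc = 1,
                                                      up_in = "NCB")),
                         hazard_theta = 0.8, seed = 5000 + i)
    coh <- simulate_expression_cohort(cfg)
    sc <- singscore_up(normalize_logcpm(coh$counts),
                       coh$truth$planted_genes$p)[coh$clinical$sample]
    g <- factor(ifelse(sc > median(sc), "high", "low"),
                levels = c("low", "high"))
    km <- suppressWarnings(km_logrank_hr(coh$clinical$pfs_months,
                                         coh$clinical$event, g))
    !is.na(km$hr) && km$hr > 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
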