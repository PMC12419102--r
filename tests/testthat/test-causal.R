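test_that("risk strata split 50/25/25 with distinct risks", {
  st <- stratify_by_overall_risk(1:100)
  expect_equal(as.vector(table(st)), c(50, 25, 25))
  expect_identical(levels(st), c("low", "medium", "high"))
})

test_that("degenerate risk inputs collapse to one stratum with a warning", {
  expect_warning(st <- stratify_by_overall_risk(rep(0.03, 50)), "one stratum")
  expect_equal(dplyr::n_distinct(st), 1L)
  expect_warning(st2 <- stratify_by_overall_risk(c(0.1, 0.2)), "fewer than 4")
  expect_equal(dplyr::n_distinct(st2), 1L)
  expect_error(stratify_by_overall_risk(c(0.1, NA)), "finite")
})

test_that("stratum proportions on a seeded fixture are within 1/n of 50/25/25", {
  set.seed(60)
  risks <- rbeta(2000, 1, 20)
  st <- stratify_by_overall_risk(risks)
  props <- as.vector(table(st)) / 2000
  expect_true(all(abs(props - c(0.5, 0.25, 0.25)) <= 1 / 2000 + 1e-12))
})

test_that("estimate_effects enforces consistent model scopes and scorer group", {
  sim <- small_sim(seed = 61)
  ms <- quick_models(sim$cohort, h = "1")
  sc1 <- fit_anomaly_scorer(sim$cohort, "1", xcols(sim$cohort),
                            num_trees = 30, seed = 1)
  sc2 <- fit_anomaly_scorer(sim$cohort, "2", xcols(sim$cohort),
                            num_trees = 30, seed = 1)
  expect_error(estimate_effects(sim$cohort, "2", ms$h, ms$o, sc2), "scope")
  expect_error(estimate_effects(sim$cohort, "1", ms$h, ms$h, sc1), "scope")
  expect_error(estimate_effects(sim$cohort, "1", ms$h, ms$o, sc2), "scorer")
})

test_that("estimates follow the in/out-of-hospital estimator switch", {
  sim <- small_sim(seed = 62)
  co <- sim$cohort
  ms <- quick_models(co, h = "1")
  sc <- fit_anomaly_scorer(co, "1", xcols(co), num_trees = 50, seed = 2)
  est <- estimate_effects(co, "1", ms$h, ms$o, sc)

  expect_equal(nrow(est), nrow(co))
  expect_identical(sum(est$origin == "in_h") + sum(est$origin == "out_h"),
                   nrow(co))
  expect_true(all(est$tau > 0))
  expect_equal(est$log_tau, log(est$theta_h) - log(est$theta_o),
               tolerance = 1e-15)
  expect_true(all(est$anomaly_score[est$keep] >= 0.05))

  # hospital-1 rows carry the hospital model's OOB estimate ...
  oob <- predict_risk_oob(ms$h)
  in_rows <- est[est$origin == "in_h", ]
  expect_equal(in_rows$theta_h, oob$risk[match(in_rows$id, oob$id)],
               tolerance = 1e-12)
  # ... and everyone else the full-ensemble estimate
  full <- predict_risk(ms$h, co)
  out_rows <- est[est$origin == "out_h", ]
  expect_equal(out_rows$theta_h, full$risk[match(out_rows$id, full$id)],
               tolerance = 1e-12)
  # the denominator is the overall model's OOB prediction for every row
  oob_o <- predict_risk_oob(ms$o)
  expect_equal(est$theta_o, oob_o$risk[match(est$id, oob_o$id)],
               tolerance = 1e-12)
})

test_that("relabelling a patient flips their numerator from OOB to full-model", {
  sim <- small_sim(seed = 63)
  co <- sim$cohort
  ms <- quick_models(co, h = "1")
  sc <- fit_anomaly_scorer(co, "1", xcols(co), num_trees = 50, seed = 3)
  est <- estimate_effects(co, "1", ms$h, ms$o, sc)

  # pick an in-hospital patient whose OOB and full-model estimates differ,
  # so the estimator switch is observable
  oob_h <- predict_risk_oob(ms$h)
  full_h <- predict_risk(ms$h, co)
  cand <- est$id[est$origin == "in_h"]
  diffs <- abs(oob_h$risk[match(cand, oob_h$id)] -
                 full_h$risk[match(cand, full_h$id)])
  target <- cand[which.max(diffs)]
  relabelled <- co
  relabelled$hospital[relabelled$id == target] <- factor("2", levels = levels(co$hospital))
  est2 <- estimate_effects(relabelled, "1", ms$h, ms$o, sc)

  expect_identical(est2$origin[est2$id == target], "out_h")
  full <- predict_risk(ms$h, co[co$id == target, ])
  expect_equal(est2$theta_h[est2$id == target], unname(full$risk),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(est$theta_h[est$id == target],
                                unname(full$risk))))
})

test_that("the threshold only removes rows, never changes kept estimates", {
  sim <- small_sim(seed = 64)
  co <- sim$cohort
  ms <- quick_models(co, h = "2")
  sc <- fit_anomaly_scorer(co, "2", xcols(co), num_trees = 50, seed = 4)
  lo <- estimate_effects(co, "2", ms$h, ms$o, sc, threshold = 0.05)
  hi <- estimate_effects(co, "2", ms$h, ms$o, sc, threshold = 0.3)
  expect_lte(sum(hi$keep), sum(lo$keep))
  shared <- intersect(lo$id[lo$keep], hi$id[hi$keep])
  expect_equal(lo$tau[match(shared, lo$id)], hi$tau[match(shared, hi$id)],
               tolerance = 1e-15)
})

test_that("pairwise effects carry the declared sign convention", {
  sim <- small_sim(seed = 65)
  co <- sim$cohort
  ma <- fit_risk_model(co, "1", num_trees = 60, seed = 5)
  mb <- fit_risk_model(co, "2", num_trees = 60, seed = 6)
  sa <- fit_anomaly_scorer(co, "1", xcols(co), num_trees = 50, seed = 7)
  sb <- fit_anomaly_scorer(co, "2", xcols(co), num_trees = 50, seed = 8)
  pw <- pairwise_effects(co, "1", "2", ma, mb, sa, sb)

  expect_equal(pw$log_tau, log(pw$theta_b) - log(pw$theta_a),
               tolerance = 1e-15)
  # positive log tau exactly when hospital b's predicted risk is higher,
  # i.e. the first-listed hospital is better
  expect_identical(pw$log_tau > 0, pw$theta_b > pw$theta_a)
  # kept rows must be valid twins under BOTH scorers
  expect_true(all(pw$score_a[pw$keep] >= 0.05 & pw$score_b[pw$keep] >= 0.05))
  expect_true(any(!pw$keep))
})

test_that("pairwise subgroup filters restrict rows; empty subgroups warn", {
  sim <- small_sim(seed = 66)
  co <- sim$cohort
  ma <- fit_risk_model(co, "1", num_trees = 30, seed = 5)
  mb <- fit_risk_model(co, "2", num_trees = 30, seed = 6)
  sa <- fit_anomaly_scorer(co, "1", xcols(co), num_trees = 30, seed = 7)
  sb <- fit_anomaly_scorer(co, "2", xcols(co), num_trees = 30, seed = 8)

  sub <- pairwise_effects(co, "1", "2", ma, mb, sa, sb, subgroup = x1 > 0)
  expect_equal(sort(sub$id), sort(co$id[co$x1 > 0]))

  expect_warning(
    empty <- pairwise_effects(co, "1", "2", ma, mb, sa, sb,
                              subgroup = x1 > 1e9),
    "0 rows")
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_kept"), 0L)
})

test_that("a protective hospital shows positive pairwise advantage", {
  # hospital 1 carries delta = -0.7, hospital 2 is average: the
  # head-to-head log relative risk of 1 vs 2 should be positive on average
  means <- sapply(1:3, function(s) {
    sim <- simulate_cohort(sim_config(n_hospitals = 2, sizes = 1000,
                                      hospital_logit_shifts = c(-0.7, 0),
                                      seed = 600 + s))
    co <- sim$cohort
    ma <- fit_risk_model(co, "1", num_trees = 200, seed = s)
    mb <- fit_risk_model(co, "2", num_trees = 200, seed = s + 50)
    sa <- fit_anomaly_scorer(co, "1", xcols(co), num_trees = 100, seed = s)
    sb <- fit_anomaly_scorer(co, "2", xcols(co), num_trees = 100, seed = s)
    pw <- pairwise_effects(co, "1", "2", ma, mb, sa, sb)
    mean(pw$log_tau[pw$keep])
  })
  expect_gte(sum(means > 0), 2)
})

test_that("hospital-effect estimates track the true effect size", {
  sim <- simulate_cohort(sim_config(n_hospitals = 2, sizes = 2000,
                                    hospital_logit_shifts = c(-0.7, 0),
                                    seed = 67))
  co <- sim$cohort
  mh <- fit_risk_model(co, "1", num_trees = 500, seed = 1)
  mo <- fit_risk_model(co, "overall", num_trees = 500, seed = 2)
  sc <- fit_anomaly_scorer(co, "1", xcols(co), num_trees = 150, seed = 3)
  est <- estimate_effects(co, "1", mh, mo, sc)
  med_hat <- median(est$tau[est$keep])
  med_true <- median(sim$truth$tau[sim$truth$hospital == "1"])
  expect_lt(med_hat, 1)
  expect_lt(abs(med_hat - med_true) / med_true, 0.3)
})
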