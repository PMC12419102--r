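test_that("a scope with no events is refused, naming the group", {
  co <- tibble::tibble(
    id = 1:40,
    hospital = factor(rep(c(1, 2), each = 20)),
    y = c(rbinom(20, 1, 0.5) * 0L, rep(0L, 20)),
    x1 = rnorm(40)
  )
  co$y[co$hospital == "1"] <- rep(c(0L, 1L), 10)
  expect_error(fit_risk_model(co, scope = "2", num_trees = 10),
               "degenerate outcome.*'2'")
  expect_error(fit_risk_model(co, scope = "3"), "no rows")
})

test_that("separable toy data is predicted at the clamp boundaries", {
  co <- tibble::tibble(
    id = 1:10,
    hospital = factor(rep(1, 10)),
    y = rep(c(0L, 1L), each = 5),
    x1 = c(1:5, 101:105)
  )
  m <- fit_risk_model(co, scope = "overall", num_trees = 50,
                      min_node_size = 1, seed = 4)
  pr <- predict_risk(m, co)
  expect_true(all(pr$risk[co$y == 1] >= 1 - m$epsilon))
  expect_true(all(pr$risk[co$y == 0] <= m$epsilon))
})

test_that("the classification threshold defaults to the training prevalence", {
  sim <- small_sim(seed = 31)
  m <- fit_risk_model(sim$cohort, scope = "overall", num_trees = 30, seed = 1)
  expect_equal(m$q, mean(sim$cohort$y))
  m2 <- fit_risk_model(sim$cohort, scope = "overall", num_trees = 30,
                       q = 0.2, seed = 1)
  expect_equal(m2$q, 0.2)
  expect_equal(m$epsilon, 1 / (2 * 30))
})

test_that("rfq_classify thresholds risks as specified", {
  expect_identical(rfq_classify(c(0.01, 0.05, 0.50), q = 0.03),
                   c(0L, 1L, 1L))
  expect_identical(rfq_classify(c(0.4, 0.6), q = 0.5), c(0L, 1L))
  expect_error(rfq_classify(c(0.1), q = 0), "q must")
  preds <- tibble::tibble(risk = c(0.2, 0.8))
  expect_identical(rfq_classify(preds, 0.5), c(0L, 1L))
})

test_that("predictions are deterministic and duplicate rows agree", {
  sim <- small_sim(seed = 32)
  m <- fit_risk_model(sim$cohort, scope = "1", num_trees = 40, seed = 2)
  probe <- sim$cohort[rep(7, 2), ]
  pr <- predict_risk(m, probe)
  expect_identical(pr$risk[1], pr$risk[2])
  expect_identical(predict_risk(m, sim$cohort)$risk,
                   predict_risk(m, sim$cohort)$risk)
})

test_that("missing feature columns are reported by name", {
  sim <- small_sim(seed = 33)
  m <- fit_risk_model(sim$cohort, scope = "overall", num_trees = 20, seed = 1)
  broken <- dplyr::select(sim$cohort, -"x2")
  expect_error(predict_risk(m, broken), "x2")
})

test_that("ensemble predictions equal brute-force per-tree aggregation", {
  sim <- small_sim(seed = 34, sizes = c(60, 60, 60))
  m <- fit_risk_model(sim$cohort, scope = "overall", num_trees = 25,
                      min_node_size = 5, seed = 6)

  # oracle: per-tree terminal-node event frequencies, averaged in an
  # explicit loop over rows and trees
  pa <- predict(m$forest, data = sim$cohort[, m$features],
                predict.all = TRUE, num.threads = 1)$predictions
  ev <- match("1", m$forest$forest$levels)
  n <- nrow(sim$cohort)

  full_oracle <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (t in seq_len(m$num_trees)) acc <- acc + pa[i, ev, t]
    full_oracle[i] <- acc / m$num_trees
  }
  full_pkg <- predict_risk(m, sim$cohort)
  expect_equal(full_pkg$risk, pmin(pmax(full_oracle, m$epsilon), 1 - m$epsilon),
               tolerance = 1e-10)

  # OOB oracle: only trees where the row was out-of-bag
  oob_oracle <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0; used <- 0
    for (t in seq_len(m$num_trees)) {
      if (m$inbag[i, t] == 0) { acc <- acc + pa[i, ev, t]; used <- used + 1 }
    }
    oob_oracle[i] <- acc / used
  }
  oob_pkg <- predict_risk_oob(m)
  expect_identical(oob_pkg$id, sim$cohort$id)
  expect_equal(oob_pkg$risk, pmin(pmax(oob_oracle, m$epsilon), 1 - m$epsilon),
               tolerance = 1e-10)
})

test_that("every training row is out-of-bag somewhere and clamping bounds hold", {
  sim <- small_sim(seed = 35)
  m <- fit_risk_model(sim$cohort, scope = "overall", num_trees = 30, seed = 3)
  expect_true(all(rowSums(m$inbag == 0) > 0))
  oob <- predict_risk_oob(m)
  expect_true(all(oob$risk >= m$epsilon & oob$risk <= 1 - m$epsilon))
})

test_that("OOB estimates are less optimistic than full in-sample estimates", {
  sim <- small_sim(seed = 36)
  logloss <- function(y, p) -mean(y * log(p) + (1 - y) * log(1 - p))
  for (scope in c("3", "overall")) {
    m <- fit_risk_model(sim$cohort, scope = scope, num_trees = 80, seed = 5)
    y <- m$train_y
    full <- predict_risk(m, dplyr::arrange(
      sim$cohort[sim$cohort$id %in% m$train_ids, ], id))
    oob <- predict_risk_oob(m)
    expect_gte(logloss(y, oob$risk), logloss(y, full$risk))
  }
})

test_that("fitting is invariant to training-row order", {
  sim <- small_sim(seed = 37)
  shuffled <- sim$cohort[sample(nrow(sim$cohort)), ]
  m1 <- fit_risk_model(sim$cohort, scope = "overall", num_trees = 40, seed = 8)
  m2 <- fit_risk_model(shuffled, scope = "overall", num_trees = 40, seed = 8)
  p1 <- predict_risk_oob(m1)
  p2 <- predict_risk_oob(m2)
  expect_identical(p1$id, p2$id)
  expect_lt(max(abs(p1$risk - p2$risk)), 1e-10)
})

test_that("prevalence-threshold classification beats 0.5 on sensitivity for rare events", {
  sim <- simulate_cohort(sim_config(n_hospitals = 1, sizes = 5000,
                                    target_prevalence = 0.03, seed = 38))
  m <- fit_risk_model(sim$cohort, scope = "overall", num_trees = 150,
                      seed = 9)
  oob <- predict_risk_oob(m)
  y <- m$train_y
  tpr <- function(lab) sum(lab == 1 & y == 1) / sum(y == 1)
  expect_gt(tpr(rfq_classify(oob, m$q)), tpr(rfq_classify(oob, 0.5)))
})

test_that("overall OOB risk error shrinks as the cohort grows", {
  err <- sapply(c(500, 5000), function(n) {
    sim <- simulate_cohort(sim_config(n_hospitals = 1, sizes = n, seed = 39))
    m <- fit_risk_model(sim$cohort, scope = "overall", num_trees = 150,
                        seed = 10)
    oob <- predict_risk_oob(m)
    truth <- sim$truth$theta_o[match(oob$id, sim$truth$id)]
    mean(abs(oob$risk - truth))
  })
  expect_lt(err[2], err[1])
})

test_that("tidy and glance summarise a fitted risk model", {
  sim <- small_sim(seed = 40)
  m <- fit_risk_model(sim$cohort, scope = "1", num_trees = 30, seed = 11)
  td <- generics::tidy(m)
  expect_named(td, c("id", "y", "risk_oob", "label_rfq"))
  expect_equal(nrow(td), sum(sim$cohort$hospital == "1"))
  gl <- generics::glance(m)
  expect_equal(gl$scope, "1")
  expect_gt(gl$oob_fraction, 0.3)
  expect_lt(gl$oob_fraction, 0.45)
})

test_that("risk models round-trip through persistence with a sidecar", {
  sim <- small_sim(seed = 41, sizes = c(60, 60, 60))
  m <- fit_risk_model(sim$cohort, scope = "overall", num_trees = 20, seed = 12)
  path <- withr::local_tempfile(fileext = ".rds")
  save_risk_model(m, path)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(side$scope, "overall")
  expect_identical(side$features, as.list(m$features))
  back <- load_risk_model(path)
  expect_identical(predict_risk_oob(back)$risk, predict_risk_oob(m)$risk)
  expect_error(suppressWarnings(load_risk_model(withr::local_tempfile())))
})
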