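make_toy <- function(n = 200, seed = 1, separable = TRUE) {
  set.seed(seed)
  x <- rnorm(n)
  y <- if (separable) as.integer(x > 0) else rbinom(n, 1, 0.5)
  data.frame(cov1 = x, label = y, weight = 1)
}

test_that("AUC: rank formulation agrees with the all-pairs oracle", {
  expect_equal(auc_mw(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_mw(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(2)
  for (k in 1:5) {
    s <- round(runif(50), 2)              # rounded scores force ties
    y <- rbinom(50, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc_mw(s, y), oracle_auc_pairs(s, y), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(3)
  s <- rnorm(100); y <- rbinom(100, 1, 0.4)
  expect_equal(auc_mw(s, y), auc_mw(exp(s), y))
  expect_equal(auc_mw(s, y), auc_mw(qlogis(plogis(s)), y), tolerance = 1e-12)
})

test_that("evaluation returns perfect statistics on perfectly ranked scores", {
  ev <- evaluate(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(ev$auc, 1)
  expect_equal(ev$tss, 1)
  expect_equal(ev$pcc, 1)
  # TSS at the evaluation threshold equals Youden's J computed directly
  set.seed(4)
  s <- rnorm(80); y <- as.integer(s + rnorm(80) > 0)
  ev2 <- evaluate(s, y)
  sens <- sum(s >= ev2$threshold & y == 1) / sum(y == 1)
  spec <- sum(s < ev2$threshold & y == 0) / sum(y == 0)
  expect_equal(ev2$tss, sens + spec - 1, tolerance = 1e-12)
  expect_error(evaluate(c(1, 2), c(1, 1)), "single class")
})

test_that("BRT separates a separable toy and is weight-scale invariant", {
  toy <- make_toy(200, seed = 5)
  idx <- seq_len(160)
  b <- fit_brt(toy[idx, ], seed = 1)
  expect_equal(evaluate(b, toy[-idx, ])$auc, 1)

  toy2 <- toy; toy2$weight <- toy2$weight * 2
  b2 <- fit_brt(toy2[idx, ], seed = 1)
  expect_equal(predict(b, toy), predict(b2, toy), tolerance = 1e-12)

  one_class <- toy[toy$label == 1, ]
  expect_error(fit_brt(one_class, seed = 1), "single class")
})

test_that("RF separates a separable toy and is seed-deterministic", {
  toy <- make_toy(200, seed = 6)
  idx <- seq_len(160)
  r <- fit_rf(toy[idx, ], seed = 2)
  expect_equal(evaluate(r, toy[-idx, ])$auc, 1)
  r2 <- fit_rf(toy[idx, ], seed = 2)
  expect_identical(predict(r, toy), predict(r2, toy))
})

test_that("permuted labels give chance-level held-out AUC", {
  aucs <- sapply(1:10, function(s) {
    toy <- make_toy(120, seed = s, separable = FALSE)   # labels independent of x
    idx <- seq_len(90)
    ev_b <- evaluate(fit_brt(toy[idx, ], seed = s, max_trees = 500), toy[-idx, ])
    ev_r <- evaluate(fit_rf(toy[idx, ], seed = s), toy[-idx, ])
    c(ev_b$auc, ev_r$auc)
  })
  expect_lt(abs(mean(aucs[1, ]) - 0.5), 0.1)
  expect_lt(abs(mean(aucs[2, ]) - 0.5), 0.1)
})

test_that("threshold choice maximizes the sens/spec/PCC trade-off", {
  # perfectly separated scores: the gap midpoint, with perfect statistics
  th <- choose_threshold(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(th$threshold, 0.5)
  expect_equal(c(th$sensitivity, th$specificity, th$pcc), c(1, 1, 1))

  # exhaustive-scan oracle on an imperfect configuration
  s <- c(0.1, 0.3, 0.5, 0.7); y <- c(1, 0, 0, 0)
  th2 <- choose_threshold(s, y)
  cand <- c(min(s) - 1, (sort(unique(s))[-1] + sort(unique(s))[-4]) / 2, max(s) + 1)
  crit <- sapply(cand, function(t) {
    pred <- s >= t
    (sum(pred & y == 1) / 1 + sum(!pred & y == 0) / 3 + mean(pred == (y == 1))) / 3
  })
  expect_equal(th2$criterion, max(crit))
  expect_equal(th2$threshold, cand[which.max(crit)])
})

test_that("partial dependence matches its defining average", {
  toy <- make_toy(150, seed = 7)
  toy$cov2 <- rnorm(150)
  r <- fit_rf(toy, seed = 3)
  vals <- seq(-2, 2, length.out = 9)
  pd <- partial_dependence(r, toy, "cov1", vals)
  expect_equal(pd$dependence, oracle_partial_dependence(r, toy, "cov1", vals),
               tolerance = 1e-12)
  expect_true(all(pd$dependence >= 0 & pd$dependence <= 1))

  # single-covariate learner: the curve is the direct prediction
  toy1 <- make_toy(150, seed = 8)
  r1 <- fit_rf(toy1, seed = 3)
  pd1 <- partial_dependence(r1, toy1, "cov1", vals)
  direct <- predict(r1, data.frame(cov1 = vals))
  expect_equal(pd1$dependence, direct, tolerance = 1e-12)

  expect_error(partial_dependence(r, toy, "nope"), "unknown covariate")
})

test_that("variable contributions are normalized and noise gets little credit", {
  toy1 <- make_toy(150, seed = 9)
  r1 <- fit_rf(toy1, seed = 4)
  vc1 <- variable_contribution(r1)
  expect_equal(vc1$contribution_pct, 100)

  toy <- make_toy(400, seed = 10)
  toy$noise <- rnorm(400)
  b <- fit_brt(toy, seed = 4, max_trees = 1000)
  vc <- variable_contribution(b)
  expect_equal(sum(vc$contribution_pct), 100, tolerance = 1e-9)
  expect_lt(vc$contribution_pct[vc$covariate == "noise"], 5)
})

test_that("a 2-member ensemble is the cell-wise mean of its members", {
  w <- tiny_world(seed = 15, grid = c(20, 20), n_comm = 150)
  st <- standardize_stack(w$covariates)
  f <- extract_features(st, w$surveys)
  f$label <- as.integer(f$cov1 > 0)       # separable labels for this check
  train <- f
  ens <- run_ensemble(train, st, n_reps = 2, seed = 16, algorithms = "rf",
                      auc_min = 0, tss_min = -1)
  expect_equal(ncol(ens$member_predictions), 2)
  mean_v <- as.vector(ens$mean_suitability$values)[ens$cells]
  expect_equal(mean_v, rowMeans(ens$member_predictions), tolerance = 1e-12)
  # the ensemble mean lies inside the member envelope, and the limits map
  # is exactly the thresholded mean
  expect_true(all(mean_v >= apply(ens$member_predictions, 1, min) - 1e-12))
  expect_true(all(mean_v <= apply(ens$member_predictions, 1, max) + 1e-12))
  expect_equal(ens$limits$values,
               (ens$mean_suitability$values >= ens$threshold$threshold) * 1)
  expect_true(all(ens$ci_low$values <= ens$mean_suitability$values + 1e-12,
                  na.rm = TRUE))

  expect_error(run_ensemble(train, st, n_reps = 2, seed = 16,
                            algorithms = "rf", auc_min = 1.01),
               "no run passed selection")
})
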