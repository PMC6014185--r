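training_xy <- function(train) {
  covs <- setdiff(names(train), c("label", "weight",
                                  "community_id", "x_km", "y_km",
                                  "n_screened", "n_cases"))
  y <- if (is.numeric(train$label)) as.integer(train$label > 0)
       else as.integer(train$label == "presence")
  w <- train$weight %||% rep(1, nrow(train))
  if (length(unique(y)) < 2) {
    stop("training set contains a single class", call. = FALSE)
  }
  list(x = as.matrix(train[, covs, drop = FALSE]), y = y, w = w, covariates = covs)
}

#' Fit a boosted regression tree suitability learner
#'
#' Gradient-boosted trees at a deliberately small learning rate (0.005) and
#' interaction depth 4, honouring observation weights. The tree count is
#' chosen by early stopping on an internal 10% validation fold (capped at
#' `max_trees`), the usual way of tuning boosting length at a fixed small
#' learning rate. Regularisation terms that would break weight-scale
#' invariance are disabled, so rescaling all weights by a constant leaves
#' predictions unchanged.
#'
#' @param train a `weighted_training_set` (or any data.frame with covariate
#'   columns plus `label` and optionally `weight`).
#' @param lr learning rate.
#' @param max_interactions interaction depth of each tree.
#' @param seed integer seed (internal validation split).
#' @param max_trees boosting-round cap.
#' @return a `podomap_learner` (algorithm `"BRT"`).
#' @export
fit_brt <- function(train, lr = 0.005, max_interactions = 4, seed = 1,
                    max_trees = 5000) {
  d <- training_xy(train)
  set.seed(seed)
  n <- nrow(d$x)
  n_val <- max(2L, floor(0.1 * n))
  val <- sample.int(n, n_val)
  # the validation fold must contain both classes for logloss to rank rounds
  tries <- 0
  while ((length(unique(d$y[val])) < 2 || length(unique(d$y[-val])) < 2) &&
         tries < 50) {
    val <- sample.int(n, n_val); tries <- tries + 1
  }
  dtr <- xgboost::xgb.DMatrix(d$x[-val, , drop = FALSE], label = d$y[-val],
                              weight = d$w[-val], nthread = 1)
  dva <- xgboost::xgb.DMatrix(d$x[val, , drop = FALSE], label = d$y[val],
                              weight = d$w[val], nthread = 1)
  params <- xgboost::xgb.params(
    objective = "binary:logistic", learning_rate = lr,
    max_depth = max_interactions, reg_lambda = 0, reg_alpha = 0,
    min_child_weight = 0, subsample = 1, nthread = 1,
    eval_metric = "logloss")
  bst <- xgboost::xgb.train(params, dtr, nrounds = max_trees,
                            evals = list(val = dva),
                            early_stopping_rounds = 50, verbose = 0)
  structure(list(algorithm = "BRT", model = bst, covariates = d$covariates),
            class = "podomap_learner")
}

#' Fit a random forest suitability learner
#'
#' A 500-tree probability forest with sqrt(p) candidate features per split
#' (the default parameterisation of random forests in distribution
#' modelling), honouring observation weights as case weights.
#'
#' @inheritParams fit_brt
#' @param num_trees number of trees.
#' @return a `podomap_learner` (algorithm `"RF"`).
#' @export
fit_rf <- function(train, seed = 1, num_trees = 500) {
  d <- training_xy(train)
  df <- as.data.frame(d$x)
  df$.y <- factor(d$y, levels = c(0, 1))
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = num_trees, mtry = max(1, floor(sqrt(ncol(d$x)))),
    probability = TRUE, case.weights = d$w, importance = "impurity",
    seed = seed, num.threads = 1)
  structure(list(algorithm = "RF", model = fit, covariates = d$covariates),
            class = "podomap_learner")
}

#' Predict suitability probabilities
#'
#' @param object a `podomap_learner`.
#' @param newdata data.frame or matrix with the learner's covariate columns.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.podomap_learner <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$covariates, drop = FALSE])
  if (object$algorithm == "BRT") {
    as.numeric(stats::predict(object$model,
                              xgboost::xgb.DMatrix(x, nthread = 1)))
  } else {
    as.numeric(stats::predict(object$model, data = as.data.frame(x),
                              num.threads = 1)$predictions[, "1"])
  }
}

#' AUC by the rank (Mann-Whitney) formulation
#'
#' Tie-corrected: midranks give each tied presence/absence pair half credit,
#' identical to the all-pairs count `(#concordant + 0.5 #ties) / (n1 n0)`.
#'
#' @param scores numeric scores.
#' @param labels 0/1 (or logical) labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  y <- as.integer(labels > 0)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("auc_mw: both classes required", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(scores, labels) {
  y <- as.integer(labels > 0)
  s <- sort(unique(scores))
  cand <- c(min(s) - 1, (s[-1] + s[-length(s)]) / 2, max(s) + 1)
  t(vapply(cand, function(th) {
    pred <- scores >= th
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    pcc <- mean(pred == (y == 1))
    c(threshold = th, sensitivity = sens, specificity = spec, pcc = pcc)
  }, numeric(4)))
}

#' Evaluate a learner on held-out data
#'
#' AUC by the rank formulation; TSS (sensitivity + specificity - 1) and PCC
#' at the ROC threshold maximizing sensitivity + specificity on the test
#' data.
#'
#' @param learner a `podomap_learner`, or a numeric score vector.
#' @param test a feature/training data.frame with `label`, or (when
#'   `learner` is a score vector) the 0/1 labels.
#' @return list: `auc`, `tss`, `pcc`, `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
evaluate <- function(learner, test) {
  if (is.numeric(learner)) {
    scores <- learner
    y <- as.integer(test > 0)
  } else {
    scores <- stats::predict(learner, test)
    y <- if (is.numeric(test$label)) as.integer(test$label > 0)
         else as.integer(test$label == "presence")
  }
  if (length(unique(y)) < 2) {
    stop("evaluate: test data contains a single class", call. = FALSE)
  }
  auc <- auc_mw(scores, y)
  rp <- roc_points(scores, y)
  best <- which.max(rp[, "sensitivity"] + rp[, "specificity"])
  list(auc = auc,
       tss = unname(rp[best, "sensitivity"] + rp[best, "specificity"] - 1),
       pcc = unname(rp[best, "pcc"]),
       threshold = unname(rp[best, "threshold"]),
       sensitivity = unname(rp[best, "sensitivity"]),
       specificity = unname(rp[best, "specificity"]))
}

#' Choose the binary suitability cut-off
#'
#' Scans every distinct-score midpoint and returns the threshold maximizing
#' the unweighted mean of sensitivity, specificity and PCC (ties broken by
#' the lower threshold), together with the statistics achieved there.
#'
#' @param scores ensemble mean suitability at labelled locations.
#' @param labels 0/1 labels.
#' @return list: `threshold`, `sensitivity`, `specificity`, `pcc`,
#'   `criterion`.
#' @export
choose_threshold <- function(scores, labels) {
  y <- as.integer(labels > 0)
  if (length(unique(y)) < 2) {
    stop("choose_threshold: both classes required", call. = FALSE)
  }
  rp <- roc_points(scores, y)
  crit <- (rp[, "sensitivity"] + rp[, "specificity"] + rp[, "pcc"]) / 3
  best <- which.max(crit)        # which.max takes the first (lowest) maximum
  list(threshold = unname(rp[best, "threshold"]),
       sensitivity = unname(rp[best, "sensitivity"]),
       specificity = unname(rp[best, "specificity"]),
       pcc = unname(rp[best, "pcc"]),
       criterion = unname(crit[best]))
}

#' Repeated-split BRT/RF ensemble over a covariate stack
#'
#' For each repetition: draw a random `train_frac` split, fit each
#' algorithm, evaluate on the held-out fraction (AUC, TSS, PCC), and predict
#' the full grid. Runs with held-out AUC below `auc_min` or TSS below
#' `tss_min` are disregarded; the ensemble surface is the per-cell mean of
#' the surviving runs with empirical 2.5/97.5 percentile bounds. The binary
#' limits map thresholds the mean surface at the cut-off chosen by
#' [choose_threshold()] on the training locations.
#'
#' @param train a `weighted_training_set`.
#' @param stack covariate `raster_stack`.
#' @param n_reps repetitions (the full design uses 100).
#' @param train_frac training fraction per split.
#' @param auc_min,tss_min selection thresholds for assembling the ensemble.
#' @param seed master seed; per-rep seeds are derived deterministically.
#' @param algorithms subset of `c("brt", "rf")`.
#' @param lr,max_interactions,max_trees BRT settings (see [fit_brt()]).
#' @return an `ensemble_result`: `mean_suitability`, `ci_low`, `ci_high`
#'   (`raster_grid`s), `runs` (one row per model run), `threshold` stats,
#'   `limits` binary grid, `member_predictions` (cells x selected runs).
#' @export
run_ensemble <- function(train, stack, n_reps = 100, train_frac = 0.8,
                         auc_min = 0.8, tss_min = 0.7, seed = 1,
                         algorithms = c("brt", "rf"),
                         lr = 0.005, max_interactions = 4, max_trees = 5000) {
  stopifnot(n_reps >= 2, train_frac > 0, train_frac < 1)
  d <- training_xy(train)
  sm <- stack_matrix(stack)
  grid_df <- as.data.frame(sm$x)
  runs <- list(); preds <- list(); train_scores <- list()
  for (i in seq_len(n_reps)) {
    rep_seed <- derive_seed(seed, paste0("rep", i))
    set.seed(rep_seed)
    n <- nrow(train)
    idx <- sample.int(n, floor(train_frac * n))
    tries <- 0
    while ((length(unique(d$y[idx])) < 2 || length(unique(d$y[-idx])) < 2) &&
           tries < 50) {
      idx <- sample.int(n, floor(train_frac * n)); tries <- tries + 1
    }
    tr <- train[idx, , drop = FALSE]; te <- train[-idx, , drop = FALSE]
    for (alg in algorithms) {
      learner <- if (alg == "brt") {
        fit_brt(tr, lr = lr, max_interactions = max_interactions,
                seed = rep_seed, max_trees = max_trees)
      } else {
        fit_rf(tr, seed = rep_seed)
      }
      ev <- evaluate(learner, te)
      selected <- ev$auc >= auc_min && ev$tss >= tss_min
      runs[[length(runs) + 1]] <- data.frame(
        algorithm = learner$algorithm, rep = i, seed = rep_seed,
        auc = ev$auc, tss = ev$tss, pcc = ev$pcc, selected = selected)
      if (selected) {
        preds[[length(preds) + 1]] <- stats::predict(learner, grid_df)
        train_scores[[length(train_scores) + 1]] <-
          stats::predict(learner, as.data.frame(d$x))
      }
    }
  }
  runs <- do.call(rbind, runs)
  if (length(preds) == 0) {
    stop(sprintf(
      "run_ensemble: no run passed selection (auc_min = %g, tss_min = %g); nothing to assemble",
      auc_min, tss_min), call. = FALSE)
  }
  P <- do.call(cbind, preds)
  shape <- stack$shape
  to_grid <- function(v) {
    m <- matrix(NA_real_, shape[1], shape[2])
    m[sm$cells] <- v
    raster_grid(m, xmin = stack$geometry$xmin, ymax = stack$geometry$ymax,
                cellsize = stack$geometry$cellsize, crs = stack$geometry$crs)
  }
  mean_s <- to_grid(rowMeans(P))
  ci_l <- to_grid(apply(P, 1, stats::quantile, probs = 0.025))
  ci_h <- to_grid(apply(P, 1, stats::quantile, probs = 0.975))
  score_train <- rowMeans(do.call(cbind, train_scores))
  thr <- choose_threshold(score_train, d$y)
  limits <- mean_s
  limits$values <- (mean_s$values >= thr$threshold) * 1
  structure(list(mean_suitability = mean_s, ci_low = ci_l, ci_high = ci_h,
                 runs = runs, threshold = thr, limits = limits,
                 member_predictions = P, cells = sm$cells),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble_result: %d/%d runs selected; threshold %.3f (sens %.3f, spec %.3f, PCC %.3f)\n",
              sum(x$runs$selected), nrow(x$runs), x$threshold$threshold,
              x$threshold$sensitivity, x$threshold$specificity, x$threshold$pcc))
  invisible(x)
}

#' Partial dependence of suitability on one covariate
#'
#' The marginal effect of a covariate: for each value on the grid, the
#' covariate is clamped to that value in every training row and the
#' predictions averaged, integrating out the remaining covariates over their
#' empirical distribution.
#'
#' @param learner a `podomap_learner`.
#' @param data training data.frame with the learner's covariates.
#' @param covariate covariate name.
#' @param values evaluation grid; default 25 points over the observed range.
#' @return data.frame with `value` and `dependence` (in `[0, 1]`).
#' @export
partial_dependence <- function(learner, data, covariate, values = NULL) {
  if (!covariate %in% learner$covariates) {
    stop("partial_dependence: unknown covariate '", covariate, "'", call. = FALSE)
  }
  df <- as.data.frame(data)[, learner$covariates, drop = FALSE]
  if (is.null(values)) {
    r <- range(df[[covariate]])
    values <- seq(r[1], r[2], length.out = 25)
  }
  dep <- vapply(values, function(v) {
    df[[covariate]] <- v
    mean(stats::predict(learner, df))
  }, numeric(1))
  data.frame(value = values, dependence = dep)
}

#' Relative contribution of each covariate
#'
#' Learner-native importance (gain for boosted trees, impurity decrease for
#' the forest), truncated at zero and normalized to sum 100.
#'
#' @param learner a `podomap_learner`.
#' @return data.frame with `covariate` and `contribution_pct`.
#' @export
variable_contribution <- function(learner) {
  imp <- stats::setNames(rep(0, length(learner$covariates)), learner$covariates)
  if (learner$algorithm == "BRT") {
    tab <- xgboost::xgb.importance(model = learner$model)
    imp[tab$Feature] <- tab$Gain
  } else {
    raw <- ranger::importance(learner$model)
    imp[names(raw)] <- pmax(raw, 0)
  }
  if (sum(imp) == 0) imp[] <- 1 / length(imp)
  data.frame(covariate = names(imp),
             contribution_pct = 100 * as.numeric(imp) / sum(imp),
             row.names = NULL)
}
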