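test_that("Youden threshold matches an exhaustive confusion-matrix scan", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    probs <- round(runif(n), 2)  # force ties among candidates
    labels <- sample(c("low", "high"), n, replace = TRUE,
                     prob = c(1 / 3, 2 / 3))
    if (length(unique(labels)) < 2) next
    got <- youden_threshold(probs, labels)
    # oracle: evaluate J at every distinct probability via table()
    cand <- sort(unique(probs))
    js <- vapply(cand, function(t) {
      pred <- factor(probs >= t, c(FALSE, TRUE))
      truth <- factor(labels == "low", c(FALSE, TRUE))
      tab <- table(pred, truth)
      tab["TRUE", "TRUE"] / sum(tab[, "TRUE"]) +
        tab["FALSE", "FALSE"] / sum(tab[, "FALSE"]) - 1
    }, 0)
    expect_equal(got$J, max(js))
    # the midpoint threshold classifies identically to the optimal observed cut
    expect_equal(probs >= got$threshold, probs >= cand[which.max(js)])
    expect_equal(got$J, got$sensitivity + got$specificity - 1)
  }
})

test_that("rank-sum AUC agrees with pROC's trapezoidal AUC", {
  set.seed(6)
  for (rep in 1:10) {
    n <- 30
    labels <- sample(c("low", "high"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    probs <- runif(n) + 0.5 * (labels == "low")
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = labels, predictor = probs, levels = c("high", "low"),
      direction = "<")))
    expect_equal(auc_rank(probs, labels), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("hyperparameter grids cover the documented axes", {
  g <- rf_grid(20)
  expect_setequal(unique(g$mtry), c(4L, 6L, 20L))
  expect_setequal(unique(g$num_trees), c(250L, 500L, 1000L))
  expect_setequal(unique(g$splitrule), c("gini", "hellinger"))
  expect_true(nrow(rf_grid_small(20)) < nrow(g))
})

test_that("a separable feature yields perfect CV and test performance", {
  set.seed(8)
  n_trip <- 10
  lab <- rep(c("low", "high", "high"), n_trip)
  trip <- rep(seq_len(n_trip), each = 3)
  x <- data.frame(f1 = ifelse(lab == "low", 1, 0) + rnorm(30, 0, 0.01),
                  f2 = rnorm(30))
  tuned <- tune_and_fit_rf(x, lab, trip, grid = rf_grid_small(2), seed = 2)
  expect_equal(tuned$cv_J, 1)
  expect_equal(tuned$cv_auc, 1)
  pr <- predict(tuned$model, data = x, num.threads = 1)$predictions[, "low"]
  expect_true(all((pr >= tuned$threshold) == (lab == "low")))
})

test_that("held-out performance is null under label permutation", {
  set.seed(13)
  n_trip <- 14
  trip <- rep(seq_len(n_trip), each = 3)
  lab <- rep(c("low", "high", "high"), n_trip)
  js <- c(); aucs <- c()
  for (rep in 1:20) {
    x <- data.frame(f1 = rnorm(3 * n_trip), f2 = rnorm(3 * n_trip))
    test_idx <- trip > n_trip - 4
    tuned <- tune_and_fit_rf(x[!test_idx, ], lab[!test_idx], trip[!test_idx],
                             m = 1, grid = rf_grid_small(2)[1, ], seed = rep)
    pr <- predict(tuned$model, data = x[test_idx, ],
                  num.threads = 1)$predictions[, "low"]
    yte <- lab[test_idx]
    sn <- mean(pr[yte == "low"] >= tuned$threshold)
    sp <- mean(pr[yte == "high"] < tuned$threshold)
    js <- c(js, sn + sp - 1)
    aucs <- c(aucs, auc_rank(pr, yte))
  }
  expect_lt(abs(mean(js)), 0.15)
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("feature selection honors the DMR span and direction filters", {
  sim <- spiked_sim()
  ds <- sim$filtered
  ts <- suppressWarnings(build_triplets(ds$samples))
  parts <- split_triplets(ts, seed = 1)
  cpgs <- select_features(ds, triplet_samples(parts$train),
                          triplet_samples(parts$confirm))
  gt <- surviving_spikes(sim)
  # the strongest spiked region spans >= 5 probes and should dominate
  expect_gt(length(intersect(cpgs, gt$probe_id)), 4)
  # a 5-probe minimum excludes the 4-probe regions by construction
  fit <- suppressWarnings(fit_dmp_model(
    subset_dataset(ds, samples = triplet_samples(parts$train)),
    covariates = character()))
  bumps <- find_bumps(fit, ds$manifest)
  small <- unlist(bumps$probes[bumps$n_probes < 5])
  expect_length(intersect(cpgs, small), 0)
})
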