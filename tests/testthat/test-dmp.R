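random_cohort_sheet <- function(n, seed) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%03d", 1:n),
             cdrisc_score = sample(c(32:65, 77:100), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("percentile subsets agree with brute-force sorted selection", {
  for (seed in 1:5) {
    sheet <- random_cohort_sheet(80, seed)
    sheet$resilience_group <- resilience_group(sheet$cdrisc_score)
    subs <- make_subsets(sheet, steps = c(1, 0.5, 0.25))
    lo <- sheet[sheet$resilience_group == "low", ]
    hi <- sheet[sheet$resilience_group == "high", ]
    # full-set subset is the identity
    expect_setequal(subs[[1]]$low_ids, lo$sample_id)
    expect_setequal(subs[[1]]$high_ids, hi$sample_id)
    for (s in subs) {
      # oracle: stable sort, take the most extreme ceil(q * n) per group
      lo_ord <- lo[order(lo$cdrisc_score, lo$sample_id), ]
      hi_ord <- hi[order(-hi$cdrisc_score, hi$sample_id), ]
      expect_identical(s$low_ids, lo_ord$sample_id[seq_len(ceiling(s$q * nrow(lo)))])
      expect_identical(s$high_ids, hi_ord$sample_id[seq_len(ceiling(s$q * nrow(hi)))])
    }
    # nesting: members at a smaller q are a subset of any larger q
    for (i in seq_len(length(subs) - 1)) {
      expect_true(all(subs[[i + 1]]$low_ids %in% subs[[i]]$low_ids))
      expect_true(all(subs[[i + 1]]$high_ids %in% subs[[i]]$high_ids))
    }
  }
})

test_that("subsets leaving too few samples are dropped with a warning", {
  sheet <- random_cohort_sheet(20, 3)
  sheet$resilience_group <- resilience_group(sheet$cdrisc_score)
  expect_warning(subs <- make_subsets(sheet, steps = c(1, 0.05)), "dropped")
  expect_length(subs, 1)
})

test_that("the group coefficient equals the closed-form mean difference", {
  # 3 samples per group, no covariates: beta-hat = mean(M_low) - mean(M_high)
  set.seed(11)
  M <- matrix(rnorm(6 * 20), 20, 6)
  ds <- make_toy_dataset(20, 6, m_values = M, scores = c(40, 40, 40, 90, 90, 90))
  fit <- fit_dmp_model(ds, covariates = character())
  grp_low <- ds$samples$resilience_group == "low"
  M2 <- get_m_values(ds)
  expect_equal(fit$log2FC,
               unname(rowMeans(M2[, grp_low]) - rowMeans(M2[, !grp_low])),
               tolerance = 1e-12)
})

test_that("moderated variances interpolate between observed and prior", {
  sim <- spiked_sim()
  fit <- suppressWarnings(fit_dmp_model(sim$filtered))
  s0 <- attr(fit, "s0_sq")
  expect_true(all(fit$s2_tilde >= pmin(fit$s2, s0) - 1e-12))
  expect_true(all(fit$s2_tilde <= pmax(fit$s2, s0) + 1e-12))
  expect_gt(attr(fit, "d0"), 0)
})

test_that("infinite prior df collapses to the common-variance statistic", {
  set.seed(2)
  ds <- make_toy_dataset(50, 20)
  s0 <- 0.3
  fit <- fit_dmp_model(ds, covariates = character(), prior_df = Inf,
                       prior_var = s0)
  expect_equal(fit$s2_tilde, rep(s0, 50))
  # recompute the limiting t from the unmoderated pieces
  grp <- as.numeric(ds$samples$resilience_group == "low")
  X <- cbind(1, grp)
  se <- sqrt(solve(crossprod(X))[2, 2])
  expect_equal(fit$t, fit$log2FC / (sqrt(s0) * se), tolerance = 1e-12)
})

test_that("the moderated fit matches limma's empirical Bayes exactly", {
  set.seed(1)
  n <- 40; G <- 400
  grp <- rep(c("low", "high"), each = n / 2)
  M <- matrix(rnorm(n * G, 0, sqrt(rgamma(G, 4, 4))), G, n)
  M[1:20, grp == "low"] <- M[1:20, grp == "low"] + 0.8
  ds <- make_toy_dataset(G, n, m_values = M / 2,
                         scores = ifelse(grp == "low", 40, 90))
  fit <- fit_dmp_model(ds, covariates = "age")
  X <- stats::model.matrix(~ I(grp == "low") + ds$samples$age)
  lf <- limma::eBayes(limma::lmFit(get_m_values(ds), X))
  expect_equal(attr(fit, "d0"), lf$df.prior, tolerance = 1e-9)
  expect_equal(attr(fit, "s0_sq"), lf$s2.prior, tolerance = 1e-9)
  expect_equal(fit$t, unname(lf$t[, 2]), tolerance = 1e-9)
  expect_equal(fit$p, unname(lf$p.value[, 2]), tolerance = 1e-9)
})

test_that("covariates constant within a subset are dropped, not fatal", {
  ds <- make_toy_dataset(10, 12)
  ds$samples$er <- "pos"  # constant
  expect_warning(fit <- fit_dmp_model(ds, covariates = c("age", "er")),
                 "dropped")
  expect_equal(nrow(fit), 10)
})

test_that("DMP calling applies both the p and fold-change gates", {
  fits <- data.frame(probe_id = c("a", "b", "c", "d"),
                     log2FC = c(0.6, 0.3, 2.0, -0.8),
                     t = 0, p = c(0.04, 0.04, 0.06, 0.01),
                     q = 1, s2 = 1, s2_tilde = 1,
                     stringsAsFactors = FALSE)
  called <- call_dmps(fits)
  expect_equal(called$dmp, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(called$direction[called$dmp], c("hyper", "hypo"))
})

test_that("null fits give uniform p values and nominal type-I error", {
  sim <- null_sim()
  fit <- suppressWarnings(fit_dmp_model(sim$filtered))
  expect_gt(suppressWarnings(stats::ks.test(fit$p, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(fit$p < 0.05) - 0.05), 0.01)
})

test_that("consistency scan counts hits, runs, and dose-response", {
  labels <- paste0(c(100, 90, 80, 70, 60, 50, 40, 30, 20, 10, 5), "%")
  gaps <- seq(28, 61, length.out = 11)
  mk <- function(hits, lfc) {
    lapply(seq_along(labels), function(i) list(
      label = labels[i], q = 1, score_gap = gaps[i],
      fit = data.frame(probe_id = "p1", log2FC = lfc[i], p = 0.5,
                       dmp = hits[i], stringsAsFactors = FALSE)))
  }
  # hits in 60/50/40%: run of 3
  res <- consistency_scan(mk(seq_along(labels) %in% 5:7, rep(1, 11)))
  expect_equal(res$n_hits, 3L)
  expect_equal(res$max_run, 3L)
  # hits in 90/40/10%: runs of 1
  res <- consistency_scan(mk(seq_along(labels) %in% c(2, 7, 10), rep(1, 11)))
  expect_equal(res$n_hits, 3L)
  expect_equal(res$max_run, 1L)
  # log2FC strictly increasing with the score gap: dose stat = 1
  res <- consistency_scan(mk(rep(TRUE, 11), seq(0.1, 1.1, by = 0.1)))
  expect_equal(res$dose_response_stat, 1)
})

test_that("spiked probes show a strong oriented dose-response statistic", {
  sim <- spiked_sim()
  subs <- make_subsets(sim$filtered$samples)
  res <- suppressWarnings(run_dmp_analysis(sim$filtered, subs))
  cons <- consistency_scan(res)
  gt <- surviving_spikes(sim)
  drs <- cons$dose_response_stat[match(gt$probe_id, cons$probe_id)]
  oriented <- drs * ifelse(gt$direction == "hyper", 1, -1)
  expect_gt(median(oriented, na.rm = TRUE), 0.8)
})

test_that("feature enrichment flags extreme sets and spares random ones", {
  man <- spiked_sim()$filtered$manifest
  # DMPs restricted to promoter probes: promoter over-represented
  promo <- man$probe_id[man$feature_class == "promoter"][1:50]
  enr <- feature_enrichment(promo, man)
  row <- enr[enr$feature_class == "promoter", ]
  expect_equal(row$status, "enriched")
  expect_lt(row$p, 1e-10)
  # a uniformly random DMP set shows no class beyond the nominal rate
  set.seed(9)
  sig <- replicate(20, {
    rnd <- sample(man$probe_id, 50)
    sum(feature_enrichment(rnd, man)$p < 0.05, na.rm = TRUE)
  })
  expect_lt(mean(sig), 1.5)  # ~0.5 expected from 10 classes at alpha .05
  expect_error(feature_enrichment(character(), man), "empty")
})
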