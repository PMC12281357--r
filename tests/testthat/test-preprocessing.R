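test_that("beta/M transforms match the logit2 definition and invert exactly", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  # antisymmetry m(beta) = -m(1 - beta)
  b <- runif(200, 0.01, 0.99)
  expect_equal(beta_to_m(b), -beta_to_m(1 - b))
  # round-trip identity on the clipped interior
  x <- runif(500, 1e-3, 1 - 1e-3)
  expect_equal(m_to_beta(beta_to_m(x)), x, tolerance = 1e-12)
  # boundaries are absorbed by clipping, never infinite
  expect_true(all(is.finite(beta_to_m(c(0, 1)))))
})

test_that("each QC rule removes exactly the probes its predicate names", {
  set.seed(41)
  n <- 50
  dp <- matrix(0.001, 10, n)
  dp[1, 1:3] <- 0.02        # 6% of samples fail detection -> removed
  dp[2, 1:2] <- 0.02        # 4% -> kept by the detection rule
  bc <- matrix(10L, 10, n)
  bc[3, 1:3] <- 2L          # 6% of samples below 3 beads -> removed
  ds <- make_toy_dataset(10, n, detection_p = dp, bead_counts = bc,
                         snp = c(rep(FALSE, 3), TRUE, rep(FALSE, 6)),
                         multihit = c(rep(FALSE, 4), TRUE, rep(FALSE, 5)),
                         sexchrom = c(rep(FALSE, 5), TRUE, rep(FALSE, 4)))
  # probe 7 is non-CpG
  rownames(ds$beta)[7] <- ds$manifest$probe_id[7] <- "ch.00007"
  res <- filter_probes(ds)
  expect_equal(res$report$probes_removed,
               c(1L, 1L, 1L, 1L, 1L, 1L))
  expect_setequal(rownames(res$dataset$beta),
                  sprintf("cg%05d", c(2, 8, 9, 10)))
})

test_that("the filter cascade is order-stable (independent predicates)", {
  sim <- spiked_sim()
  res <- suppressWarnings(filter_probes(sim$dataset))
  # survivors = probes failing no predicate, regardless of application order
  ds <- sim$dataset
  fail <- rowMeans(ds$detection_p > 0.01) > 0.05 |
    rowMeans(ds$bead_counts < 3) >= 0.05 |
    !startsWith(ds$manifest$probe_id, "cg") |
    ds$manifest$snp_flag | ds$manifest$multihit_flag |
    ds$manifest$sex_chrom_flag
  expect_setequal(rownames(res$dataset$beta), ds$manifest$probe_id[!fail])
  expect_equal(sum(res$report$probes_removed), sum(fail))
})

test_that("default QC failure rates retain about 84% of probes", {
  sim <- spiked_sim()
  res <- suppressWarnings(filter_probes(sim$dataset))
  retained <- nrow(res$dataset$beta) / nrow(sim$dataset$beta)
  expect_lt(abs(retained - 0.84), 0.02)
})

test_that("batch standardization removes shifts and preserves probe moments", {
  set.seed(7)
  n <- 40
  M <- matrix(rnorm(30 * n, 0, 0.6), 30, n)
  batch <- rep(c("a", "b"), each = n / 2)
  M[, batch == "b"] <- M[, batch == "b"] + 1   # pure location shift
  ds <- make_toy_dataset(30, n, m_values = M,
                         extra_samples = data.frame(batch = batch))
  adj <- adjust_batch(ds)
  Madj <- get_m_values(adj)
  # batch means coincide after adjustment
  expect_lt(max(abs(rowMeans(Madj[, batch == "a"]) -
                    rowMeans(Madj[, batch == "b"]))), 1e-10)
  # per-probe grand mean and SD are preserved
  M0 <- get_m_values(ds)
  expect_equal(rowMeans(Madj), rowMeans(M0), tolerance = 1e-10)
  expect_equal(apply(Madj, 1, sd), apply(M0, 1, sd), tolerance = 1e-10)
})

test_that("single batches pass through; singleton batches are refused", {
  ds <- make_toy_dataset(10, 10,
                         extra_samples = data.frame(batch = rep("a", 10)))
  expect_identical(adjust_batch(ds)$beta, ds$beta)
  ds2 <- make_toy_dataset(10, 10,
                          extra_samples = data.frame(batch = c(rep("a", 9), "b")))
  expect_error(adjust_batch(ds2), "singleton batch")
})

test_that("batch structure disappears from the top PCs after adjustment", {
  sim <- fixture("batch_sim", function() simulate_dataset(
    simulation_config(n_probes = 800, n_samples = 60,
                      batch_effects = list(location = c(0, 0.8),
                                           scale = c(1, 1.4)),
                      seed = 13)))
  ds <- sim$dataset
  p_batch <- function(d) {
    scan <- pca_covariate_scan(d, covariates = "batch", n_components = 3)
    min(scan$associations$p, na.rm = TRUE)
  }
  expect_lt(p_batch(ds), 0.001)
  expect_gt(p_batch(adjust_batch(ds)), 0.05)
})

test_that("constrained projection recovers cell fractions", {
  sim <- spiked_sim()
  ds <- sim$dataset
  gt <- sim$ground_truth$cells
  dec <- deconvolve_cells(ds, gt$reference)
  expect_true(all(dec$fractions >= 0))
  expect_equal(unname(rowSums(dec$fractions)), rep(1, nrow(dec$fractions)),
               tolerance = 1e-6)
  # mixtures were generated noiselessly from the reference: exact round trip
  expect_lt(max(abs(dec$fractions - gt$fractions)), 1e-6)
  expect_lt(max(dec$residual_norm), 1e-6)
})

test_that("one-hot mixtures are recovered as pure samples", {
  ref <- default_cell_reference(n_ref = 40, n_types = 5)
  frac <- diag(5)
  beta <- mix_cell_types(frac, ref)
  ids <- sprintf("cg%05d", 1:40)
  dimnames(beta) <- list(ids, paste0("P", 1:5))
  ds <- methylation_dataset(
    beta,
    data.frame(probe_id = ids, chrom = "chr1", pos = 1:40 * 100, gene = "",
               feature_class = "exon", snp_flag = FALSE, multihit_flag = FALSE,
               sex_chrom_flag = FALSE),
    data.frame(sample_id = paste0("P", 1:5), cdrisc_score = 50))
  rownames(ref) <- ids
  dec <- deconvolve_cells(ds, ref)
  expect_true(all(diag(dec$fractions) >= 0.999))
})

test_that("cell composition does not differ between groups on null data", {
  sim <- null_sim()
  dec <- deconvolve_cells(sim$dataset, sim$ground_truth$cells$reference)
  cmp <- compare_cell_fractions(dec, sim$dataset$samples$resilience_group)
  # fractions were drawn identically for both groups
  expect_gt(min(cmp$p), 0.05 / nrow(cmp))
})

test_that("PCA scan finds planted covariate structure and skips constants", {
  sim <- fixture("age_sim", function() simulate_dataset(
    simulation_config(n_probes = 800, n_samples = 60,
                      covariate_effects = c(age = 0.5), seed = 17)))
  ds <- sim$dataset
  scan <- pca_covariate_scan(ds, covariates = c("age", "er"), n_components = 3)
  expect_lt(min(scan$associations$p[scan$associations$covariate == "age"]), 1e-4)
  # variance explained is a non-increasing fraction of the total
  expect_true(all(diff(scan$variance_explained) <= 1e-12))
  expect_lte(sum(scan$variance_explained), 1)
  # permuted copies of age carry no association (median over permutations of
  # the strongest PC association stays clearly non-significant)
  set.seed(4)
  min_p <- vapply(1:10, function(i) {
    ds$samples$age_perm <- sample(ds$samples$age)
    scan2 <- pca_covariate_scan(ds, covariates = "age_perm", n_components = 3)
    min(scan2$associations$p)
  }, 0)
  expect_gt(median(min_p), 0.05)
  # self-association: a covariate equal to PC1 scores is found on PC1
  ds$samples$pc1 <- scan$scores[, 1]
  scan3 <- pca_covariate_scan(ds, covariates = c("pc1", "er"), n_components = 2)
  expect_lt(scan3$associations$p[scan3$associations$pc == "PC1" &
                                 scan3$associations$covariate == "pc1"], 1e-20)
  # constant covariate flagged and skipped
  ds$samples$const <- 1
  scan4 <- pca_covariate_scan(ds, covariates = "const", n_components = 2)
  expect_true(all(scan4$associations$skipped))
})
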