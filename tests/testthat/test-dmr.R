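toy_manifest <- function(pos, chrom = "chr1", gene = "") {
  data.frame(probe_id = sprintf("cg%05d", seq_along(pos)), chrom = chrom,
             pos = pos, gene = gene, feature_class = "exon",
             snp_flag = FALSE, multihit_flag = FALSE, sex_chrom_flag = FALSE,
             stringsAsFactors = FALSE)
}

test_that("probe clustering matches the direct gap rule", {
  man <- toy_manifest(cumsum(c(1000, 100, 100, 10000, 100)))
  cl <- cluster_probes(man, max_gap_bp = 500)
  expect_equal(as.vector(table(cl$cluster)), c(3L, 2L))
  # max_gap = 0: every probe its own cluster
  cl0 <- cluster_probes(man, max_gap_bp = 0)
  expect_equal(cl0$cluster, 1:5)
  # unsorted input is sorted with a warning
  expect_warning(cluster_probes(man[c(3, 1, 2, 5, 4), ]), "sorting")
})

test_that("clustering agrees with a brute-force transitive-closure oracle", {
  set.seed(71)
  n <- 1000
  man <- toy_manifest(sort(sample.int(3e6, n)),
                      chrom = sort(rep_len(c("chr1", "chr2"), n)))
  man <- man[order(man$chrom, man$pos), ]
  man$probe_id <- sprintf("cg%05d", seq_len(n))
  cl <- cluster_probes(man, max_gap_bp = 500)
  # oracle: probes i<j share a cluster iff every adjacent gap between them
  # (same chromosome) is <= max_gap
  oracle <- integer(n); oracle[1] <- 1L
  for (i in 2:n) {
    same <- man$chrom[i] == man$chrom[i - 1] &&
      man$pos[i] - man$pos[i - 1] <= 500
    oracle[i] <- if (same) oracle[i - 1] else oracle[i - 1] + 1L
  }
  expect_equal(cl$cluster, oracle)
})

test_that("bump areas equal the absolute coefficient sum, smoothing aside", {
  man <- toy_manifest(c(1000, 1100, 1200))
  fits <- data.frame(probe_id = man$probe_id, log2FC = c(0.6, 0.7, 0.55),
                     stringsAsFactors = FALSE)
  b <- find_bumps(fits, man, cutoff = 0.5)
  expect_equal(nrow(b), 1)
  expect_equal(b$area, 1.85)
  expect_equal(b$n_probes, 3L)
  expect_equal(b$direction, "hyper")
  # all-zero coefficients yield no regions
  fits$log2FC <- 0
  expect_equal(nrow(find_bumps(fits, man, cutoff = 0.1)), 0)
})

test_that("every emitted region's area matches a brute-force sum", {
  sim <- spiked_sim()
  fit <- suppressWarnings(fit_dmp_model(sim$filtered))
  b <- find_bumps(fit, sim$filtered$manifest)
  expect_gt(nrow(b), 0)
  for (i in seq_len(nrow(b))) {
    expect_equal(b$area[i],
                 abs(sum(fit$log2FC[match(b$probes[[i]], fit$probe_id)])),
                 tolerance = 1e-12)
    expect_lte(b$start[i], b$end[i])
  }
})

test_that("bump finding is invariant to a global sign flip", {
  sim <- spiked_sim()
  fit <- suppressWarnings(fit_dmp_model(sim$filtered))
  b1 <- find_bumps(fit, sim$filtered$manifest)
  fit2 <- fit; fit2$log2FC <- -fit2$log2FC
  b2 <- find_bumps(fit2, sim$filtered$manifest, cutoff = attr(b1, "cutoff"))
  expect_equal(b1[c("chrom", "start", "end", "n_probes", "area")],
               b2[c("chrom", "start", "end", "n_probes", "area")])
  expect_true(all(b1$direction != b2$direction))
})

test_that("spiked regions surface as the top-area candidates", {
  sim <- spiked_sim()
  fit <- suppressWarnings(fit_dmp_model(sim$filtered))
  b <- find_bumps(fit, sim$filtered$manifest)
  gt <- surviving_spikes(sim)
  top3_probes <- unlist(b$probes[1:3])
  # each of the 3 spiked regions is recovered among the top 3 areas
  for (ri in unique(gt$region)) {
    hit <- gt$probe_id[gt$region == ri]
    recall <- length(intersect(top3_probes, hit)) / length(hit)
    expect_gt(recall, 0.8)
  }
})

test_that("permutation p values respect their support and determinism", {
  sim <- fixture("perm_sim", function() {
    s <- simulate_dataset(simulation_config(
      n_probes = 600, n_samples = 50,
      spiked_regions = list(spiked_region(2, 20, 27, max_effect = 1.5)),
      seed = 55))
    s$filtered <- suppressWarnings(filter_probes(s$dataset)$dataset)
    s
  })
  pn <- permute_null(sim$filtered, n_perm = 20, seed = 9)
  B <- 20
  expect_true(all(pn$regions$perm_p >= 1 / (B + 1)))
  expect_true(all(pn$regions$perm_p <= 1))
  # the planted region beats every permutation
  gt <- surviving_spikes(sim)
  planted <- which(vapply(pn$regions$probes,
                          function(p) length(intersect(p, gt$probe_id)) > 0,
                          TRUE))
  expect_equal(pn$regions$perm_p[planted[1]], 1 / (B + 1))
  # deterministic under the seed
  pn2 <- permute_null(sim$filtered, n_perm = 20, seed = 9)
  expect_identical(pn$null_max_areas, pn2$null_max_areas)
  expect_error(permute_null(sim$filtered, n_perm = 5), "at least 10")
})

test_that("region matching across subsets tracks presence, runs and trend", {
  labels <- paste0(c(100, 90, 80, 70, 60, 50, 40, 30, 20, 10, 5), "%")
  region <- function(area, gene = "GENEA") {
    r <- data.frame(region_id = 1L, chrom = "chr1", start = 100L, end = 900L,
                    n_probes = 5L, area = area, mean_coef = area / 5,
                    direction = "hyper", gene = gene, stringsAsFactors = FALSE)
    r$probes <- list(sprintf("cg%05d", 1:5))
    r
  }
  empty <- region(1)[0, ]
  mk <- function(present, areas) {
    lapply(seq_along(labels), function(i) list(
      label = labels[i], q = 1, score_gap = 30,
      regions = if (present[i]) region(areas[i]) else empty))
  }
  # present in the 6 most distal subsets with increasing area
  cs <- dmr_consistency_scan(mk(seq_along(labels) %in% 6:11, seq(0.5, 5.5, 0.5)))
  expect_equal(cs$max_run, 6L)
  expect_equal(cs$area_trend_stat, 1)
  expect_equal(cs$key, "GENEA")
  # present only in 80% and 30%: run of 1
  cs <- dmr_consistency_scan(mk(seq_along(labels) %in% c(3, 8), rep(1, 11)))
  expect_equal(cs$max_run, 1L)
  expect_equal(cs$n_subsets, 2)
})

test_that("spiked regions persist across subsets with growing area", {
  sim <- spiked_sim()
  subs <- make_subsets(sim$filtered$samples)
  dmr <- suppressWarnings(run_dmr_analysis(sim$filtered, subs))
  cs <- dmr_consistency_scan(dmr)
  gt <- surviving_spikes(sim)
  for (ri in unique(gt$region)) {
    probes <- gt$probe_id[gt$region == ri]
    # locate the key overlapping this spiked region via the full-set regions
    full <- dmr[[1]]$regions
    hit <- which(vapply(full$probes, function(p) length(intersect(p, probes)) > 0, TRUE))[1]
    key <- cs[cs$chrom == full$chrom[hit] & cs$start <= full$end[hit] &
              cs$end >= full$start[hit], ]
    expect_gte(key$n_subsets[1], 8)
    expect_gt(key$area_trend_stat[1], 0)
  }
})
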