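# Shared fixtures, built once per test run and cached (several test files
# reuse the same simulated cohorts).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# hand-built tiny dataset: full control over every matrix entry
make_toy_dataset <- function(n_probes = 10, n_samples = 50, m_values = NULL,
                             scores = NULL, chrom = "chr1",
                             pos = seq(1000, by = 200, length.out = n_probes),
                             snp = rep(FALSE, n_probes),
                             multihit = rep(FALSE, n_probes),
                             sexchrom = rep(FALSE, n_probes),
                             probe_prefix = "cg",
                             detection_p = NULL, bead_counts = NULL,
                             extra_samples = NULL) {
  probe_id <- sprintf("%s%05d", probe_prefix, seq_len(n_probes))
  if (is.null(m_values)) {
    m_values <- matrix(rnorm(n_probes * n_samples, 0, 0.5), n_probes, n_samples)
  }
  beta <- epires::m_to_beta(m_values)
  dimnames(beta) <- list(probe_id, sprintf("S%03d", seq_len(n_samples)))
  manifest <- data.frame(probe_id = probe_id,
                         chrom = rep(chrom, length.out = n_probes), pos = pos,
                         gene = paste0("G", ceiling(seq_len(n_probes) / 5)),
                         feature_class = "exon", snp_flag = snp,
                         multihit_flag = multihit, sex_chrom_flag = sexchrom,
                         stringsAsFactors = FALSE)
  if (is.null(scores)) scores <- rep(c(40, 90), length.out = n_samples)
  samples <- data.frame(sample_id = colnames(beta), cdrisc_score = scores,
                        age = seq(45, 75, length.out = n_samples),
                        stringsAsFactors = FALSE)
  if (!is.null(extra_samples)) samples <- cbind(samples, extra_samples)
  if (!is.null(detection_p)) dimnames(detection_p) <- dimnames(beta)
  if (!is.null(bead_counts)) dimnames(bead_counts) <- dimnames(beta)
  methylation_dataset(beta, manifest, samples,
                      detection_p = detection_p, bead_counts = bead_counts,
                      low_max = 65, high_min = 77)
}

# three spiked dose-responsive DMRs, the standard recovery scenario
spiked_config <- function(seed, n_probes = 2000, n_samples = 160) {
  simulation_config(
    n_probes = n_probes, n_samples = n_samples,
    spiked_regions = list(
      spiked_region(2, 30, 37, max_effect = 1.2, direction = "hyper"),
      spiked_region(3, 60, 66, max_effect = 1.5, direction = "hypo"),
      spiked_region(4, 100, 105, max_effect = 1.0, direction = "hyper")),
    seed = seed)
}

spiked_sim <- function() fixture("spiked_sim", function() {
  sim <- simulate_dataset(spiked_config(seed = 21))
  sim$filtered <- suppressWarnings(filter_probes(sim$dataset)$dataset)
  sim
})

null_sim <- function() fixture("null_sim", function() {
  sim <- simulate_dataset(simulation_config(n_probes = 1500, n_samples = 120,
                                            seed = 33))
  sim$filtered <- suppressWarnings(filter_probes(sim$dataset)$dataset)
  sim
})

# probes actually spiked AND surviving QC, with their planted direction
surviving_spikes <- function(sim, ds = sim$filtered) {
  gt <- sim$ground_truth$spiked
  keep <- gt$probe_id %in% rownames(ds$beta)
  gt[keep, , drop = FALSE]
}
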