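#' Describe a spiked dose-responsive region
#'
#' A contiguous run of probes carrying a known methylation difference between
#' low- and high-resilience samples, whose magnitude grows with a sample's
#' CD-RISC distance from the score midpoint (a dose-response spike).
#'
#' @param chrom chromosome index (1-based, among the simulated autosomes).
#' @param start_probe,end_probe probe-run bounds on that chromosome
#'   (1-based, inclusive).
#' @param max_effect M-scale shift magnitude reached at the extreme tail
#'   of the score scale (must be >= 0).
#' @param dose_exponent shape of effect growth with score distance from the
#'   midpoint (1 = linear).
#' @param direction `"hyper"` or `"hypo"`: methylation direction in the
#'   LOW-resilience group.
#' @return A `spiked_region` list.
#' @export
spiked_region <- function(chrom, start_probe, end_probe, max_effect,
                          dose_exponent = 1, direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  stopifnot(end_probe >= start_probe, max_effect >= 0, dose_exponent > 0)
  structure(list(chrom = as.integer(chrom),
                 start_probe = as.integer(start_probe),
                 end_probe = as.integer(end_probe),
                 max_effect = max_effect,
                 dose_exponent = dose_exponent,
                 direction = direction),
            class = "spiked_region")
}

#' Dose-response shift at a spiked probe
#'
#' The M-scale shift a sample with CD-RISC score `score` receives at a spiked
#' probe. The magnitude is `max_effect * (|score - midpoint| / half_range) ^
#' dose_exponent`, where `half_range` is the distance from the midpoint to the
#' near end of the 0-100 scale, so the extreme scorer on each side reaches the
#' full `max_effect`. The shift is antisymmetric about the midpoint: for a
#' `"hyper"` (in the low group) spike, samples below the midpoint are shifted
#' up and samples above it down, so the group contrast (low minus high) is
#' positive and grows toward the tails; a sample exactly at the midpoint is
#' unshifted.
#'
#' @param score CD-RISC score(s) in \[0, 100\].
#' @param max_effect,dose_exponent,direction see [spiked_region()].
#' @param midpoint score midpoint anchoring the dose-response (default 71,
#'   the boundary between the high/low selection ranges).
#' @return numeric shift(s) on the M scale.
#' @export
dose_response_shift <- function(score, max_effect, dose_exponent = 1,
                                direction = c("hyper", "hypo"), midpoint = 71) {
  direction <- match.arg(direction)
  sgn_dir <- if (direction == "hyper") 1 else -1
  half <- ifelse(score < midpoint, midpoint, 100 - midpoint)
  d <- pmin(abs(score - midpoint) / half, 1)
  side <- sign(midpoint - score)  # +1 below the midpoint (low side)
  sgn_dir * side * max_effect * d^dose_exponent
}

#' Default synthetic cell-type reference
#'
#' A small synthetic leukocyte-style reference panel: per-cell-type mean beta
#' values at discriminating reference probes, built deterministically so the
#' generator and the deconvolution stage share a common panel. Synthetic: it
#' is not derived from any sorted-cell dataset.
#'
#' @param n_ref number of reference probes.
#' @param n_types number of cell types.
#' @return matrix (n_ref x n_types) of mean beta values in (0.03, 0.97),
#'   column names `cell1..cellK`.
#' @export
default_cell_reference <- function(n_ref = 50, n_types = 6) {
  with_seed(20240901, {
    ref <- matrix(runif(n_ref * n_types, 0.05, 0.95), n_ref, n_types)
    # sharpen contrasts so types are identifiable: push a subset per type
    # toward the boundaries
    for (k in seq_len(n_types)) {
      idx <- seq.int(k, n_ref, by = n_types)
      ref[idx, k] <- ifelse(ref[idx, k] > 0.5, 0.95, 0.05)
    }
    dimnames(ref) <- list(NULL, paste0("cell", seq_len(n_types)))
    ref
  })
}

#' Simulation configuration for EPIC-like synthetic cohorts
#'
#' Defines the study conditions for [simulate_dataset()]: cohort size, probe
#' layout, score distribution of the tail-selected groups, spiked
#' dose-responsive regions, covariate and batch structure, cell mixing, and
#' QC failure rates. Defaults emulate a tail-dichotomized breast-cancer
#' cohort: low group scores ~N(56, 8) truncated to \[32, 65\], high group
#' ~N(84, 5) truncated to \[77, 100\]; covariate frequencies follow typical
#' screening-age cohorts (postmenopausal ~80%, ER+ ~86%, PR+ ~68%,
#' HER2+ ~11%, ever-smokers ~13%); ~16% of probes carry a QC-failure flag so
#' ~84% survive the filter cascade.
#'
#' @param n_probes,n_samples cohort dimensions.
#' @param n_chromosomes number of autosomes probes are spread over (a small
#'   X-chromosome block is added on top at rate `qc_rates$sex`).
#' @param probe_spacing_bp mean gap of the between-cluster (long-range)
#'   spacing component; within-cluster gaps are short (30-400 bp).
#' @param cluster_prob probability that consecutive probes are in the same
#'   dense cluster (short gap).
#' @param spiked_regions list of [spiked_region()] objects (may be empty).
#' @param covariate_effects named numeric: M-scale coefficient per standard
#'   deviation of the covariate, applied to a random `covariate_frac` of
#'   probes. Names among `age`, `menstrual`, `smoking`, `er`, `detection_mode`.
#' @param covariate_frac fraction of probes carrying each covariate effect.
#' @param batch_effects list with `location` and `scale` numeric vectors (one
#'   entry per batch); batches are assigned uniformly at random.
#' @param cell_reference reference-panel matrix (probes x cell types) of mean
#'   beta values; the first `nrow(cell_reference)` generated probes are the
#'   reference probes. `NULL` disables cell mixing.
#' @param cell_alpha Dirichlet concentration for per-sample cell fractions.
#' @param noise_sd M-scale residual SD.
#' @param score_mix group score distribution parameters (means, SDs, ranges,
#'   proportion low).
#' @param midpoint dose-response anchor score (default 71, the boundary
#'   between the group selection ranges).
#' @param qc_rates per-failure-class probe flag rates (detection, beads,
#'   noncpg, snp, multihit, sex); defaults total ~16% flagged.
#' @param seed integer RNG seed; a fixed seed makes the dataset byte-identical
#'   across calls.
#' @return A `simulation_config` list, validated.
#' @export
simulation_config <- function(n_probes = 5000, n_samples = 120,
                              n_chromosomes = 6, probe_spacing_bp = 5000,
                              cluster_prob = 0.7,
                              spiked_regions = list(),
                              covariate_effects = c(),
                              covariate_frac = 0.2,
                              batch_effects = list(location = c(0, 0),
                                                   scale = c(1, 1)),
                              cell_reference = default_cell_reference(),
                              cell_alpha = c(6, 1.5, 1, 0.8, 0.5, 0.3),
                              noise_sd = 0.35,
                              score_mix = list(low_mean = 56, low_sd = 8,
                                               low_range = c(32, 65),
                                               high_mean = 84, high_sd = 5,
                                               high_range = c(77, 100),
                                               prop_low = 0.5),
                              midpoint = 71,
                              qc_rates = list(detection = 0.05, beads = 0.03,
                                              noncpg = 0.02, snp = 0.03,
                                              multihit = 0.02, sex = 0.015),
                              seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), n_samples = as.integer(n_samples),
              n_chromosomes = as.integer(n_chromosomes),
              probe_spacing_bp = probe_spacing_bp, cluster_prob = cluster_prob,
              spiked_regions = spiked_regions,
              covariate_effects = covariate_effects,
              covariate_frac = covariate_frac,
              batch_effects = batch_effects,
              cell_reference = cell_reference, cell_alpha = cell_alpha,
              noise_sd = noise_sd, score_mix = score_mix, midpoint = midpoint,
              qc_rates = qc_rates, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_probes <= 0) stopf("n_probes must be > 0")
  if (cfg$n_samples <= 0) stopf("n_samples must be > 0")
  if (cfg$noise_sd <= 0) stopf("noise_sd must be > 0")
  if (length(cfg$batch_effects$location) != length(cfg$batch_effects$scale)) {
    stopf("batch_effects location/scale lengths differ")
  }
  per_chrom <- cfg$n_probes %/% cfg$n_chromosomes
  for (sp in cfg$spiked_regions) {
    if (!inherits(sp, "spiked_region")) stopf("spiked_regions must be spiked_region objects")
    if (sp$chrom < 1 || sp$chrom > cfg$n_chromosomes) {
      stopf("spiked region chromosome %d outside 1..%d", sp$chrom, cfg$n_chromosomes)
    }
    if (sp$end_probe > per_chrom) {
      stopf("spiked region [%d, %d] exceeds the %d probes on chromosome %d",
            sp$start_probe, sp$end_probe, per_chrom, sp$chrom)
    }
  }
  if (!is.null(cfg$cell_reference)) {
    if (nrow(cfg$cell_reference) > per_chrom) stopf("cell reference larger than chromosome 1")
    if (length(cfg$cell_alpha) != ncol(cfg$cell_reference)) {
      stopf("cell_alpha length must match the number of cell types")
    }
    for (sp in cfg$spiked_regions) {
      if (sp$chrom == 1L && sp$start_probe <= nrow(cfg$cell_reference)) {
        stopf("spiked region overlaps the reference probes at the start of chromosome 1")
      }
    }
  }
  invisible(cfg)
}

# truncated-normal sampler by quantile inversion
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

# Dirichlet rows
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  g / rowSums(g)
}

#' Mix cell-type reference profiles into per-sample beta values
#'
#' Reference-probe beta values are the convex combination of per-cell-type
#' mean profiles weighted by each sample's cell fractions, optionally with
#' added noise, clipped into (0, 1).
#'
#' @param fractions samples x cell-types matrix; each row non-negative and
#'   summing to 1 (within 1e-6).
#' @param reference probes x cell-types matrix of mean beta values.
#' @param noise_sd beta-scale Gaussian noise SD (0 = noiseless).
#' @param eps boundary clip.
#' @return probes x samples beta matrix.
#' @export
mix_cell_types <- function(fractions, reference, noise_sd = 0, eps = 1e-3) {
  fractions <- as.matrix(fractions)
  reference <- as.matrix(reference)
  if (ncol(fractions) != ncol(reference)) {
    stopf("fractions and reference disagree on the number of cell types")
  }
  if (any(fractions < -1e-9) || any(abs(rowSums(fractions) - 1) > 1e-6)) {
    stopf("cell fractions must be non-negative and sum to 1 per sample")
  }
  b <- reference %*% t(fractions)
  if (noise_sd > 0) b <- b + matrix(rnorm(length(b), 0, noise_sd), nrow(b))
  pmin(pmax(b, eps), 1 - eps)
}

#' Simulate an EPIC-like methylation cohort with known ground truth
#'
#' Generates a [methylation_dataset()] (beta matrix, probe manifest with
#' genomic coordinates/feature classes/QC flags, sample sheet with CD-RISC
#' scores and clinical covariates, detection-p and bead-count matrices)
#' together with the ground truth of everything that was planted: spiked
#' probe indices and their dose-response parameters, per-sample cell
#' fractions, per-probe covariate loadings, and batch assignments.
#'
#' Probes are laid out along autosomes with a dense-cluster/between-cluster
#' gap mixture; beta values arise from a bimodal per-probe baseline on the M
#' scale (inverse-logit gives the familiar two-humped beta distribution) plus
#' spiked dose-response shifts ([dose_response_shift()]), covariate-linked
#' structure, batch location/scale effects, and Gaussian M-scale noise.
#' Reference probes (first rows of chromosome 1) instead carry cell-mixture
#' beta values from [mix_cell_types()].
#'
#' @param config a [simulation_config()].
#' @return list with `dataset` (a `methylation_dataset`) and `ground_truth`
#'   (list: `spiked` data.frame of spiked probes with region id, direction,
#'   max_effect, dose_exponent; `spike_probe_ids`; `cell_fractions`;
#'   `reference` with probe-id rownames; `covariate_loadings`; `batch`).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  validate_simulation_config(config)
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  n_auto <- cfg$n_probes
  per_chrom <- n_auto %/% cfg$n_chromosomes
  counts <- rep(per_chrom, cfg$n_chromosomes)
  counts[cfg$n_chromosomes] <- counts[cfg$n_chromosomes] + (n_auto - sum(counts))
  n_sex <- max(0L, round(cfg$qc_rates$sex * n_auto))
  n_total <- n_auto + n_sex

  chrom <- c(rep(paste0("chr", seq_len(cfg$n_chromosomes)), counts),
             rep("chrX", n_sex))

  # positions: dense-cluster / long-range gap mixture, strictly increasing
  gen_positions <- function(n) {
    if (n == 0L) return(integer())
    short <- runif(n) < cfg$cluster_prob
    gaps <- ifelse(short, round(runif(n, 30, 400)),
                   500 + round(rexp(n, 1 / cfg$probe_spacing_bp)))
    cumsum(pmax(gaps, 2)) + 10000L
  }
  pos <- unlist(lapply(c(counts, if (n_sex) n_sex), gen_positions), use.names = FALSE)

  probe_id <- sprintf("cg%07d", seq_len(n_total))
  noncpg <- runif(n_total) < cfg$qc_rates$noncpg
  probe_id[noncpg] <- sub("^cg", "ch.", probe_id[noncpg])

  feature_class <- sample(c("promoter", "5utr", "exon", "intron", "3utr",
                            "intergenic", "island", "shore", "shelf", "opensea"),
                          n_total, replace = TRUE,
                          prob = c(.12, .05, .10, .25, .04, .20, .08, .07, .04, .05))
  # gene labels: blocks of ~25 consecutive probes share a gene; intergenic blank
  gene <- paste0("GENE", ceiling(seq_len(n_total) / 25))
  gene[feature_class == "intergenic"] <- ""

  manifest <- data.frame(
    probe_id = probe_id, chrom = chrom, pos = pos, gene = gene,
    feature_class = feature_class,
    snp_flag = runif(n_total) < cfg$qc_rates$snp,
    multihit_flag = runif(n_total) < cfg$qc_rates$multihit,
    sex_chrom_flag = chrom %in% c("chrX", "chrY"),
    stringsAsFactors = FALSE)

  # ---- samples ----
  n <- cfg$n_samples
  sm <- cfg$score_mix
  n_low <- round(sm$prop_low * n)
  n_high <- n - n_low
  score <- round(c(
    rtruncnorm(n_low, sm$low_mean, sm$low_sd, sm$low_range[1], sm$low_range[2]),
    rtruncnorm(n_high, sm$high_mean, sm$high_sd, sm$high_range[1], sm$high_range[2])))
  sample_id <- sprintf("S%04d", seq_len(n))
  age <- pmin(pmax(round(rnorm(n, 62, 11)), 28), 90)
  menstrual <- ifelse(age + rnorm(n, 0, 2) < 51, "pre", "post")
  detection_mode <- sample(c("screening", "symptomatic"), n, TRUE, c(.6, .4))
  er <- sample(c("pos", "neg"), n, TRUE, c(.86, .14))
  pr <- sample(c("pos", "neg"), n, TRUE, c(.68, .32))
  her2 <- sample(c("pos", "neg"), n, TRUE, c(.11, .89))
  smoking <- sample(c("ever", "never"), n, TRUE, c(.13, .87))
  n_batches <- length(cfg$batch_effects$location)
  batch <- paste0("batch", sample.int(n_batches, n, replace = TRUE))

  samples <- data.frame(sample_id = sample_id, cdrisc_score = score,
                        age = age, menstrual = menstrual,
                        detection_mode = detection_mode, er = er, pr = pr,
                        her2 = her2, smoking = smoking, batch = batch,
                        stringsAsFactors = FALSE)

  # ---- beta matrix on the M scale ----
  comp <- sample.int(3L, n_total, replace = TRUE, prob = c(.45, .40, .15))
  mu <- c(rnorm(n_total, -3.5, 0.8), rnorm(n_total, 3.5, 0.8),
          rnorm(n_total, 0, 1.2))[seq_len(n_total) + (comp - 1L) * n_total]

  # spiked probes: global row indices, intermediate baseline so shifts do not
  # saturate on the beta scale
  chrom_offset <- c(0L, cumsum(counts))[seq_len(cfg$n_chromosomes)]
  spiked <- data.frame()
  for (ri in seq_along(cfg$spiked_regions)) {
    sp <- cfg$spiked_regions[[ri]]
    idx <- chrom_offset[sp$chrom] + sp$start_probe:sp$end_probe
    mu[idx] <- rnorm(length(idx), 0, 0.4)
    spiked <- rbind(spiked, data.frame(
      region = ri, probe_index = idx, probe_id = probe_id[idx],
      chrom = chrom[idx], direction = sp$direction,
      max_effect = sp$max_effect, dose_exponent = sp$dose_exponent,
      stringsAsFactors = FALSE))
  }
  if (nrow(spiked)) {
    # spiked runs must form a genomic cluster: compress their internal gaps
    for (ri in unique(spiked$region)) {
      idx <- spiked$probe_index[spiked$region == ri]
      if (length(idx) > 1) {
        new_gaps <- round(runif(length(idx) - 1, 30, 200))
        pos[idx[-1]] <- pos[idx[1]] + cumsum(new_gaps)
        run_end <- idx[length(idx)]
        same_chr <- which(chrom == chrom[run_end])
        after <- same_chr[same_chr > run_end]
        if (length(after)) {
          shift_needed <- pos[run_end] + 1000 - pos[after[1]]
          if (shift_needed > 0) pos[after] <- pos[after] + shift_needed
        }
      }
    }
    manifest$pos <- pos
  }

  M <- matrix(mu, n_total, n) +
    matrix(rnorm(n_total * n, 0, cfg$noise_sd), n_total, n)

  # spiked dose-response shifts
  if (nrow(spiked)) {
    for (ri in unique(spiked$region)) {
      sp <- cfg$spiked_regions[[ri]]
      idx <- spiked$probe_index[spiked$region == ri]
      shift <- dose_response_shift(score, sp$max_effect, sp$dose_exponent,
                                   sp$direction, cfg$midpoint)
      M[idx, ] <- M[idx, ] + rep(shift, each = length(idx))
    }
  }

  # covariate-linked structure
  cov_loadings <- list()
  if (length(cfg$covariate_effects)) {
    cov_num <- list(age = as.numeric(scale(age)),
                    menstrual = as.numeric(menstrual == "pre"),
                    smoking = as.numeric(smoking == "ever"),
                    er = as.numeric(er == "pos"),
                    detection_mode = as.numeric(detection_mode == "screening"))
    for (nm in names(cfg$covariate_effects)) {
      if (!nm %in% names(cov_num)) stopf("unknown covariate effect '%s'", nm)
      eff <- cfg$covariate_effects[[nm]]
      idx <- sample.int(n_total, round(cfg$covariate_frac * n_total))
      M[idx, ] <- M[idx, ] + eff * rep(cov_num[[nm]], each = length(idx))
      cov_loadings[[nm]] <- idx
    }
  }

  # batch location/scale on top of the composed signal's residual structure
  loc <- cfg$batch_effects$location
  scl <- cfg$batch_effects$scale
  b_idx <- as.integer(sub("batch", "", batch))
  if (any(loc != 0) || any(scl != 1)) {
    M <- sweep(M, 1, mu) # residual + signal beyond baseline
    M <- sweep(M, 2, scl[b_idx], `*`)
    M <- sweep(M, 2, loc[b_idx], `+`)
    M <- M + mu
  }

  beta <- m_to_beta(M)

  # reference probes: cell-mixture betas replace the model values
  gt_cells <- NULL
  if (!is.null(cfg$cell_reference)) {
    n_ref <- nrow(cfg$cell_reference)
    frac <- rdirichlet(n, cfg$cell_alpha)
    dimnames(frac) <- list(sample_id, colnames(cfg$cell_reference))
    ref_idx <- seq_len(n_ref)  # first probes of chromosome 1
    beta[ref_idx, ] <- mix_cell_types(frac, cfg$cell_reference, noise_sd = 0)
    reference <- cfg$cell_reference
    rownames(reference) <- probe_id[ref_idx]
    gt_cells <- list(fractions = frac, reference = reference,
                     ref_probe_ids = probe_id[ref_idx])
  }
  dimnames(beta) <- list(probe_id, sample_id)

  # detection p and bead counts with planted failure probes
  detection_p <- matrix(runif(n_total * n, 0, 0.005), n_total, n,
                        dimnames = dimnames(beta))
  fail_det <- runif(n_total) < cfg$qc_rates$detection
  for (i in which(fail_det)) {
    k <- max(1L, round(runif(1, 0.08, 0.3) * n))
    detection_p[i, sample.int(n, k)] <- runif(k, 0.02, 0.5)
  }
  bead_counts <- matrix(3L + stats::rpois(n_total * n, 9), n_total, n,
                        dimnames = dimnames(beta))
  fail_beads <- runif(n_total) < cfg$qc_rates$beads
  for (i in which(fail_beads)) {
    k <- max(ceiling(0.05 * n), round(runif(1, 0.06, 0.3) * n))
    bead_counts[i, sample.int(n, k)] <- sample(1:2, k, replace = TRUE)
  }

  ds <- methylation_dataset(beta, manifest, samples,
                            detection_p = detection_p,
                            bead_counts = bead_counts)
  gt <- list(spiked = spiked,
             spike_probe_ids = spiked$probe_id,
             cells = gt_cells,
             covariate_loadings = cov_loadings,
             batch = setNames(batch, sample_id),
             midpoint = cfg$midpoint,
             config = cfg)
  list(dataset = ds, ground_truth = gt)
}
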