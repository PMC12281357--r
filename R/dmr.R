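#' Cluster probes into genomic neighbourhoods
#'
#' Maximal runs of manifest probes whose inter-probe gap is at most
#' `max_gap_bp` within a chromosome (the clustering step of bump hunting).
#' An unsorted manifest is sorted internally with a warning.
#'
#' @param manifest probe manifest with `probe_id`, `chrom`, `pos`.
#' @param max_gap_bp maximum within-cluster gap in bases.
#' @return the manifest rows sorted by (chrom, pos) with an integer
#'   `cluster` column; cluster ids are unique across chromosomes.
#' @export
cluster_probes <- function(manifest, max_gap_bp = 500) {
  ord <- order(manifest$chrom, manifest$pos)
  if (!identical(ord, seq_len(nrow(manifest)))) {
    warnf("manifest not sorted by (chrom, pos); sorting internally")
    manifest <- manifest[ord, , drop = FALSE]
  }
  new_chrom <- c(TRUE, manifest$chrom[-1] != manifest$chrom[-nrow(manifest)])
  gap <- c(Inf, diff(manifest$pos))
  gap[new_chrom] <- Inf
  manifest$cluster <- cumsum(new_chrom | gap > max_gap_bp)
  rownames(manifest) <- NULL
  manifest
}

# centered running mean with shrinking windows at cluster edges
running_mean <- function(x, window = 3) {
  n <- length(x)
  if (n == 1L || window <= 1L) return(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, 0)
}

#' Bump hunting: candidate differentially methylated regions
#'
#' Within each probe cluster of at least `smooth_min_probes` probes, the
#' per-probe group coefficients (M-scale log2FC from [fit_dmp_model()]) are
#' smoothed by a centered running mean; smaller clusters use the raw
#' coefficients. Candidate regions are maximal same-sign runs where the
#' absolute smoothed coefficient exceeds the cutoff (by default the
#' `cutoff_quantile` of all absolute smoothed coefficients). Each region's
#' area is the absolute sum of the UNsmoothed coefficients of its member
#' probes; singleton regions are allowed.
#'
#' @param fits a `dmp_fit` (or data.frame with `probe_id`, `log2FC`).
#' @param manifest manifest covering the fitted probes.
#' @param max_gap_bp cluster gap, see [cluster_probes()].
#' @param smooth_window running-mean window (probes).
#' @param smooth_min_probes minimum cluster size for smoothing.
#' @param cutoff_quantile quantile of |smoothed coefficient| defining the
#'   cutoff when `cutoff` is not supplied.
#' @param cutoff absolute cutoff override (used by the permutation null so
#'   every permutation is judged against the observed cutoff).
#' @return A data.frame of regions: `region_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `n_probes`, `area`, `mean_coef`, `direction`
#'   ("hyper"/"hypo" in the low group), `gene`, and a list column `probes`
#'   of member probe ids. The cutoff used is attached as attribute
#'   `cutoff`.
#' @export
find_bumps <- function(fits, manifest, max_gap_bp = 500, smooth_window = 3,
                       smooth_min_probes = 3, cutoff_quantile = 0.99,
                       cutoff = NULL) {
  if (!nrow(fits)) stopf("empty fit set")
  man <- cluster_probes(manifest[manifest$probe_id %in% fits$probe_id, ,
                                 drop = FALSE], max_gap_bp)
  coefv <- fits$log2FC[match(man$probe_id, fits$probe_id)]

  smoothed <- coefv
  for (cl in split(seq_len(nrow(man)), man$cluster)) {
    if (length(cl) >= smooth_min_probes) {
      smoothed[cl] <- running_mean(coefv[cl], smooth_window)
    }
  }
  if (is.null(cutoff)) cutoff <- as.numeric(quantile(abs(smoothed), cutoff_quantile))

  state <- sign(smoothed) * (abs(smoothed) > cutoff)
  regions <- list()
  for (cl in split(seq_len(nrow(man)), man$cluster)) {
    r <- rle(state[cl])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values != 0)) {
      idx <- cl[starts[k]:ends[k]]
      genes <- setdiff(unique(man$gene[idx]), "")
      regions[[length(regions) + 1L]] <- list(
        chrom = man$chrom[idx[1]], start = man$pos[idx[1]],
        end = man$pos[idx[length(idx)]], n_probes = length(idx),
        area = abs(sum(coefv[idx])), mean_coef = mean(coefv[idx]),
        direction = if (r$values[k] > 0) "hyper" else "hypo",
        gene = if (length(genes)) paste(genes, collapse = ";") else "",
        probes = man$probe_id[idx])
    }
  }
  if (!length(regions)) {
    out <- data.frame(region_id = integer(), chrom = character(),
                      start = integer(), end = integer(), n_probes = integer(),
                      area = numeric(), mean_coef = numeric(),
                      direction = character(), gene = character(),
                      stringsAsFactors = FALSE)
    out$probes <- list()
  } else {
    out <- data.frame(
      region_id = seq_along(regions),
      chrom = vapply(regions, `[[`, "", "chrom"),
      start = vapply(regions, `[[`, 0, "start"),
      end = vapply(regions, `[[`, 0, "end"),
      n_probes = vapply(regions, `[[`, 0L, "n_probes"),
      area = vapply(regions, `[[`, 0, "area"),
      mean_coef = vapply(regions, `[[`, 0, "mean_coef"),
      direction = vapply(regions, `[[`, "", "direction"),
      gene = vapply(regions, `[[`, "", "gene"),
      stringsAsFactors = FALSE)
    out$probes <- lapply(regions, `[[`, "probes")
    out <- out[order(-out$area), , drop = FALSE]
    out$region_id <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  attr(out, "cutoff") <- cutoff
  attr(out, "params") <- list(max_gap_bp = max_gap_bp,
                              smooth_window = smooth_window,
                              smooth_min_probes = smooth_min_probes,
                              cutoff_quantile = cutoff_quantile)
  out
}

#' Permutation null for DMR areas
#'
#' Permutes the group labels (covariates fixed) `n_perm` times, refits the
#' per-probe model, re-runs bump finding at the observed cutoff, and records
#' the maximum null area per permutation. Each observed region's permutation
#' p value is `(1 + #\{max null area >= observed area\}) / (1 + n_perm)`, so
#' the smallest achievable p is `1/(n_perm + 1)`.
#'
#' @param ds the (subset) dataset the observed regions came from.
#' @param covariates covariates of the per-probe model.
#' @param n_perm number of permutations (at least 10).
#' @param seed RNG seed for the permutations.
#' @param ... bump-finding parameters passed to [find_bumps()].
#' @return list with `regions` (observed regions plus `perm_p`),
#'   `null_max_areas` (length `n_perm`), and `cutoff`.
#' @export
permute_null <- function(ds, covariates = c("age", "menstrual",
                                            "detection_mode", "er"),
                         n_perm = 100, seed = 1, ...) {
  if (n_perm < 10) stopf("n_perm must be at least 10")
  keep <- ds$samples$resilience_group %in% c("high", "low")
  ds2 <- subset_dataset(ds, samples = which(keep))

  obs_fit <- suppressWarnings(fit_dmp_model(ds2, covariates = covariates))
  obs <- find_bumps(obs_fit, ds2$manifest, ...)
  cutoff <- attr(obs, "cutoff")

  labels <- ds2$samples$resilience_group
  null_max <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    dsp <- ds2
    dsp$samples$resilience_group <- sample(labels)
    fit <- suppressWarnings(fit_dmp_model(dsp, covariates = covariates))
    nb <- find_bumps(fit, dsp$manifest, ..., cutoff = cutoff)
    if (nrow(nb)) max(nb$area) else 0
  }, 0))

  obs$perm_p <- vapply(obs$area, function(a) {
    (1 + sum(null_max >= a)) / (1 + n_perm)
  }, 0)
  list(regions = obs, null_max_areas = null_max, cutoff = cutoff)
}

#' Run the subset-wise DMR analysis
#'
#' Bump hunting on the full discovery set and every percentile subset,
#' reusing the subset-wise model fits.
#'
#' @param ds a QC-filtered [methylation_dataset()].
#' @param subsets list from [make_subsets()].
#' @param covariates model covariates.
#' @param ... bump-finding parameters for [find_bumps()].
#' @return list of per-subset results: `label`, `q`, `score_gap`, `regions`.
#' @export
run_dmr_analysis <- function(ds, subsets,
                             covariates = c("age", "menstrual",
                                            "detection_mode", "er"), ...) {
  lapply(subsets, function(sp) {
    sub <- subset_dataset(ds, samples = c(sp$low_ids, sp$high_ids))
    fit <- suppressWarnings(fit_dmp_model(sub, covariates = covariates))
    list(label = sp$label, q = sp$q, score_gap = sp$score_gap,
         regions = find_bumps(fit, sub$manifest, ...))
  })
}

#' Cross-subset DMR consistency and area-trend scan
#'
#' Matches candidate regions across subset analyses by shared gene label
#' when available, otherwise by coordinate overlap (>= 1 bp on the same
#' chromosome), and summarizes each matched region key: per-subset presence
#' and area, the longest consecutive presence run over the ordered subsets,
#' and an area-trend statistic (Spearman correlation of area against subset
#' distality rank; +1 means the area grows steadily toward the most distal
#' subset).
#'
#' @param dmr_results output of [run_dmr_analysis()], ordered from the full
#'   set to the most distal subset.
#' @return data.frame: `key`, `gene`, `chrom`, `start`, `end`, `n_subsets`,
#'   `max_run`, `area_trend_stat`, and one `area_<label>` column per subset
#'   (NA when absent).
#' @export
dmr_consistency_scan <- function(dmr_results) {
  if (length(dmr_results) < 2L) stopf("need at least 2 subset analyses")
  labels <- vapply(dmr_results, `[[`, "", "label")
  keys <- list()
  presence <- list()

  match_key <- function(reg) {
    for (ki in seq_along(keys)) {
      k <- keys[[ki]]
      if (nzchar(reg$gene) && nzchar(k$gene) &&
          length(intersect(strsplit(reg$gene, ";")[[1]],
                           strsplit(k$gene, ";")[[1]]))) return(ki)
      if (reg$chrom == k$chrom && reg$start <= k$end && reg$end >= k$start) return(ki)
    }
    0L
  }

  for (si in seq_along(dmr_results)) {
    regs <- dmr_results[[si]]$regions
    for (ri in seq_len(nrow(regs))) {
      reg <- regs[ri, ]
      ki <- match_key(reg)
      if (ki == 0L) {
        keys[[length(keys) + 1L]] <- list(gene = reg$gene, chrom = reg$chrom,
                                          start = reg$start, end = reg$end)
        ki <- length(keys)
        presence[[ki]] <- matrix(NA_real_, 1, length(labels),
                                 dimnames = list(NULL, labels))
      } else {
        keys[[ki]]$start <- min(keys[[ki]]$start, reg$start)
        keys[[ki]]$end <- max(keys[[ki]]$end, reg$end)
        if (!nzchar(keys[[ki]]$gene)) keys[[ki]]$gene <- reg$gene
      }
      prev <- presence[[ki]][1, si]
      presence[[ki]][1, si] <- max(prev, reg$area, na.rm = TRUE)
    }
  }
  if (!length(keys)) {
    return(data.frame(key = character(), gene = character(),
                      chrom = character(), start = integer(), end = integer(),
                      n_subsets = integer(), max_run = integer(),
                      area_trend_stat = numeric(), stringsAsFactors = FALSE))
  }
  areas <- do.call(rbind, presence)
  present <- !is.na(areas)
  rank_seq <- seq_along(labels)
  out <- data.frame(
    key = vapply(seq_along(keys), function(i) {
      k <- keys[[i]]
      if (nzchar(k$gene)) k$gene else sprintf("%s:%d-%d", k$chrom, k$start, k$end)
    }, ""),
    gene = vapply(keys, `[[`, "", "gene"),
    chrom = vapply(keys, `[[`, "", "chrom"),
    start = vapply(keys, `[[`, 0, "start"),
    end = vapply(keys, `[[`, 0, "end"),
    n_subsets = rowSums(present),
    max_run = apply(present, 1, max_run),
    area_trend_stat = vapply(seq_along(keys), function(i) {
      spearman_safe(areas[i, present[i, ]], rank_seq[present[i, ]])
    }, 0),
    stringsAsFactors = FALSE)
  cbind(out, setNames(as.data.frame(areas), paste0("area_", labels)))
}
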