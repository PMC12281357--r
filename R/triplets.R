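#' Build matched triplets of one low- and two high-resilience samples
#'
#' Greedy covariate matching for the classifier set: each low-resilience
#' sample (CD-RISC score <= `low_max`), processed in ascending score order,
#' is matched with the 2 still-unused high-resilience samples (score >=
#' `high_min`) that agree exactly on ER, PR and HER2 status, respect the
#' smoking rule (never-smokers are matched only to never-smokers;
#' ever-smoker lows may match either, preferring ever-smokers), and minimize
#' the absolute age difference. Ties are broken by sample id. Lows with
#' fewer than 2 feasible partners are excluded with a warning.
#'
#' @param samples sample sheet with `sample_id`, `cdrisc_score`, `age`,
#'   `er`, `pr`, `her2`, `smoking`.
#' @param low_max,high_min score thresholds defining the classifier groups.
#' @param match_covs categorical covariates requiring exact agreement.
#' @return A `triplet_set`: data.frame `triplet_id`, `low_id`, `high_id1`,
#'   `high_id2`, `age_dist1`, `age_dist2`, with attributes `low_max`,
#'   `high_min`, `excluded` (unmatched low ids).
#' @export
build_triplets <- function(samples, low_max = 50, high_min = 80,
                           match_covs = c("er", "pr", "her2")) {
  need <- c("sample_id", "cdrisc_score", "age", "smoking", match_covs)
  miss <- setdiff(need, names(samples))
  if (length(miss)) stopf("sample sheet lacks columns: %s", paste(miss, collapse = ", "))

  lows <- samples[samples$cdrisc_score <= low_max, , drop = FALSE]
  highs <- samples[samples$cdrisc_score >= high_min, , drop = FALSE]
  lows <- lows[order(lows$cdrisc_score, lows$sample_id), , drop = FALSE]
  if (nrow(highs) < 2 * nrow(lows)) {
    warnf("only %d high-resilience samples for %d lows; some lows will go unmatched",
          nrow(highs), nrow(lows))
  }

  used <- character()
  rows <- list()
  excluded <- character()
  for (i in seq_len(nrow(lows))) {
    low <- lows[i, ]
    cand <- highs[!(highs$sample_id %in% used), , drop = FALSE]
    for (cv in match_covs) cand <- cand[cand[[cv]] == low[[cv]], , drop = FALSE]
    if (low$smoking == "never") {
      cand <- cand[cand$smoking == "never", , drop = FALSE]
      pref <- rep(0L, nrow(cand))
    } else {
      pref <- as.integer(cand$smoking != "ever") # prefer ever-smoker partners
    }
    if (nrow(cand) < 2) {
      warnf("low sample %s has no feasible matched pair; excluded", low$sample_id)
      excluded <- c(excluded, low$sample_id)
      next
    }
    age_dist <- abs(cand$age - low$age)
    ord <- order(pref, age_dist, cand$sample_id)
    pick <- cand[ord[1:2], ]
    used <- c(used, pick$sample_id)
    rows[[length(rows) + 1L]] <- data.frame(
      low_id = low$sample_id,
      high_id1 = pick$sample_id[1], high_id2 = pick$sample_id[2],
      age_dist1 = abs(pick$age[1] - low$age),
      age_dist2 = abs(pick$age[2] - low$age),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stopf("no triplets could be formed")
  ts <- do.call(rbind, rows)
  ts <- cbind(triplet_id = seq_len(nrow(ts)), ts)
  structure(ts, class = c("triplet_set", "data.frame"),
            low_max = low_max, high_min = high_min, excluded = excluded)
}

#' All sample ids of a triplet set
#' @param ts a `triplet_set`.
#' @return character vector (lows and highs).
#' @export
triplet_samples <- function(ts) {
  c(ts$low_id, ts$high_id1, ts$high_id2)
}

#' Split triplets into train/confirmation/test sets
#'
#' Triplets (not individual samples) are randomly partitioned by the given
#' fractions, so every matched unit stays whole inside one partition and the
#' 1:2 class balance is preserved in each. Partition sizes follow the
#' largest-remainder rounding of `fractions * n`.
#'
#' @param ts a `triplet_set` (at least 5 triplets).
#' @param fractions train/confirmation/test fractions, summing to 1.
#' @param seed RNG seed; the split is fully determined by it.
#' @return list of `triplet_set`s: `train`, `confirm`, `test`.
#' @export
split_triplets <- function(ts, fractions = c(train = 0.5, confirm = 0.2,
                                             test = 0.3), seed = 1) {
  if (nrow(ts) < 5) stopf("need at least 5 triplets to split")
  if (abs(sum(fractions) - 1) > 1e-8) stopf("fractions must sum to 1")
  n <- nrow(ts)
  exact <- fractions * n
  sizes <- floor(exact)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(-(exact - sizes), seq_along(fractions))[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  perm <- with_seed(seed, sample.int(n))
  bounds <- cumsum(sizes)
  idx <- list(train = perm[seq_len(bounds[1])],
              confirm = perm[setdiff(seq_len(bounds[2]), seq_len(bounds[1]))],
              test = perm[setdiff(seq_len(bounds[3]), seq_len(bounds[2]))])
  lapply(idx, function(i) {
    out <- ts[sort(i), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
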