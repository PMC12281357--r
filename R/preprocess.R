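#' Beta/M-value transforms
#'
#' `beta_to_m()` maps methylation fractions to the variance-stabilized
#' modeling scale, `M = log2(beta / (1 - beta))`; `m_to_beta()` inverts it.
#' Beta values are clipped into `[eps, 1 - eps]` before the logit so boundary
#' values cannot produce infinities; on the interior the two maps are exact
#' inverses.
#'
#' @param beta,m numeric vector or matrix.
#' @param eps boundary clip (default 1e-3).
#' @return transformed values, same shape as the input.
#' @examples
#' beta_to_m(0.5)  # 0
#' beta_to_m(0.8)  # 2
#' m_to_beta(-2)   # 0.2
#' @export
beta_to_m <- function(beta, eps = 1e-3) {
  beta <- pmin(pmax(beta, eps), 1 - eps)
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

#' M-value matrix of a dataset
#'
#' @param ds a [methylation_dataset()].
#' @param eps boundary clip for the logit.
#' @return probes x samples matrix of M values.
#' @export
get_m_values <- function(ds, eps = ds$eps %||% 1e-3) {
  stopifnot(inherits(ds, "methylation_dataset"))
  beta_to_m(ds$beta, eps)
}

#' Probe QC filter cascade
#'
#' Applies the six-rule probe filter used for EPIC arrays, in order:
#' 1) detection p > `detection_p_max` in more than `max_fail_fraction` of
#' samples; 2) fewer than `min_beads` beads in at least `bead_fail_fraction`
#' of samples; 3) non-CpG probes (ids not starting with "cg"); 4) SNP-related
#' probes; 5) multihit probes; 6) X/Y-chromosome probes. The rules are
#' independent predicates, so the surviving probe set does not depend on
#' their order; the report counts removals sequentially in the order above.
#' The bead-count rule's sample fraction is evaluated per probe across
#' samples.
#'
#' @param ds a [methylation_dataset()].
#' @param detection_p_max per-measurement detection p threshold.
#' @param max_fail_fraction a probe is removed when the fraction of samples
#'   failing the detection threshold exceeds this.
#' @param min_beads minimum bead count per measurement.
#' @param bead_fail_fraction a probe is removed when at least this fraction
#'   of samples falls below `min_beads`.
#' @return list with `dataset` (filtered) and `report` (data.frame
#'   `rule`, `probes_removed`, applied in order).
#' @export
filter_probes <- function(ds, detection_p_max = 0.01, max_fail_fraction = 0.05,
                          min_beads = 3, bead_fail_fraction = 0.05) {
  stopifnot(inherits(ds, "methylation_dataset"))
  n <- ncol(ds$beta)
  man <- ds$manifest

  fail <- list()
  if (is.null(ds$detection_p)) {
    warnf("no detection-p matrix: detection filter skipped")
    fail$detection_p <- rep(FALSE, nrow(ds$beta))
  } else {
    fail$detection_p <- rowMeans(ds$detection_p > detection_p_max) > max_fail_fraction
  }
  if (is.null(ds$bead_counts)) {
    warnf("no bead-count matrix: bead filter skipped")
    fail$bead_count <- rep(FALSE, nrow(ds$beta))
  } else {
    fail$bead_count <- rowMeans(ds$bead_counts < min_beads) >= bead_fail_fraction
  }
  fail$non_cpg <- !startsWith(man$probe_id, "cg")
  fail$snp <- as.logical(man$snp_flag)
  fail$multihit <- as.logical(man$multihit_flag)
  fail$sex_chrom <- as.logical(man$sex_chrom_flag) | man$chrom %in% c("chrX", "chrY")

  remaining <- rep(TRUE, nrow(ds$beta))
  report <- data.frame(rule = names(fail),
                       probes_removed = NA_integer_,
                       stringsAsFactors = FALSE)
  for (i in seq_along(fail)) {
    removed <- remaining & fail[[i]]
    report$probes_removed[i] <- sum(removed)
    remaining <- remaining & !fail[[i]]
  }
  if (!any(remaining)) stopf("no probes survive the filter cascade")
  list(dataset = subset_dataset(ds, probes = which(remaining)),
       report = report)
}

#' Batch adjustment by per-batch location/scale standardization
#'
#' For each probe, each batch's M values are standardized to the probe's
#' grand mean and SD, removing batch location and scale differences while
#' preserving each probe's overall mean and SD exactly. With a single batch
#' the data are returned unchanged. This is a deliberately exact,
#' shrinkage-free adjustment (`method = "standardize"`); the method key is
#' kept in configs for future extension.
#'
#' @param ds a [methylation_dataset()].
#' @param batch batch labels (defaults to the sample sheet's `batch` column).
#' @param method adjustment method; only `"standardize"` is implemented.
#' @return the adjusted `methylation_dataset` (beta values re-derived from
#'   adjusted M values).
#' @export
adjust_batch <- function(ds, batch = ds$samples$batch, method = "standardize") {
  stopifnot(inherits(ds, "methylation_dataset"))
  method <- match.arg(method, "standardize")
  batch <- as.character(batch)
  if (length(batch) != ncol(ds$beta)) stopf("batch labels do not match the sample count")
  tab <- table(batch)
  if (any(tab < 2)) {
    stopf("singleton batch (%s): at least 2 samples per batch are required",
          paste(names(tab)[tab < 2], collapse = ", "))
  }
  if (length(tab) == 1L) return(ds)

  M <- get_m_values(ds)
  gm <- rowMeans(M)
  gsd <- apply(M, 1, sd)
  adj <- M
  for (b in names(tab)) {
    idx <- which(batch == b)
    bm <- rowMeans(M[, idx, drop = FALSE])
    bsd <- apply(M[, idx, drop = FALSE], 1, sd)
    bsd[bsd == 0] <- 1 # constant within batch: centering only
    adj[, idx] <- (M[, idx, drop = FALSE] - bm) / bsd * gsd + gm
  }
  # rescale each probe so the grand mean/SD are preserved exactly
  am <- rowMeans(adj)
  asd <- apply(adj, 1, sd)
  asd[asd == 0] <- 1
  adj <- (adj - am) / asd * gsd + gm
  ds$beta <- m_to_beta(adj)
  ds$beta[] <- pmin(pmax(ds$beta, ds$eps), 1 - ds$eps)
  ds
}

#' PCA-covariate association scan
#'
#' Principal component analysis of the centered M values (samples as
#' observations), followed by a per-PC association test against each
#' covariate: a Pearson correlation test for numeric covariates and a
#' one-way ANOVA for categorical ones. Constant covariates are flagged and
#' skipped. Used as the data-structure diagnostic before differential
#' analysis (which PCs carry age/menstrual/batch/score signal).
#'
#' @param ds a [methylation_dataset()].
#' @param covariates character vector of sample-sheet columns to test
#'   (default: every column except `sample_id`).
#' @param n_components number of leading PCs to test.
#' @return list with `associations` (data.frame `pc`, `covariate`, `p`,
#'   `skipped`), `variance_explained` (fraction per PC), and `scores`
#'   (samples x PCs).
#' @export
pca_covariate_scan <- function(ds, covariates = NULL, n_components = 5) {
  stopifnot(inherits(ds, "methylation_dataset"))
  if (ncol(ds$beta) < 2) stopf("need at least 2 samples for PCA")
  if (is.null(covariates)) {
    covariates <- setdiff(names(ds$samples), "sample_id")
  }
  M <- get_m_values(ds)
  pc <- prcomp(t(M), center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(pc$x))
  ve <- pc$sdev^2 / sum(pc$sdev^2)

  res <- list()
  for (j in seq_len(n_components)) {
    sc <- pc$x[, j]
    for (cv in covariates) {
      x <- ds$samples[[cv]]
      skipped <- FALSE
      p <- NA_real_
      if (length(unique(x[!is.na(x)])) < 2L) {
        skipped <- TRUE
      } else if (is.numeric(x)) {
        p <- cor.test(sc, x)$p.value
      } else {
        fit <- aov(sc ~ factor(x))
        p <- summary(fit)[[1]][["Pr(>F)"]][1]
      }
      res[[length(res) + 1L]] <- data.frame(
        pc = paste0("PC", j), covariate = cv, p = p, skipped = skipped,
        stringsAsFactors = FALSE)
    }
  }
  list(associations = do.call(rbind, res),
       variance_explained = ve[seq_len(n_components)],
       scores = pc$x[, seq_len(n_components), drop = FALSE])
}
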