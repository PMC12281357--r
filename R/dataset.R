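#' Construct a methylation dataset
#'
#' The container every pipeline stage consumes and produces: a beta-value
#' matrix (probes x samples, values in (0, 1)), a probe manifest, and a
#' sample sheet, with optional detection-p and bead-count matrices of the
#' same shape as `beta`. Rows/columns are aligned to the manifest/sample
#' sheet by id, not by order.
#'
#' @param beta numeric matrix, probes x samples, rownames = probe ids,
#'   colnames = sample ids, values in (0, 1) (clipped into
#'   `[eps, 1 - eps]` on construction).
#' @param manifest data.frame with columns `probe_id`, `chrom`, `pos`
#'   (1-based), `gene`, `feature_class`, `snp_flag`, `multihit_flag`,
#'   `sex_chrom_flag`.
#' @param samples data.frame with columns `sample_id`, `cdrisc_score`, and
#'   any covariates (`age`, `menstrual`, `detection_mode`, `er`, `pr`,
#'   `her2`, `smoking`, `batch`); a `resilience_group` column
#'   (high/low/unassigned) is derived from `cdrisc_score` if absent.
#' @param detection_p,bead_counts optional matrices, same shape and
#'   dimnames as `beta`.
#' @param eps boundary clip for beta values (default 1e-3).
#' @param low_max,high_min score thresholds used to derive
#'   `resilience_group` when absent (low: score <= `low_max`; high:
#'   score >= `high_min`).
#' @return An object of class `methylation_dataset`.
#' @export
methylation_dataset <- function(beta, manifest, samples,
                                detection_p = NULL, bead_counts = NULL,
                                eps = 1e-3, low_max = 65, high_min = 77) {
  beta <- as.matrix(beta)
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  need_m <- c("probe_id", "chrom", "pos")
  if (!all(need_m %in% names(manifest))) {
    stopf("manifest lacks columns: %s",
          paste(setdiff(need_m, names(manifest)), collapse = ", "))
  }
  if (!"sample_id" %in% names(samples)) stopf("sample sheet lacks 'sample_id'")
  if (anyDuplicated(manifest$probe_id)) {
    stopf("duplicate probe ids in manifest: %s",
          paste(head(manifest$probe_id[duplicated(manifest$probe_id)], 3), collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stopf("duplicate sample ids in sample sheet: %s",
          paste(head(samples$sample_id[duplicated(samples$sample_id)], 3), collapse = ", "))
  }
  if (any(manifest$pos <= 0)) stopf("manifest positions must be positive (1-based)")

  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stopf("beta matrix needs probe ids as rownames and sample ids as colnames")
  }
  miss_p <- setdiff(rownames(beta), manifest$probe_id)
  if (length(miss_p)) stopf("beta probes absent from manifest: %s",
                            paste(head(miss_p, 3), collapse = ", "))
  miss_s <- setdiff(colnames(beta), samples$sample_id)
  if (length(miss_s)) stopf("beta samples absent from sample sheet: %s",
                            paste(head(miss_s, 3), collapse = ", "))

  # align metadata to the matrix by id
  manifest <- manifest[match(rownames(beta), manifest$probe_id), , drop = FALSE]
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
  rownames(manifest) <- NULL
  rownames(samples) <- NULL

  bad <- which(!is.finite(beta) | beta <= 0 | beta >= 1)
  if (length(bad)) {
    out_of_eps <- beta[bad] < -eps | beta[bad] > 1 + eps | !is.finite(beta[bad])
    if (any(out_of_eps)) {
      ids <- unique(rownames(beta)[((bad - 1L) %% nrow(beta)) + 1L][out_of_eps])
      stopf("beta values outside (0,1) beyond eps for probes: %s",
            paste(head(ids, 3), collapse = ", "))
    }
  }
  beta[] <- pmin(pmax(beta, eps), 1 - eps)

  for (extra in list(detection_p = detection_p, bead_counts = bead_counts)) NULL
  check_aux <- function(x, what) {
    if (is.null(x)) return(NULL)
    x <- as.matrix(x)
    if (!identical(dim(x), dim(beta))) stopf("%s shape differs from beta", what)
    x[match(rownames(beta), rownames(x)), match(colnames(beta), colnames(x)), drop = FALSE]
  }
  detection_p <- check_aux(detection_p, "detection_p")
  bead_counts <- check_aux(bead_counts, "bead_counts")

  if (!"resilience_group" %in% names(samples)) {
    samples$resilience_group <- resilience_group(samples$cdrisc_score, low_max, high_min)
  }

  structure(list(beta = beta, manifest = manifest, samples = samples,
                 detection_p = detection_p, bead_counts = bead_counts,
                 eps = eps),
            class = "methylation_dataset")
}

#' Assign resilience groups from CD-RISC scores
#'
#' @param score numeric CD-RISC totals.
#' @param low_max scores `<= low_max` are "low".
#' @param high_min scores `>= high_min` are "high".
#' @return character vector in `{"low", "high", "unassigned"}`.
#' @export
resilience_group <- function(score, low_max = 65, high_min = 77) {
  ifelse(is.na(score), "unassigned",
         ifelse(score <= low_max, "low",
                ifelse(score >= high_min, "high", "unassigned")))
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat(sprintf("methylation_dataset: %d probes x %d samples\n",
              nrow(x$beta), ncol(x$beta)))
  grp <- table(factor(x$samples$resilience_group, c("high", "low", "unassigned")))
  cat(sprintf("  groups: high=%d low=%d unassigned=%d\n",
              grp[["high"]], grp[["low"]], grp[["unassigned"]]))
  cat(sprintf("  chromosomes: %d; detection_p: %s; bead_counts: %s\n",
              length(unique(x$manifest$chrom)),
              ifelse(is.null(x$detection_p), "absent", "present"),
              ifelse(is.null(x$bead_counts), "absent", "present")))
  invisible(x)
}

#' @export
dim.methylation_dataset <- function(x) dim(x$beta)

#' Subset a methylation dataset by probes and/or samples
#'
#' @param ds a `methylation_dataset`.
#' @param probes probe ids (or logical/integer index over rows) to keep.
#' @param samples sample ids (or index over columns) to keep.
#' @return the subsetted `methylation_dataset`.
#' @export
subset_dataset <- function(ds, probes = NULL, samples = NULL) {
  stopifnot(inherits(ds, "methylation_dataset"))
  ridx <- if (is.null(probes)) seq_len(nrow(ds$beta)) else {
    if (is.character(probes)) match(probes, rownames(ds$beta)) else probes
  }
  cidx <- if (is.null(samples)) seq_len(ncol(ds$beta)) else {
    if (is.character(samples)) match(samples, colnames(ds$beta)) else samples
  }
  if (anyNA(ridx)) stopf("unknown probe ids in subset")
  if (anyNA(cidx)) stopf("unknown sample ids in subset")
  ds$beta <- ds$beta[ridx, cidx, drop = FALSE]
  ds$manifest <- ds$manifest[ridx, , drop = FALSE]
  ds$samples <- ds$samples[cidx, , drop = FALSE]
  rownames(ds$manifest) <- NULL
  rownames(ds$samples) <- NULL
  if (!is.null(ds$detection_p)) ds$detection_p <- ds$detection_p[ridx, cidx, drop = FALSE]
  if (!is.null(ds$bead_counts)) ds$bead_counts <- ds$bead_counts[ridx, cidx, drop = FALSE]
  ds
}
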