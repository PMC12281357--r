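#' Read a methylation dataset from delimited-text files
#'
#' Reads the canonical interchange files: a beta matrix as TSV (probes x
#' samples, probe id in the first column), a probe manifest CSV and a sample
#' sheet CSV, plus optional detection-p / bead-count TSVs with the beta
#' matrix's shape. Rows and columns are aligned to the manifest and sample
#' sheet by id, so file order does not matter; mismatched or duplicate ids
#' fail with the offending ids named.
#'
#' @param beta_path,manifest_path,samples_path file paths.
#' @param detection_p_path,bead_counts_path optional auxiliary matrices.
#' @return a [methylation_dataset()].
#' @export
read_methylation_dataset <- function(beta_path, manifest_path, samples_path,
                                     detection_p_path = NULL,
                                     bead_counts_path = NULL) {
  read_matrix <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
    m <- as.matrix(dt[, -1, drop = FALSE])
    rownames(m) <- dt[[1]]
    m
  }
  beta <- read_matrix(beta_path)
  manifest <- data.table::fread(manifest_path, sep = ",", header = TRUE,
                                data.table = FALSE)
  samples <- data.table::fread(samples_path, sep = ",", header = TRUE,
                               data.table = FALSE)
  detection_p <- if (!is.null(detection_p_path)) read_matrix(detection_p_path)
  bead_counts <- if (!is.null(bead_counts_path)) read_matrix(bead_counts_path)
  methylation_dataset(beta, manifest, samples,
                      detection_p = detection_p, bead_counts = bead_counts)
}

#' Write a methylation dataset as delimited-text files
#'
#' Inverse of [read_methylation_dataset()]: beta (and any auxiliary
#' matrices) as TSV with the probe id as first column, manifest and sample
#' sheet as CSV.
#'
#' @param ds a [methylation_dataset()].
#' @param dir output directory (created if absent).
#' @param prefix filename prefix.
#' @return invisibly, the named vector of written paths.
#' @export
write_methylation_dataset <- function(ds, dir, prefix = "dataset") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  write_matrix <- function(m, name) {
    path <- file.path(dir, paste0(prefix, "_", name, ".tsv"))
    df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    data.table::fwrite(df, path, sep = "\t")
    path
  }
  paths["beta"] <- write_matrix(ds$beta, "beta")
  paths["manifest"] <- file.path(dir, paste0(prefix, "_manifest.csv"))
  data.table::fwrite(ds$manifest, paths["manifest"])
  paths["samples"] <- file.path(dir, paste0(prefix, "_samples.csv"))
  data.table::fwrite(ds$samples, paths["samples"])
  if (!is.null(ds$detection_p)) paths["detection_p"] <- write_matrix(ds$detection_p, "detection_p")
  if (!is.null(ds$bead_counts)) paths["bead_counts"] <- write_matrix(ds$bead_counts, "bead_counts")
  invisible(paths)
}

#' Export DMRs as a BED file
#'
#' Converts the 1-based inclusive region coordinates to BED's 0-based
#' half-open convention (start-1, end).
#'
#' @param regions a region table from [find_bumps()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_dmr_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end,
                    name = ifelse(nzchar(regions$gene), regions$gene,
                                  paste0("region", regions$region_id)),
                    score = round(1000 * regions$area / max(regions$area, 1)),
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every stage toggle, threshold and seed of the end-to-end
#' pipeline in one validated list that round-trips through YAML unchanged.
#'
#' @param beta,manifest,samples,detection_p,bead_counts input file paths
#'   (auxiliary ones optional).
#' @param out_dir output directory.
#' @param stages named logical: which of qc/dmp/dmr/classify to run; a
#'   disabled stage's outputs are expected on disk from a prior run.
#' @param detection_p_max,max_fail_fraction,min_beads,bead_fail_fraction
#'   probe-filter thresholds, see [filter_probes()].
#' @param adjust_batch logical: apply the per-batch standardization.
#' @param p_max,lfc_min DMP calling gates.
#' @param steps percentile subset steps.
#' @param max_gap_bp,smooth_window,cutoff_quantile bump-hunting parameters.
#' @param n_perm DMR permutations (0 = skip the permutation null).
#' @param n_iter,base_seed classifier resampling controls.
#' @param low_max,high_min triplet score thresholds.
#' @param covariates model covariates.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(beta, manifest, samples,
                            detection_p = NULL, bead_counts = NULL,
                            out_dir = "epires_out",
                            stages = c(qc = TRUE, dmp = TRUE, dmr = TRUE,
                                       classify = TRUE),
                            detection_p_max = 0.01, max_fail_fraction = 0.05,
                            min_beads = 3, bead_fail_fraction = 0.05,
                            adjust_batch = FALSE,
                            p_max = 0.05, lfc_min = 0.5,
                            steps = c(1, .9, .8, .7, .6, .5, .4, .3, .2, .1, .05),
                            max_gap_bp = 500, smooth_window = 3,
                            cutoff_quantile = 0.99, n_perm = 0,
                            n_iter = 50, base_seed = 42,
                            low_max = 50, high_min = 80,
                            covariates = c("age", "menstrual",
                                           "detection_mode", "er")) {
  cfg <- as.list(environment())
  stopifnot(detection_p_max > 0, detection_p_max < 1,
            max_fail_fraction >= 0, max_fail_fraction <= 1,
            min_beads >= 1, p_max > 0, p_max <= 1, lfc_min >= 0,
            all(steps > 0), all(steps <= 1),
            max_gap_bp >= 0, smooth_window >= 1,
            cutoff_quantile > 0, cutoff_quantile < 1,
            n_perm >= 0, n_iter >= 1, low_max < high_min)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read/write a pipeline configuration as YAML
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$stages <- as.list(out$stages)  # keep stage names as a YAML mapping
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$stages <- unlist(raw$stages)
  do.call(pipeline_config, raw[!vapply(raw, is.null, TRUE)])
}

#' Run the full pipeline
#'
#' Executes qc -> dmp -> dmr -> classify on the configured inputs, writing
#' each stage's tables as CSV under `out_dir` and a run manifest (config
#' snapshot, package version, per-file checksums, collected warnings) as
#' YAML. Stages toggled off are skipped; downstream stages then read the
#' QC-filtered dataset cached by a prior run. Given fixed seeds the outputs
#' are byte-identical across reruns.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the run manifest list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))

  qc_prefix <- file.path(cfg$out_dir, "qc")
  if (cfg$stages[["qc"]]) {
    ds <- read_methylation_dataset(cfg$beta, cfg$manifest, cfg$samples,
                                   cfg$detection_p, cfg$bead_counts)
    res <- withCallingHandlers(
      filter_probes(ds, cfg$detection_p_max, cfg$max_fail_fraction,
                    cfg$min_beads, cfg$bead_fail_fraction),
      warning = function(w) { note(w); invokeRestart("muffleWarning") })
    ds <- res$dataset
    if (cfg$adjust_batch) ds <- adjust_batch(ds)
    data.table::fwrite(res$report, file.path(cfg$out_dir, "qc_filter_report.csv"))
    write_methylation_dataset(ds, cfg$out_dir, prefix = "qc")
  } else {
    ds <- read_methylation_dataset(paste0(qc_prefix, "_beta.tsv"),
                                   paste0(qc_prefix, "_manifest.csv"),
                                   paste0(qc_prefix, "_samples.csv"))
  }

  subsets <- make_subsets(ds$samples, steps = cfg$steps)
  if (cfg$stages[["dmp"]]) {
    dmp_res <- withCallingHandlers(
      run_dmp_analysis(ds, subsets, covariates = cfg$covariates,
                       p_max = cfg$p_max, lfc_min = cfg$lfc_min),
      warning = function(w) { note(w); invokeRestart("muffleWarning") })
    for (r in dmp_res) {
      data.table::fwrite(r$fit, file.path(cfg$out_dir,
                                          sprintf("dmp_subset_%s.csv",
                                                  sub("%", "", r$label))))
    }
    cons <- consistency_scan(dmp_res)
    data.table::fwrite(cons, file.path(cfg$out_dir, "dmp_consistency.csv"))
    dmps_full <- dmp_res[[1]]$fit
    if (any(dmps_full$dmp)) {
      enr <- feature_enrichment(dmps_full$probe_id[dmps_full$dmp], ds$manifest)
      data.table::fwrite(enr, file.path(cfg$out_dir, "dmp_enrichment.csv"))
    }
  }

  if (cfg$stages[["dmr"]]) {
    dmr_res <- withCallingHandlers(
      run_dmr_analysis(ds, subsets, covariates = cfg$covariates,
                       max_gap_bp = cfg$max_gap_bp,
                       smooth_window = cfg$smooth_window,
                       cutoff_quantile = cfg$cutoff_quantile),
      warning = function(w) { note(w); invokeRestart("muffleWarning") })
    for (r in dmr_res) {
      tab <- r$regions
      tab$probes <- vapply(tab$probes, paste, "", collapse = ";")
      data.table::fwrite(tab, file.path(cfg$out_dir,
                                        sprintf("dmr_subset_%s.csv",
                                                sub("%", "", r$label))))
      if (nrow(tab)) {
        write_dmr_bed(r$regions, file.path(cfg$out_dir,
                                           sprintf("dmr_subset_%s.bed",
                                                   sub("%", "", r$label))))
      }
    }
    dmr_cons <- dmr_consistency_scan(dmr_res)
    data.table::fwrite(dmr_cons, file.path(cfg$out_dir, "dmr_consistency.csv"))
  }

  if (cfg$stages[["classify"]]) {
    ts <- withCallingHandlers(
      build_triplets(ds$samples, low_max = cfg$low_max, high_min = cfg$high_min),
      warning = function(w) { note(w); invokeRestart("muffleWarning") })
    report <- run_iterations(ds, ts, n_iter = cfg$n_iter,
                             base_seed = cfg$base_seed,
                             max_gap_bp = cfg$max_gap_bp,
                             smooth_window = cfg$smooth_window,
                             cutoff_quantile = cfg$cutoff_quantile)
    data.table::fwrite(as.data.frame(ts), file.path(cfg$out_dir, "triplets.csv"))
    data.table::fwrite(report$iterations, file.path(cfg$out_dir, "classifier_iterations.csv"))
    data.table::fwrite(report$ranking, file.path(cfg$out_dir, "classifier_ranking.csv"))
  }

  files <- list.files(cfg$out_dir, full.names = TRUE)
  files <- files[!grepl("run_manifest", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("epires")),
    config = unclass(cfg),
    checksums = as.list(tools::md5sum(files)),
    warnings = warnings_log)
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "run_manifest.yaml"))
  invisible(manifest)
}
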