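#' Percentile subsets of the tail-selected discovery groups
#'
#' Builds the nested sample subsets used to expose dose-response methylation
#' signal: for each retained fraction `q`, the subset keeps the top
#' `ceiling(q * n_high)` scorers of the high-resilience group and the bottom
#' `ceiling(q * n_low)` scorers of the low-resilience group, so distal
#' subsets compare increasingly extreme tails of the score distribution.
#' Ties in score are broken by sample id (stable), which makes the subsets
#' nested: the members at step q' are a subset of the members at any q > q'.
#'
#' @param samples sample sheet with `sample_id`, `cdrisc_score` and
#'   `resilience_group` columns (only "high"/"low" rows are used).
#' @param steps retained fractions, largest first. Default: the full groups
#'   plus 10 percentile steps down to 5%.
#' @param min_group_size subsets leaving fewer samples than this in either
#'   group are dropped with a warning.
#' @return list of `subset_spec` lists: `label` ("100%", ...), `q`,
#'   `low_ids`, `high_ids`, `summary` (per-group mean/SD/range of scores)
#'   and `score_gap` (high mean minus low mean).
#' @export
make_subsets <- function(samples,
                         steps = c(1, .9, .8, .7, .6, .5, .4, .3, .2, .1, .05),
                         min_group_size = 3) {
  stopifnot(all(c("sample_id", "cdrisc_score", "resilience_group") %in% names(samples)))
  lo <- samples[samples$resilience_group == "low", ]
  hi <- samples[samples$resilience_group == "high", ]
  if (!nrow(lo) || !nrow(hi)) stopf("both resilience groups must be non-empty")
  lo <- lo[order(lo$cdrisc_score, lo$sample_id), ]                 # lowest first
  hi <- hi[order(-hi$cdrisc_score, hi$sample_id), ]                # highest first

  out <- list()
  for (q in steps) {
    n_lo <- ceiling(q * nrow(lo))
    n_hi <- ceiling(q * nrow(hi))
    if (n_lo < min_group_size || n_hi < min_group_size) {
      warnf("subset %g%% leaves <%d samples in a group; dropped", 100 * q, min_group_size)
      next
    }
    lo_q <- lo[seq_len(n_lo), ]
    hi_q <- hi[seq_len(n_hi), ]
    summ <- function(x) c(n = length(x), mean = mean(x), sd = sd(x),
                          min = min(x), max = max(x))
    out[[length(out) + 1L]] <- structure(list(
      label = paste0(round(100 * q), "%"), q = q,
      low_ids = lo_q$sample_id, high_ids = hi_q$sample_id,
      summary = rbind(low = summ(lo_q$cdrisc_score),
                      high = summ(hi_q$cdrisc_score)),
      score_gap = mean(hi_q$cdrisc_score) - mean(lo_q$cdrisc_score)),
      class = "subset_spec")
  }
  out
}

# Build a full-rank design matrix for the group contrast plus covariates,
# dropping covariates that are constant (or collinear) within the subset.
build_design <- function(samples, covariates) {
  group_low <- as.numeric(samples$resilience_group == "low")
  df <- data.frame(group_low = group_low)
  dropped <- character()
  for (cv in covariates) {
    x <- samples[[cv]]
    if (is.null(x)) { dropped <- c(dropped, cv); next }
    if (length(unique(x[!is.na(x)])) < 2L) { dropped <- c(dropped, cv); next }
    df[[cv]] <- if (is.numeric(x)) x else factor(x)
  }
  X <- stats::model.matrix(~ ., df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    lost <- colnames(X)[-keep]
    dropped <- c(dropped, lost)
    X <- X[, keep, drop = FALSE]
  }
  if (length(dropped)) {
    warnf("covariates dropped (constant or collinear in this subset): %s",
          paste(unique(dropped), collapse = ", "))
  }
  list(X = X, dropped = unique(dropped))
}

#' Per-CpG covariate-adjusted linear model with moderated variance
#'
#' Fits, for every probe, an ordinary least-squares model of M values on the
#' resilience-group indicator plus covariates, then shrinks the residual
#' variances toward a common prior by empirical Bayes (method of moments on
#' the log variances), yielding a moderated t statistic with
#' `df = df_residual + d0`. The group coefficient is the "log2FC" on the M
#' scale; it is positive when a probe is hypermethylated in the
#' LOW-resilience group.
#'
#' @param ds a [methylation_dataset()] (or a subset of one); only samples
#'   with `resilience_group` in high/low enter the fit.
#' @param covariates sample-sheet columns to adjust for. Covariates constant
#'   within the data are dropped with a warning.
#' @param prior_df,prior_var optional overrides for the empirical-Bayes
#'   prior (`d0`, `s0^2`); `NULL` means estimate both from the data.
#'   `prior_df = Inf` with a supplied `prior_var` gives the limiting fully
#'   moderated statistic.
#' @return A `dmp_fit` object: data.frame with `probe_id`, `log2FC`, `t`,
#'   `p`, `q` (BH), `s2` (residual variance), `s2_tilde` (moderated), plus
#'   attributes `d0`, `s0_sq`, `df_residual`, `dropped_covariates`,
#'   `n_low`, `n_high`.
#' @export
fit_dmp_model <- function(ds, covariates = c("age", "menstrual",
                                             "detection_mode", "er"),
                          prior_df = NULL, prior_var = NULL) {
  stopifnot(inherits(ds, "methylation_dataset"))
  keep <- ds$samples$resilience_group %in% c("high", "low")
  ds2 <- subset_dataset(ds, samples = which(keep))
  if (length(unique(ds2$samples$resilience_group)) < 2L) {
    stopf("both resilience groups are required for the group contrast")
  }
  des <- build_design(ds2$samples, covariates)
  X <- des$X
  M <- get_m_values(ds2)
  n <- nrow(X); pX <- ncol(X)
  df_resid <- n - pX
  if (df_resid < 1) stopf("not enough samples for the design (df <= 0)")

  fit <- lm.fit(X, t(M))
  coefs <- fit$coefficients
  resid <- t(M) - X %*% coefs
  s2 <- colSums(resid^2) / df_resid
  s2 <- pmax(s2, 1e-12)

  # empirical Bayes on log variances (method of moments)
  if (is.null(prior_df) || is.null(prior_var)) {
    z <- log(s2)
    e <- z - digamma(df_resid / 2) + log(df_resid / 2)
    evar <- var(e) - trigamma(df_resid / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(mean(e))
    }
    if (!is.null(prior_df)) d0 <- prior_df
    if (!is.null(prior_var)) s0_sq <- prior_var
  } else {
    d0 <- prior_df
    s0_sq <- prior_var
  }
  s2_tilde <- if (is.finite(d0)) (d0 * s0_sq + df_resid * s2) / (d0 + df_resid) else rep(s0_sq, length(s2))

  xtxi <- chol2inv(chol(crossprod(X)))
  gcol <- match("group_low", colnames(X))
  se_unscaled <- sqrt(xtxi[gcol, gcol])
  lfc <- coefs[gcol, ]
  tstat <- lfc / (sqrt(s2_tilde) * se_unscaled)
  df_total <- df_resid + d0
  p <- 2 * pt(-abs(tstat), df = df_total)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  res <- data.frame(probe_id = rownames(ds2$beta),
                    log2FC = as.numeric(lfc), t = as.numeric(tstat),
                    p = as.numeric(p), q = p.adjust(p, "BH"),
                    s2 = as.numeric(s2), s2_tilde = as.numeric(s2_tilde),
                    stringsAsFactors = FALSE)
  structure(res, class = c("dmp_fit", "data.frame"),
            d0 = d0, s0_sq = s0_sq, df_residual = df_resid,
            dropped_covariates = des$dropped,
            n_low = sum(ds2$samples$resilience_group == "low"),
            n_high = sum(ds2$samples$resilience_group == "high"),
            sign_convention = "log2FC > 0: hypermethylated in the low-resilience group")
}

#' Call differentially methylated probes
#'
#' A probe is a DMP iff its raw p value is below `p_max` AND its absolute
#' M-scale log2 fold change exceeds `lfc_min` (|log2FC| > 0.5 corresponds to
#' roughly a 10-15% beta-value difference at intermediate methylation).
#' BH-adjusted q values are carried along for reporting but do not enter the
#' call.
#'
#' @param fits a `dmp_fit` from [fit_dmp_model()].
#' @param p_max raw p threshold.
#' @param lfc_min absolute log2FC threshold (strict).
#' @return the fit data.frame with added `dmp` (logical) and `direction`
#'   ("hyper"/"hypo" in the low-resilience group).
#' @export
call_dmps <- function(fits, p_max = 0.05, lfc_min = 0.5) {
  fits$dmp <- fits$p < p_max & abs(fits$log2FC) > lfc_min
  fits$direction <- ifelse(fits$log2FC > 0, "hyper", "hypo")
  fits
}

#' Run the subset-wise DMP analysis
#'
#' Fits the moderated per-CpG model and calls DMPs in the full discovery set
#' and every percentile subset, the substrate for [consistency_scan()].
#'
#' @param ds a QC-filtered [methylation_dataset()].
#' @param subsets list of subset specs from [make_subsets()].
#' @param covariates,p_max,lfc_min passed to [fit_dmp_model()] / [call_dmps()].
#' @return list of per-subset results: `label`, `q`, `score_gap`, `fit`
#'   (called DMP table).
#' @export
run_dmp_analysis <- function(ds, subsets,
                             covariates = c("age", "menstrual",
                                            "detection_mode", "er"),
                             p_max = 0.05, lfc_min = 0.5) {
  lapply(subsets, function(sp) {
    sub <- subset_dataset(ds, samples = c(sp$low_ids, sp$high_ids))
    fit <- fit_dmp_model(sub, covariates = covariates)
    list(label = sp$label, q = sp$q, score_gap = sp$score_gap,
         n_low = length(sp$low_ids), n_high = length(sp$high_ids),
         fit = call_dmps(fit, p_max = p_max, lfc_min = lfc_min))
  })
}

#' Cross-subset DMP consistency and dose-response scan
#'
#' For every probe, counts in how many subset analyses it was called a DMP,
#' the longest consecutive run over the ordered subset sequence (full set
#' toward the most distal subset), and a dose-response statistic: the
#' Spearman correlation between the probe's per-subset log2FC and the
#' per-subset difference in group mean CD-RISC scores. Probes whose effect
#' grows as the compared groups move toward the score tails score near +1
#' (hyper) or -1 (hypo).
#'
#' @param subset_results output of [run_dmp_analysis()], ordered from the
#'   full set to the most distal subset.
#' @return data.frame `probe_id`, `n_hits`, `max_run`, `dose_response_stat`,
#'   plus one logical hit column per subset label.
#' @export
consistency_scan <- function(subset_results) {
  if (length(subset_results) < 2L) stopf("need at least 2 subset analyses")
  labels <- vapply(subset_results, `[[`, "", "label")
  probes <- subset_results[[1]]$fit$probe_id
  hit <- vapply(subset_results, function(r) {
    r$fit$dmp[match(probes, r$fit$probe_id)]
  }, logical(length(probes)))
  lfc <- vapply(subset_results, function(r) {
    r$fit$log2FC[match(probes, r$fit$probe_id)]
  }, numeric(length(probes)))
  if (!is.matrix(hit)) hit <- matrix(hit, nrow = 1)
  if (!is.matrix(lfc)) lfc <- matrix(lfc, nrow = 1)
  gaps <- vapply(subset_results, `[[`, 0, "score_gap")
  hit[is.na(hit)] <- FALSE

  n_hits <- rowSums(hit)
  max_run <- apply(hit, 1, max_run)
  drs <- apply(lfc, 1, function(l) spearman_safe(l, gaps))

  out <- data.frame(probe_id = probes, n_hits = as.integer(n_hits),
                    max_run = as.integer(max_run), dose_response_stat = drs,
                    stringsAsFactors = FALSE)
  colnames(hit) <- paste0("hit_", labels)
  cbind(out, as.data.frame(hit))
}

#' Genomic feature-class enrichment of DMPs
#'
#' Per feature class, compares the proportion of DMPs in the class with the
#' proportion among background probes (all QC-passing probes) by a
#' two-proportion test, flagging over- and under-representation.
#'
#' @param dmp_ids probe ids called as DMPs.
#' @param manifest probe manifest of the background (QC-passing) probes,
#'   with `probe_id` and `feature_class`.
#' @param alpha significance level for the enrichment flag.
#' @return data.frame `feature_class`, `n_dmp`, `n_background`, `prop_dmp`,
#'   `prop_background`, `p`, `status` (enriched/depleted/ns).
#' @export
feature_enrichment <- function(dmp_ids, manifest, alpha = 0.05) {
  if (!length(dmp_ids)) stopf("empty DMP set")
  is_dmp <- manifest$probe_id %in% dmp_ids
  n_dmp <- sum(is_dmp)
  n_bg <- nrow(manifest)
  out <- lapply(sort(unique(manifest$feature_class)), function(fc) {
    in_fc <- manifest$feature_class == fc
    x_dmp <- sum(is_dmp & in_fc)
    x_bg <- sum(in_fc)
    p <- tryCatch(
      stats::prop.test(c(x_dmp, x_bg), c(n_dmp, n_bg))$p.value,
      warning = function(w) suppressWarnings(
        stats::prop.test(c(x_dmp, x_bg), c(n_dmp, n_bg))$p.value))
    prop_d <- x_dmp / n_dmp
    prop_b <- x_bg / n_bg
    data.frame(feature_class = fc, n_dmp = x_dmp, n_background = x_bg,
               prop_dmp = prop_d, prop_background = prop_b, p = p,
               status = if (is.na(p) || p >= alpha) "ns"
                        else if (prop_d > prop_b) "enriched" else "depleted",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
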