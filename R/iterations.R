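# feature matrix (samples x CpGs on the M scale, optional age column)
feature_matrix <- function(ds, sample_ids, cpgs, include_age = FALSE) {
  sub <- subset_dataset(ds, probes = cpgs, samples = sample_ids)
  x <- as.data.frame(t(get_m_values(sub)))
  colnames(x) <- cpgs
  if (include_age) x$age <- sub$samples$age
  x
}

# labels + triplet membership for a set of samples under a triplet set
triplet_labels <- function(ts, sample_ids) {
  long <- data.frame(
    sample_id = c(ts$low_id, ts$high_id1, ts$high_id2),
    label = rep(c("low", "high", "high"), each = nrow(ts)),
    triplet_id = rep(ts$triplet_id, 3),
    stringsAsFactors = FALSE)
  long[match(sample_ids, long$sample_id), ]
}

#' Resampling feature selection and classification over many triplet splits
#'
#' The core resampling loop: in each iteration the triplet set is randomly
#' split into training (50%), confirmation (20%) and test (30%) partitions
#' (whole triplets), CpGs are selected from training-set DMRs of at least
#' `min_probes` probes and filtered for fold-change direction agreement in
#' the confirmation set, a random forest is tuned on the training +
#' confirmation samples by nested cross-validation maximizing Youden's J,
#' and the tuned model is assessed on the held-out test partition. CpGs are
#' then ranked by how often they were selected across iterations.
#'
#' Iterations with fewer than 2 selected CpGs are recorded as degenerate and
#' excluded from metric summaries. Everything is reproducible from
#' `base_seed`: iteration i uses seed `base_seed + i`.
#'
#' @param ds the classifier-set [methylation_dataset()].
#' @param ts a [build_triplets()] triplet set consistent with `ds`.
#' @param n_iter number of split-select-tune-test iterations.
#' @param base_seed seed anchoring the whole run.
#' @param min_probes minimum DMR span for feature selection.
#' @param k,m folds/repeats of the inner cross-validation.
#' @param grid hyperparameter grid; default [rf_grid_small()] (the full
#'   [rf_grid()] is impractical over hundreds of iterations).
#' @param covariates covariates of the per-probe model in feature selection.
#' @param ... bump-finding parameters for [find_bumps()].
#' @return A `classifier_report`: list with `iterations` (data.frame:
#'   iteration, seed, n_features, auc, sensitivity, specificity, threshold,
#'   degenerate), `ranking` (data.frame: probe_id, count, rank),
#'   `selected` (list of per-iteration CpG vectors), `summary`
#'   (mean AUC/SN/SP over non-degenerate iterations).
#' @export
run_iterations <- function(ds, ts, n_iter = 500, base_seed = 42,
                           min_probes = 5, k = 5, m = 3, grid = NULL,
                           covariates = character(), ...) {
  stopifnot(inherits(ts, "triplet_set"))
  missing <- setdiff(triplet_samples(ts), colnames(ds$beta))
  if (length(missing)) stopf("triplet samples absent from dataset: %s",
                             paste(head(missing, 3), collapse = ", "))
  iters <- list()
  selected <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    seed_i <- base_seed + i
    parts <- split_triplets(ts, seed = seed_i)
    train_ids <- triplet_samples(parts$train)
    confirm_ids <- triplet_samples(parts$confirm)
    test_ids <- triplet_samples(parts$test)
    stopifnot(!anyDuplicated(c(train_ids, confirm_ids, test_ids)))

    cpgs <- select_features(ds, train_ids, confirm_ids,
                            min_probes = min_probes,
                            covariates = covariates, ...)
    selected[[i]] <- cpgs
    if (length(cpgs) < 2) {
      iters[[i]] <- data.frame(iteration = i, seed = seed_i,
                               n_features = length(cpgs), auc = NA_real_,
                               sensitivity = NA_real_, specificity = NA_real_,
                               threshold = NA_real_, degenerate = TRUE)
      next
    }
    fit_ids <- c(train_ids, confirm_ids)
    lab <- triplet_labels(rbind(parts$train, parts$confirm), fit_ids)
    x <- feature_matrix(ds, fit_ids, cpgs)
    tuned <- tune_and_fit_rf(x, lab$label, lab$triplet_id, k = k, m = m,
                             grid = grid %||% rf_grid_small(length(cpgs)),
                             seed = seed_i)

    lab_te <- triplet_labels(parts$test, test_ids)
    x_te <- feature_matrix(ds, test_ids, cpgs)
    pr <- predict_prob(tuned$model, x_te)
    pred_pos <- pr >= tuned$threshold
    is_pos <- lab_te$label == "low"
    iters[[i]] <- data.frame(
      iteration = i, seed = seed_i, n_features = length(cpgs),
      auc = auc_rank(pr, lab_te$label),
      sensitivity = sum(pred_pos & is_pos) / sum(is_pos),
      specificity = sum(!pred_pos & !is_pos) / sum(!is_pos),
      threshold = tuned$threshold, degenerate = FALSE)
  }
  iterations <- do.call(rbind, iters)

  counts <- table(unlist(selected))
  ranking <- if (length(counts)) {
    rk <- data.frame(probe_id = names(counts), count = as.integer(counts),
                     stringsAsFactors = FALSE)
    rk <- rk[order(-rk$count, rk$probe_id), ]
    rk$rank <- seq_len(nrow(rk))
    rownames(rk) <- NULL
    rk
  } else {
    data.frame(probe_id = character(), count = integer(), rank = integer())
  }
  ok <- !iterations$degenerate
  structure(list(
    iterations = iterations, ranking = ranking, selected = selected,
    summary = c(n_iter = n_iter, n_degenerate = sum(!ok),
                mean_auc = mean(iterations$auc[ok]),
                mean_sensitivity = mean(iterations$sensitivity[ok]),
                mean_specificity = mean(iterations$specificity[ok]))),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("classifier_report: %d iterations (%d degenerate)\n",
              s[["n_iter"]], s[["n_degenerate"]]))
  cat(sprintf("  mean test AUC %.3f, SN %.3f, SP %.3f\n",
              s[["mean_auc"]], s[["mean_sensitivity"]], s[["mean_specificity"]]))
  cat(sprintf("  %d distinct CpGs selected; top: %s\n", nrow(x$ranking),
              paste(head(x$ranking$probe_id, 3), collapse = ", ")))
  invisible(x)
}

#' Final model selection and independent validation
#'
#' Scans `n_top_grid`: for each candidate size, tunes a random forest on the
#' entire classifier set using the top-ranked CpGs plus age as features
#' (nested CV, k folds, m repeats, Youden-J threshold tuning), and selects
#' the size maximizing the cross-validated AUC (largest size on ties). The
#' winning model is then evaluated once on the independent validation set
#' at its tuned threshold.
#'
#' @param ranking the CpG frequency ranking from [run_iterations()].
#' @param ds_classifier classifier-set dataset (used for final tuning).
#' @param ts classifier-set triplets (fold structure for the final tuning).
#' @param ds_validation independent validation dataset; its sample sheet
#'   must carry `cdrisc_score` (labels derive from the triplet thresholds).
#'   Must not share samples with the classifier set.
#' @param n_top_grid candidate numbers of top CpGs.
#' @param k,m,grid,seed tuning controls as in [tune_and_fit_rf()].
#' @return list: `final_model` (list: features, config, threshold, cv_auc,
#'   n_top), `scan` (data.frame n_top vs cv_auc), `validation` (list: auc,
#'   sensitivity, specificity, J, n, roc (data.frame threshold/sn/sp)).
#' @export
finalize_and_validate <- function(ranking, ds_classifier, ts, ds_validation,
                                  n_top_grid = c(2, 4, 6, 8, 10), k = 5,
                                  m = 3, grid = NULL, seed = 42) {
  if (!nrow(ranking)) stopf("empty CpG ranking")
  overlap <- intersect(colnames(ds_classifier$beta), colnames(ds_validation$beta))
  if (length(overlap)) stopf("validation samples overlap the classifier set: %s",
                             paste(head(overlap, 3), collapse = ", "))

  ids <- triplet_samples(ts)
  lab <- triplet_labels(ts, ids)
  n_top_grid <- n_top_grid[n_top_grid <= nrow(ranking)]
  if (!length(n_top_grid)) stopf("n_top_grid exceeds the ranking size")

  scan <- list()
  tuned_by_n <- list()
  for (nt in n_top_grid) {
    cpgs <- ranking$probe_id[seq_len(nt)]
    x <- feature_matrix(ds_classifier, ids, cpgs, include_age = TRUE)
    tuned <- tune_and_fit_rf(x, lab$label, lab$triplet_id, k = k, m = m,
                             grid = grid %||% rf_grid_small(ncol(x)),
                             seed = seed + nt)
    tuned_by_n[[as.character(nt)]] <- tuned
    scan[[length(scan) + 1L]] <- data.frame(n_top = nt, cv_auc = tuned$cv_auc,
                                            cv_J = tuned$cv_J)
  }
  scan <- do.call(rbind, scan)
  # ties on CV AUC break toward the larger model: with near-separable
  # training data many sizes tie at 1 and the larger CpG panel is the more
  # robust operating choice
  best_n <- max(scan$n_top[scan$cv_auc == max(scan$cv_auc)])
  tuned <- tuned_by_n[[as.character(best_n)]]
  cpgs <- ranking$probe_id[seq_len(best_n)]

  # single validation pass at the tuned threshold
  v_lab <- ifelse(ds_validation$samples$cdrisc_score <= attr(ts, "low_max"),
                  "low",
                  ifelse(ds_validation$samples$cdrisc_score >= attr(ts, "high_min"),
                         "high", NA))
  keep <- !is.na(v_lab)
  x_val <- feature_matrix(ds_validation, ds_validation$samples$sample_id[keep],
                          cpgs, include_age = TRUE)
  pr <- predict_prob(tuned$model, x_val)
  y <- v_lab[keep]
  pred_pos <- pr >= tuned$threshold
  is_pos <- y == "low"
  sn <- sum(pred_pos & is_pos) / sum(is_pos)
  sp <- sum(!pred_pos & !is_pos) / sum(!is_pos)

  roc <- do.call(rbind, lapply(sort(unique(c(0, pr, 1))), function(t) {
    data.frame(threshold = t,
               sensitivity = sum(pr >= t & is_pos) / sum(is_pos),
               specificity = sum(pr < t & !is_pos) / sum(!is_pos))
  }))

  list(final_model = list(features = c(cpgs, "age"), n_top = best_n,
                          config = tuned$config, threshold = tuned$threshold,
                          cv_auc = tuned$cv_auc, seed = seed, model = tuned$model),
       scan = scan,
       validation = list(auc = auc_rank(pr, y), sensitivity = sn,
                         specificity = sp, J = sn + sp - 1,
                         n = length(y), roc = roc))
}
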