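#' Youden-optimal classification threshold
#'
#' Exhaustive scan over the observed predicted probabilities: for every
#' candidate threshold t (predict positive when prob >= t), computes
#' sensitivity, specificity and Youden's J = SN + SP - 1, and returns the
#' threshold maximizing J (smallest such threshold on ties). Robust to the
#' 1:2 class imbalance of the triplet design, which is why J rather than
#' accuracy drives the tuning.
#'
#' @param probs predicted probabilities of the positive class.
#' @param labels true class labels.
#' @param positive label of the positive class (default "low").
#' @return list: `threshold`, `J`, `sensitivity`, `specificity`. The
#'   returned threshold is placed at the midpoint of the gap below the
#'   J-optimal observed probability (the decision boundary is centered
#'   between the classes), which classifies identically to the optimal
#'   observed cut on the given data but transfers better to new samples.
#' @export
youden_threshold <- function(probs, labels, positive = "low") {
  is_pos <- labels == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) stopf("both classes required to tune a threshold")
  cand <- sort(unique(probs))
  best <- list(idx = 1L, J = -Inf, sensitivity = NA, specificity = NA)
  for (i in seq_along(cand)) {
    pred_pos <- probs >= cand[i]
    sn <- sum(pred_pos & is_pos) / n_pos
    sp <- sum(!pred_pos & !is_pos) / n_neg
    j <- sn + sp - 1
    if (j > best$J) best <- list(idx = i, J = j, sensitivity = sn, specificity = sp)
  }
  thr <- if (best$idx == 1L) cand[1] else mean(cand[(best$idx - 1):best$idx])
  list(threshold = thr, J = best$J,
       sensitivity = best$sensitivity, specificity = best$specificity)
}

#' Area under the ROC curve by the rank-sum method
#'
#' Equivalent to the trapezoidal ROC area: the Mann-Whitney probability that
#' a random positive outranks a random negative, with ties counted 1/2.
#'
#' @inheritParams youden_threshold
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(probs, labels, positive = "low") {
  is_pos <- labels == positive
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probs)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Random-forest hyperparameter grids
#'
#' `rf_grid()` is the documented default grid: mtry in
#' \{floor(sqrt(p)), floor(p/3), p\}, 250/500/1000 trees, minimum node size
#' 1/5/10, maximum depth unlimited/4/8, split rule gini and hellinger.
#' `rf_grid_small()` is the reduced grid used for large iteration counts:
#' mtry in \{floor(sqrt(p)), floor(p/3)\}, 250 trees, node size 1/5,
#' unlimited depth, gini.
#'
#' @param p number of features.
#' @return data.frame with columns `mtry`, `num_trees`, `min_node`,
#'   `max_depth` (0 = unlimited), `splitrule`.
#' @export
rf_grid <- function(p) {
  unique(expand.grid(
    mtry = unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3), p))),
    num_trees = c(250L, 500L, 1000L),
    min_node = c(1L, 5L, 10L),
    max_depth = c(0L, 4L, 8L),
    splitrule = c("gini", "hellinger"),
    stringsAsFactors = FALSE))
}

#' @rdname rf_grid
#' @export
rf_grid_small <- function(p) {
  unique(expand.grid(
    mtry = unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3)))),
    num_trees = 250L,
    min_node = c(1L, 5L),
    max_depth = 0L,
    splitrule = "gini",
    stringsAsFactors = FALSE))
}

fit_ranger <- function(x, y, cfg, seed) {
  ranger::ranger(x = x, y = y, probability = TRUE,
                 num.trees = cfg$num_trees, mtry = min(cfg$mtry, ncol(x)),
                 min.node.size = cfg$min_node, max.depth = cfg$max_depth,
                 splitrule = cfg$splitrule,
                 seed = seed, num.threads = 1)
}

predict_prob <- function(model, x, positive = "low") {
  pr <- predict(model, data = x, num.threads = 1)$predictions
  pr[, positive]
}

# fold assignment at the triplet level: every fold keeps whole triplets (and
# therefore both classes, 1:2)
triplet_folds <- function(triplet_id, k) {
  ids <- unique(triplet_id)
  if (length(ids) < k) stopf("fewer triplets (%d) than folds (%d)", length(ids), k)
  fold_of <- setNames(rep(seq_len(k), length.out = length(ids)), sample(ids))
  unname(fold_of[as.character(triplet_id)])
}

#' Tune and fit a random-forest classifier by nested CV and Youden's J
#'
#' Grid search over random-forest hyperparameters with m repeats of
#' stratified k-fold cross-validation. Folds are drawn at the triplet level
#' so matched units never straddle a fold and the 1:2 class ratio is
#' preserved. Within each held-out fold, the classification threshold is
#' chosen by exhaustive Youden scan over the fold's predicted probabilities;
#' a configuration's score is its mean out-of-fold J. The winning
#' configuration is refit on all samples and its operating threshold is the
#' Youden-optimal threshold of the pooled out-of-fold predictions.
#'
#' @param x feature matrix/data.frame (samples x features, >= 2 features).
#' @param y class labels ("low"/"high").
#' @param triplet_id triplet membership per sample (drives fold assignment).
#' @param k,m folds and repeats of the cross-validation.
#' @param grid hyperparameter grid (default [rf_grid()] on `ncol(x)`).
#' @param seed RNG seed governing fold assignment and forest seeds.
#' @param positive positive class label.
#' @return list: `model` (ranger fit on all data), `threshold`, `config`
#'   (winning row), `cv_J`, `cv_auc` (mean out-of-fold J and AUC of the
#'   winner), `cv_table` (per-config mean J and AUC).
#' @export
tune_and_fit_rf <- function(x, y, triplet_id, k = 5, m = 3, grid = NULL,
                            seed = 1, positive = "low") {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stopf("need at least 2 features")
  y <- factor(y, levels = c("high", "low"))
  if (nlevels(droplevels(y)) < 2) stopf("both classes required")
  if (is.null(grid)) grid <- rf_grid(ncol(x))

  folds <- with_seed(seed, lapply(seq_len(m), function(r) triplet_folds(triplet_id, k)))

  cv <- lapply(seq_len(nrow(grid)), function(gi) {
    cfg <- grid[gi, ]
    js <- c(); aucs <- c()
    oof_prob <- rep(NA_real_, length(y) * m)
    for (r in seq_len(m)) {
      fl <- folds[[r]]
      for (f in seq_len(k)) {
        tr <- fl != f
        model <- fit_ranger(x[tr, , drop = FALSE], y[tr], cfg,
                            seed = seed * 1000L + r * 100L + f)
        pr <- predict_prob(model, x[!tr, , drop = FALSE], positive)
        th <- youden_threshold(pr, y[!tr], positive)
        js <- c(js, th$J)
        aucs <- c(aucs, auc_rank(pr, y[!tr], positive))
        oof_prob[(r - 1L) * length(y) + which(!tr)] <- pr
      }
    }
    list(mean_J = mean(js), mean_auc = mean(aucs, na.rm = TRUE), oof = oof_prob)
  })
  mean_J <- vapply(cv, `[[`, 0, "mean_J")
  mean_auc <- vapply(cv, `[[`, 0, "mean_auc")
  best <- which.max(mean_J)

  # threshold from the winner's out-of-fold predictions pooled over all
  # repeats, then refit on everything
  oof <- cv[[best]]$oof
  th <- youden_threshold(oof, rep(as.character(y), m), positive)
  model <- fit_ranger(x, y, grid[best, ], seed = seed * 1000L + 1L)

  cv_table <- cbind(grid, mean_J = mean_J, mean_auc = mean_auc)
  list(model = model, threshold = th$threshold, config = grid[best, ],
       cv_J = mean_J[best], cv_auc = mean_auc[best], cv_table = cv_table)
}

#' Select candidate CpGs from training-set DMRs with confirmation filtering
#'
#' Runs bump hunting on the training samples (group contrast on M values),
#' keeps CpGs inside candidate regions spanning at least `min_probes`
#' probes, then retains only CpGs whose group fold-change direction agrees
#' between the training and confirmation samples.
#'
#' @param ds the classifier-set [methylation_dataset()].
#' @param train_ids,confirm_ids sample ids of the training and confirmation
#'   partitions.
#' @param min_probes minimum DMR span (probes) for a region to contribute.
#' @param covariates covariates for the per-probe model (default none: the
#'   triplet matching already balances them).
#' @param ... bump-finding parameters for [find_bumps()].
#' @return character vector of selected CpG ids (possibly empty).
#' @export
select_features <- function(ds, train_ids, confirm_ids, min_probes = 5,
                            covariates = character(), ...) {
  train <- subset_dataset(ds, samples = train_ids)
  fit_tr <- suppressWarnings(fit_dmp_model(train, covariates = covariates))
  bumps <- find_bumps(fit_tr, train$manifest, ...)
  bumps <- bumps[bumps$n_probes >= min_probes, , drop = FALSE]
  if (!nrow(bumps)) return(character())
  cpgs <- unique(unlist(bumps$probes))

  confirm <- subset_dataset(ds, samples = confirm_ids)
  fit_cf <- suppressWarnings(fit_dmp_model(confirm, covariates = covariates))
  lfc_tr <- fit_tr$log2FC[match(cpgs, fit_tr$probe_id)]
  lfc_cf <- fit_cf$log2FC[match(cpgs, fit_cf$probe_id)]
  keep <- !is.na(lfc_cf) & sign(lfc_tr) == sign(lfc_cf) & lfc_tr != 0
  sort(cpgs[keep])
}
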