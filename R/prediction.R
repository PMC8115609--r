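#' Near-zero-variance feature filter
#'
#' Removes features that are zero-variance, or whose frequency ratio of the
#' two most common values exceeds `freq_cut` while the percentage of unique
#' values is at most `unique_cut` — the conventional near-zero-variance
#' screen applied to maternal abundance features before model training.
#'
#' @param x samples x features numeric matrix.
#' @param freq_cut frequency-ratio cutoff (default 95/5).
#' @param unique_cut percent-unique cutoff (default 10).
#' @return character vector of retained feature names.
#' @export
near_zero_variance_filter <- function(x, freq_cut = 95 / 5,
                                      unique_cut = 10) {
  keep <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) == 1L) return(FALSE)          # zero variance
    freq_ratio <- tab[1L] / tab[2L]
    pct_unique <- 100 * length(tab) / length(v)
    !(freq_ratio > freq_cut && pct_unique <= unique_cut)
  }, logical(1))
  if (!any(keep)) stop("all features removed by near-zero-variance filter")
  colnames(x)[keep]
}

#' Pairwise-correlation feature filter
#'
#' Greedy removal of highly correlated features: repeatedly find the
#' remaining pair with the largest absolute Pearson correlation above
#' `cutoff` and drop the member with the larger mean absolute correlation
#' to all remaining features (ties drop the lexicographically later name).
#'
#' @param x samples x features numeric matrix (>= 2 features).
#' @param cutoff absolute correlation threshold (default 0.90).
#' @return character vector of retained feature names.
#' @export
correlation_filter <- function(x, cutoff = 0.90) {
  if (ncol(x) < 2L) return(colnames(x))
  cm <- suppressWarnings(abs(stats::cor(x)))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  keep <- colnames(x)
  repeat {
    sub <- cm[keep, keep, drop = FALSE]
    if (max(sub) <= cutoff) break
    ij <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    a <- keep[ij[1L]]; b <- keep[ij[2L]]
    mean_a <- mean(sub[a, setdiff(keep, a)])
    mean_b <- mean(sub[b, setdiff(keep, b)])
    drop <- if (mean_a > mean_b) a
            else if (mean_b > mean_a) b
            else max(a, b)                         # lexicographically later
    keep <- setdiff(keep, drop)
    if (length(keep) == 1L) break
  }
  keep
}

#' Rank-based AUC
#'
#' Mann-Whitney AUC of scores against binary labels, counting ties as one
#' half.
#'
#' @param scores numeric prediction scores.
#' @param labels logical (or 0/1) class labels; both classes must occur.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) for single-class
#'   labels.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: single-class labels")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Build leave-one-study-out prediction tasks
#'
#' Assembles, per dyad, the maternal delivery-window species profile as the
#' feature vector and a binary label per target: whether the target species
#' (from sharing records) or target strain (from transmission calls) occurs
#' shared in the infant at any timepoint. Only *admissible* targets are
#' kept: both label classes must occur within every study, the condition
#' for leave-one-study-out evaluation.
#'
#' @param maternal_table species table containing the maternal samples.
#' @param pairing output of [pair_dyads()].
#' @param label_source a `sharing_records` (species targets, feature ids
#'   are reduced to their `s__` token) or `transmission_calls` (strain
#'   targets).
#' @param metadata sample metadata (study and delivery mode per dyad).
#' @param targets candidate target keys (default: every admissible one).
#' @return `prediction_task` list: `features` (dyads x species matrix),
#'   `labels` (dyads x targets logical), `study`, `delivery_mode` (named
#'   vectors), `targets`.
#' @export
prediction_tasks <- function(maternal_table, pairing, label_source,
                             metadata, targets = NULL) {
  vals <- tab_values(maternal_table)
  dyads <- unique(pairing$dyad_id)
  mom <- tapply(pairing$mother_sample, pairing$dyad_id, function(x) x[1L])
  mom <- mom[dyads]
  feats <- t(vals[, unname(mom), drop = FALSE])
  rownames(feats) <- dyads
  if (inherits(maternal_table, "abund_table") &&
      maternal_table$feature_kind == "taxon")
    colnames(feats) <- species_key(colnames(feats))
  if (inherits(label_source, "sharing_records")) {
    lab_df <- unique(label_source$features[c("dyad_id", "feature_id")])
    lab_df$key <- species_key(lab_df$feature_id)
  } else if (inherits(label_source, "transmission_calls")) {
    sh <- label_source[!is.na(label_source$shared) & label_source$shared, ]
    lab_df <- unique(data.frame(dyad_id = sh$dyad_id, key = sh$species,
                                stringsAsFactors = FALSE))
  } else stop("label_source must be sharing records or transmission calls")
  keys <- if (is.null(targets)) sort(unique(lab_df$key)) else targets
  labels <- matrix(FALSE, length(dyads), length(keys),
                   dimnames = list(dyads, keys))
  hit <- lab_df[lab_df$key %in% keys, ]
  labels[cbind(hit$dyad_id, hit$key)] <- TRUE
  study <- stats::setNames(
    metadata$study_id[match(dyads, metadata$dyad_id)], dyads)
  dm <- if ("delivery_mode" %in% names(metadata))
    stats::setNames(metadata$delivery_mode[match(dyads, metadata$dyad_id)],
                    dyads) else NULL
  admissible <- vapply(keys, function(k) {
    all(vapply(split(labels[, k], study),
               function(l) any(l) && !all(l), logical(1)))
  }, logical(1))
  if (!is.null(targets) && any(!admissible))
    message(sum(!admissible), " target(s) dropped: a study lacks one of ",
            "the label classes")
  structure(list(features = feats, labels = labels[, admissible,
                                                   drop = FALSE],
                 study = study, delivery_mode = dm,
                 targets = keys[admissible]),
            class = "prediction_task")
}

# Fit one model and return test-fold scores. Filtering (near-zero-variance
# then correlation) is computed on the training rows only unless
# `pooled_filter`.
fit_and_score <- function(feats, labels, train, test, model, seed,
                          ntree, do_filter, pooled_filter) {
  cols <- colnames(feats)
  if (do_filter) {
    base <- if (pooled_filter) feats else feats[train, , drop = FALSE]
    cols <- tryCatch(near_zero_variance_filter(base),
                     error = function(e) colnames(feats))
    if (length(cols) > 1L)
      cols <- correlation_filter(base[, cols, drop = FALSE])
  }
  xtr <- feats[train, cols, drop = FALSE]
  xte <- feats[test, cols, drop = FALSE]
  set.seed(seed)
  if (model == "rf") {
    fit <- randomForest::randomForest(
      x = xtr, y = factor(labels[train], levels = c(FALSE, TRUE)),
      ntree = ntree)
    scores <- stats::predict(fit, xte, type = "prob")[, "TRUE"]
    imp <- fit$importance[, "MeanDecreaseGini"]
  } else if (model == "gbm") {
    dtr <- xgboost::xgb.DMatrix(xtr, label = as.numeric(labels[train]),
                                nthread = 1)
    # minimum terminal-node size of 5 observations: the logistic hessian
    # contributes at most 0.25 per observation, so 5 obs ~ 1.25 weight
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 1,
                    eta = 0.1, min_child_weight = 1.25, subsample = 0.5,
                    nthread = 1),
      data = dtr, nrounds = 100, verbose = 0)
    scores <- stats::predict(fit, xgboost::xgb.DMatrix(xte, nthread = 1))
    imp <- NULL
  } else stop("unknown model")
  list(scores = scores, importance = imp, features_used = cols)
}

#' Leave-one-study-out model evaluation
#'
#' For every admissible target and every held-out study, trains a
#' classifier of shared/not-shared on the pooled dyads of the remaining
#' studies and computes the AUC on the held-out study; repeated over
#' `seeds` and reported per repetition. Models: `"rf"` (random forest,
#' 1000 trees, default `mtry`) or `"gbm"` (stochastic gradient-boosted
#' stumps: depth 1, 100 trees, shrinkage 0.1, minimum node size 5, bag
#' fraction 0.5). Feature filters run on the training fold only unless
#' `pooled_filter = TRUE`.
#'
#' @param task `prediction_task`.
#' @param model `"rf"` or `"gbm"`.
#' @param seeds integer vector of training seeds (results are averaged by
#'   the caller; each row carries its seed).
#' @param ntree random-forest tree count (default 1000).
#' @param do_filter apply the near-zero-variance + correlation filters.
#' @param pooled_filter compute the filters on all dyads (reproduces the
#'   pooled pre-processing route) instead of per training fold.
#' @return list of class `loso_result`: `results` data.frame (`target`,
#'   `held_out_study`, `model`, `seed`, `auc`, `n_train`, `n_test`) and
#'   `importance` (nested list target -> study -> mean-decrease-Gini
#'   vector, averaged over seeds; rf only).
#' @export
loso_evaluate <- function(task, model = c("rf", "gbm"), seeds = 1:5,
                          ntree = 1000, do_filter = TRUE,
                          pooled_filter = FALSE) {
  model <- match.arg(model)
  studies <- sort(unique(task$study))
  if (length(studies) < 2L) stop("need at least two studies")
  rows <- list()
  importance <- list()
  for (tg in task$targets) {
    lab <- task$labels[, tg]
    importance[[tg]] <- list()
    for (ho in studies) {
      test <- task$study == ho
      train <- !test
      imp_acc <- NULL
      for (sd in seeds) {
        if (length(unique(lab[test])) < 2L ||
            length(unique(lab[train])) < 2L) {
          rows[[length(rows) + 1L]] <- data.frame(
            target = tg, held_out_study = ho, model = model, seed = sd,
            auc = NA_real_, n_train = sum(train), n_test = sum(test),
            stringsAsFactors = FALSE)
          next
        }
        fs <- fit_and_score(task$features, lab, train, test, model, sd,
                            ntree, do_filter, pooled_filter)
        rows[[length(rows) + 1L]] <- data.frame(
          target = tg, held_out_study = ho, model = model, seed = sd,
          auc = auc_score(fs$scores, lab[test]),
          n_train = sum(train), n_test = sum(test),
          stringsAsFactors = FALSE)
        if (!is.null(fs$importance)) {
          if (is.null(imp_acc)) imp_acc <- fs$importance
          else {
            common <- union(names(imp_acc), names(fs$importance))
            a <- stats::setNames(numeric(length(common)), common)
            a[names(imp_acc)] <- imp_acc
            a[names(fs$importance)] <- a[names(fs$importance)] +
              fs$importance
            imp_acc <- a
          }
        }
      }
      if (!is.null(imp_acc))
        importance[[tg]][[ho]] <- sort(imp_acc / length(seeds),
                                       decreasing = TRUE)
    }
  }
  structure(list(results = do.call(rbind, rows), importance = importance),
            class = "loso_result")
}

#' AUC against number of top-Gini features
#'
#' For one target: per held-out study, ranks features by mean decrease in
#' Gini from a random forest trained on the training fold, retrains on the
#' top-k features only, and evaluates on the held-out study; reports the
#' per-fold AUC at each k and the mean curve.
#'
#' @param task `prediction_task`.
#' @param target one of `task$targets`.
#' @param ks feature counts to evaluate (capped at the number of available
#'   features, with a message).
#' @param seed training seed.
#' @param ntree random-forest tree count.
#' @return list: `per_fold` data.frame (`k`, `held_out_study`, `auc`,
#'   `top_feature`), `mean_curve` data.frame (`k`, `mean_auc`).
#' @export
gini_top_k_curve <- function(task, target, ks = c(1, 2, 5, 10, 20),
                             seed = 1, ntree = 1000) {
  stopifnot(target %in% task$targets)
  studies <- sort(unique(task$study))
  lab <- task$labels[, target]
  rows <- list()
  for (ho in studies) {
    test <- task$study == ho
    train <- !test
    if (length(unique(lab[test])) < 2L) next
    fs <- fit_and_score(task$features, lab, train, test, "rf", seed,
                        ntree, do_filter = TRUE, pooled_filter = FALSE)
    ranked <- names(sort(fs$importance, decreasing = TRUE))
    for (k in ks) {
      kk <- min(k, length(ranked))
      if (kk < k) message("k = ", k, " capped at ", kk, " features")
      cols <- ranked[seq_len(kk)]
      set.seed(seed)
      fit <- randomForest::randomForest(
        x = task$features[train, cols, drop = FALSE],
        y = factor(lab[train], levels = c(FALSE, TRUE)), ntree = ntree)
      sc <- stats::predict(fit, task$features[test, cols, drop = FALSE],
                           type = "prob")[, "TRUE"]
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, held_out_study = ho, auc = auc_score(sc, lab[test]),
        top_feature = ranked[1L], stringsAsFactors = FALSE)
    }
  }
  per_fold <- do.call(rbind, rows)
  mean_curve <- stats::aggregate(auc ~ k, data = per_fold, FUN = mean)
  names(mean_curve) <- c("k", "mean_auc")
  list(per_fold = per_fold, mean_curve = mean_curve)
}

#' Delivery-mode-stratified LOSO evaluation
#'
#' Splits dyads by a stratum (default delivery mode) and runs an
#' independent leave-one-study-out evaluation inside each stratum; targets
#' or folds whose held-out labels collapse to one class yield `NA` AUCs.
#'
#' @param task `prediction_task` (built with metadata containing the
#'   stratum).
#' @param stratum named per-dyad vector (default
#'   `task$delivery_mode`).
#' @param model,seeds,ntree forwarded to [loso_evaluate()].
#' @return named list of `loso_result`, one per stratum level.
#' @export
stratified_evaluate <- function(task, stratum = NULL, model = "rf",
                                seeds = 1:5, ntree = 1000) {
  if (is.null(stratum)) stratum <- task$delivery_mode
  if (is.null(stratum)) stop("no stratum available")
  out <- list()
  for (lv in sort(unique(stratum))) {
    sel <- stratum == lv
    sub <- structure(list(
      features = task$features[sel, , drop = FALSE],
      labels = task$labels[sel, , drop = FALSE],
      study = task$study[sel],
      delivery_mode = task$delivery_mode[sel],
      targets = task$targets), class = "prediction_task")
    out[[lv]] <- loso_evaluate(sub, model = model, seeds = seeds,
                               ntree = ntree)
  }
  out
}
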