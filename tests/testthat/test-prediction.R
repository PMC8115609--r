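test_that("near-zero-variance filter implements both criteria", {
  n <- 100
  x <- cbind(const = rep(1, n),
             sparse = c(rep(0, 96), 1, 1, 2, 2),
             balanced = rep(c(0, 1), n / 2),
             cont = rnorm(n))
  kept <- near_zero_variance_filter(x)
  expect_false("const" %in% kept)   # zero variance
  expect_false("sparse" %in% kept)  # ratio 96/2 > 19, 3% unique < 10%
  expect_true(all(c("balanced", "cont") %in% kept))
  expect_error(near_zero_variance_filter(x[, "const", drop = FALSE]),
               "all features removed")
  skip_if_not_installed("caret")
  set.seed(3)
  y <- cbind(x, round(matrix(rexp(5 * n), n), 1) *
               matrix(rbinom(5 * n, 1, 0.05), n))
  colnames(y) <- paste0("v", seq_len(ncol(y)))
  ref <- caret::nearZeroVar(y)
  expect_equal(sort(near_zero_variance_filter(y)),
               sort(setdiff(colnames(y), colnames(y)[ref])))
})

test_that("correlation filter drops the member with larger mean |r|", {
  set.seed(4)
  n <- 500
  base <- rnorm(n)
  x <- cbind(A = base,
             B = base + rnorm(n, 0, 0.25),      # r(A,B) ~ 0.97
             C = 0.6 * base + rnorm(n, 0, 0.8)) # r(A,C) > r(B,C)
  expect_gt(abs(cor(x))["A", "B"], 0.9)
  kept <- correlation_filter(x, cutoff = 0.9)
  expect_equal(sort(kept), c("B", "C"))  # A has the larger mean |r|
  # duplicated feature: exactly one copy removed (lexicographically later)
  d <- cbind(f1 = base, f2 = base, other = rnorm(n))
  expect_equal(sort(correlation_filter(d)), c("f1", "other"))
  # independent features all retained
  ind <- matrix(rnorm(3 * n), n, dimnames = list(NULL, c("u", "v", "w")))
  expect_equal(sort(correlation_filter(ind)), c("u", "v", "w"))
})

test_that("rank-based AUC counts ties as one half", {
  expect_equal(auc_score(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(auc_score(c(0.9, 0.8, 0.3, 0.4), c(1, 1, 1, 0)), 2 / 3)
  expect_equal(auc_score(c(1, 1, 2, 2), c(0, 1, 0, 1)), 0.5)
  expect_warning(a <- auc_score(1:3, c(1, 1, 1)), "single-class")
  expect_true(is.na(a))
  # invariant under monotone transforms of the scores
  set.seed(5)
  sc <- rnorm(50); lb <- rbinom(50, 1, 0.5)
  expect_equal(auc_score(sc, lb), auc_score(exp(sc), lb))
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(lb, round(sc, 1), quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_score(round(sc, 1), lb), ref, tolerance = 1e-12)
  # permuted labels centre on 0.5
  set.seed(6)
  sc <- rnorm(200); lb <- rep(c(TRUE, FALSE), 100)
  aucs <- replicate(100, auc_score(sc, sample(lb)))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("task construction enforces per-study class balance", {
  dyads <- paste0("d", 1:10)
  tab <- matrix(1, 4, 10,
                dimnames = list(paste0("sp", 1:4), paste0("m", 1:10)))
  pairing <- data.frame(dyad_id = dyads,
                        infant_sample = paste0("i", 1:10),
                        mother_sample = paste0("m", 1:10),
                        infant_day = 5, mother_day = 0,
                        study_id = rep(c("S1", "S2"), each = 5))
  md <- data.frame(sample_id = c(paste0("i", 1:10), paste0("m", 1:10)),
                   subject_id = "u", dyad_id = rep(dyads, 2),
                   role = rep(c("infant", "mother"), each = 10),
                   study_id = rep(rep(c("S1", "S2"), each = 5), 2),
                   day = 1, day_scale = "postnatal",
                   delivery_mode = "vaginal", stringsAsFactors = FALSE)
  # sp1 shared in both studies with both classes; sp2 all-positive in S1
  sh <- structure(list(
    pairs = data.frame(dyad_id = dyads,
                       study_id = pairing$study_id),
    features = data.frame(
      dyad_id = c("d1", "d2", "d6", "d7", "d1", "d2", "d3", "d4", "d5",
                  "d6"),
      infant_sample = "x",
      feature_id = c(rep("sp1", 4), rep("sp2", 6)),
      stringsAsFactors = FALSE),
    feature_kind = "taxon"), class = "sharing_records")
  task <- suppressMessages(prediction_tasks(tab, pairing, sh, md))
  expect_true("sp1" %in% task$targets)
  expect_false("sp2" %in% task$targets)  # S1 has no negative dyad
})

test_that("LOSO prediction finds a strong maternal signal", {
  task <- signal_task()
  expect_gte(length(task$targets), 3)
  targets <- task$targets[1:3]
  sub <- task; sub$targets <- targets
  res <- loso_evaluate(sub, model = "rf", seeds = 1, ntree = 300)
  expect_gt(mean(res$results$auc, na.rm = TRUE), 0.8)
  # determinism given the seed
  res2 <- loso_evaluate(sub, model = "rf", seeds = 1, ntree = 300)
  expect_identical(res$results, res2$results)
  # gradient boosting agrees on the strong signal
  resg <- loso_evaluate(sub, model = "gbm", seeds = 1)
  expect_gt(mean(resg$results$auc, na.rm = TRUE), 0.75)
})

test_that("feature filtering never touches the held-out fold", {
  task <- signal_task()
  tg <- task$targets[1]
  ho <- sort(unique(task$study))[1]
  test_rows <- task$study == ho
  poisoned <- task
  poison <- numeric(nrow(task$features))
  poison[test_rows] <- as.numeric(task$labels[test_rows, tg])
  poisoned$features <- cbind(task$features, zzz_poison = poison)
  sub <- function(t) {
    t$targets <- tg
    t
  }
  base <- loso_evaluate(sub(task), seeds = 1, ntree = 300)
  pois <- loso_evaluate(sub(poisoned), seeds = 1, ntree = 300)
  b <- base$results[base$results$held_out_study == ho, ]
  p <- pois$results[pois$results$held_out_study == ho, ]
  expect_equal(p$auc, b$auc, tolerance = 1e-12)
  expect_false("zzz_poison" %in%
                 names(pois$importance[[tg]][[ho]]))
})

test_that("top-Gini retraining identifies the self-signal feature", {
  task <- signal_task()
  # add the maternal profile of the target itself as the dominant signal
  tg <- task$targets[which.max(vapply(task$targets, function(t)
    abs(cor(task$features[, t] > 0, task$labels[, t])), numeric(1)))]
  curve <- gini_top_k_curve(task, tg, ks = c(1, 5, 10), seed = 1,
                            ntree = 300)
  expect_true(all(c(1, 5, 10) %in% curve$per_fold$k))
  # the top-ranked feature is the maternal abundance of the target species
  expect_true(all(curve$per_fold$top_feature == tg))
  m1 <- curve$mean_curve$mean_auc[curve$mean_curve$k == 1]
  mf <- curve$mean_curve$mean_auc[curve$mean_curve$k == 10]
  expect_lt(abs(m1 - mf), 0.15)
  expect_message(gini_top_k_curve(task, tg, ks = 10000, seed = 1,
                                  ntree = 50), "capped")
})

test_that("stratified evaluation partitions dyads by delivery mode", {
  task <- signal_task()
  sub <- task; sub$targets <- task$targets[1:2]
  res <- stratified_evaluate(sub, seeds = 1, ntree = 200)
  expect_named(res, sort(unique(task$delivery_mode)))
  n_tot <- vapply(res, function(r)
    sum(r$results$n_train[1], r$results$n_test[1]), numeric(1))
  expect_equal(sum(n_tot), length(task$study))
})
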