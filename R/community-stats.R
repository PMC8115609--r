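#' Alpha diversity of a single profile
#'
#' Richness is the count of features with non-zero abundance; Shannon is
#' `-sum(p * ln p)` over non-zero proportions (natural log); Simpson is the
#' Gini-Simpson index `1 - sum(p^2)`. Profiles are renormalized to
#' proportions internally, so percent and proportion inputs give identical
#' diversities. An all-zero profile has richness 0 and diversity 0.
#'
#' @param profile non-negative numeric vector.
#' @param metric `"richness"`, `"shannon"` or `"simpson"`.
#' @return a single number.
#' @export
alpha_diversity <- function(profile,
                            metric = c("richness", "shannon", "simpson")) {
  metric <- match.arg(metric)
  if (any(profile < 0)) stop("negative abundances")
  if (metric == "richness") return(sum(profile > 0))
  tot <- sum(profile)
  if (tot == 0) return(0)
  p <- profile / tot
  switch(metric,
         shannon = vegan::diversity(p, index = "shannon"),
         simpson = vegan::diversity(p, index = "simpson"))
}

#' Bray-Curtis dissimilarity between two profiles
#'
#' `sum(|p - q|) / sum(p + q)`, in `[0, 1]` for non-negative input.
#'
#' @param p,q equal-length non-negative vectors, not both all-zero.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(p, q) {
  if (length(p) != length(q)) stop("profiles differ in length")
  if (any(p < 0) || any(q < 0)) stop("negative abundances")
  if (sum(p) == 0 && sum(q) == 0) stop("both profiles are all-zero")
  sum(abs(p - q)) / sum(p + q)
}

#' Bray-Curtis dissimilarity matrix of a table's samples
#'
#' @param table `abund_table` or features x samples matrix.
#' @return a `dist` over samples (via `vegan::vegdist`).
#' @export
bray_curtis_matrix <- function(table) {
  vals <- tab_values(table)
  vegan::vegdist(t(vals), method = "bray")
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower-centred double-centring of `-D^2/2` and eigendecomposition; axes
#' are ordered by eigenvalue, axes with non-positive eigenvalues are
#' dropped from the coordinates, and the full eigenvalue spectrum (including
#' negative eigenvalues of non-Euclidean dissimilarities) is reported.
#'
#' @param d `dist` object or symmetric zero-diagonal matrix.
#' @param k number of requested axes (default 2; capped at the number of
#'   positive eigenvalues).
#' @return list with `coordinates` (n x k' matrix), `eigenvalues` (all n),
#'   `relative_eig` (positive eigenvalues as fractions of their sum).
#' @export
pcoa <- function(d, k = 2) {
  if (!inherits(d, "dist")) {
    if (!is.matrix(d) || !isSymmetric(unname(d), tol = 1e-8))
      stop("'d' must be a dist object or a symmetric matrix")
    if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal not zero")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  fit <- stats::cmdscale(d, k = min(k, n - 1L), eig = TRUE)
  eig <- fit$eig
  pos <- sum(eig > 1e-8 * max(abs(eig)))
  keep <- min(k, pos)
  coords <- fit$points[, seq_len(keep), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(keep))
  list(coordinates = coords, eigenvalues = eig,
       relative_eig = eig[eig > 0] / sum(eig[eig > 0]))
}

#' Per-feature differential abundance between two groups
#'
#' Runs a [blocked_wilcoxon()] per feature (blocked by `block`, typically
#' study) between the two levels of `grouping` and corrects p-values by
#' Benjamini-Hochberg across all tested features. By default every feature
#' is tested and the prevalence/mean-abundance reporting filters are
#' applied afterwards via the returned columns; set `prefilter = TRUE` to
#' filter before testing instead.
#'
#' @param table `abund_table` or features x samples matrix.
#' @param metadata sample metadata with `sample_id` plus the grouping and
#'   blocking columns.
#' @param grouping metadata column with exactly two levels (default
#'   `"role"`).
#' @param block metadata column used as blocking factor (default
#'   `"study_id"`).
#' @param min_prevalence,min_mean_abundance reporting filters (computed per
#'   group and satisfied if either group passes).
#' @param prefilter apply the filters before testing (affects the BH family).
#' @return data.frame with one row per tested feature: `feature_id`,
#'   `statistic`, `p_value`, `q_value`, `direction`, per-group means and
#'   prevalences, and `reportable` (passes the filters).
#' @export
differential_abundance <- function(table, metadata, grouping = "role",
                                   block = "study_id",
                                   min_prevalence = 0.05,
                                   min_mean_abundance = 0.1,
                                   prefilter = FALSE) {
  vals <- tab_values(table)
  md <- metadata[match(colnames(vals), metadata$sample_id), ]
  if (any(is.na(md$sample_id))) stop("samples missing from metadata")
  grp <- as.character(md[[grouping]])
  blk <- as.character(md[[block]])
  lev <- sort(unique(grp))
  if (length(lev) != 2L) stop("grouping must have exactly two levels")
  g1 <- grp == lev[1L]
  mean1 <- rowMeans(vals[, g1, drop = FALSE])
  mean2 <- rowMeans(vals[, !g1, drop = FALSE])
  prev1 <- rowMeans(vals[, g1, drop = FALSE] > 0)
  prev2 <- rowMeans(vals[, !g1, drop = FALSE] > 0)
  reportable <- (prev1 >= min_prevalence & mean1 > min_mean_abundance) |
    (prev2 >= min_prevalence & mean2 > min_mean_abundance)
  test_idx <- if (prefilter) which(reportable) else seq_len(nrow(vals))
  res <- lapply(test_idx, function(i) {
    bt <- blocked_wilcoxon(vals[i, ], grp, blk)
    data.frame(feature_id = rownames(vals)[i], statistic = bt$statistic,
               p_value = bt$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$p_value)
  i <- match(out$feature_id, rownames(vals))
  out$direction <- ifelse(mean1[i] >= mean2[i], lev[1L], lev[2L])
  out[[paste0("mean_", lev[1L])]] <- mean1[i]
  out[[paste0("mean_", lev[2L])]] <- mean2[i]
  out[[paste0("prevalence_", lev[1L])]] <- prev1[i]
  out[[paste0("prevalence_", lev[2L])]] <- prev2[i]
  out$reportable <- reportable[i]
  rownames(out) <- NULL
  out
}

#' Single-covariate PERMANOVA
#'
#' Distance-based permutational ANOVA of one grouping factor, delegated to
#' `vegan::adonis2` (the adonis route) with exactly `n_perm` unrestricted
#' label permutations and the `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`
#' p-value convention. Samples with missing labels are dropped first, and
#' any group with fewer than `min_group_size` samples is excluded (with its
#' samples) before testing.
#'
#' @param d `dist` or symmetric matrix of dissimilarities.
#' @param labels grouping vector aligned with the distance object's samples.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed controlling the permutations.
#' @param min_group_size smallest admissible group (default 3, the
#'   covariate-screening rule).
#' @return data.frame row: `r_squared`, `pseudo_F`, `p_value`,
#'   `n_samples`, `n_groups`.
#' @export
permanova_test <- function(d, labels, n_perm = 1000, seed = 1,
                           min_group_size = 3) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  m <- as.matrix(d)
  labels <- as.character(labels)
  keep <- !is.na(labels)
  cnt <- table(labels[keep])
  small <- names(cnt)[cnt < min_group_size]
  keep <- keep & !(labels %in% small)
  if (sum(keep) < 2L || length(unique(labels[keep])) < 2L)
    stop("fewer than two admissible groups")
  m <- m[keep, keep]
  df <- data.frame(grp = factor(labels[keep]))
  set.seed(seed)
  fit <- vegan::adonis2(stats::as.dist(m) ~ grp, data = df,
                        permutations = n_perm)
  data.frame(r_squared = fit$R2[1L], pseudo_F = fit$F[1L],
             p_value = fit$`Pr(>F)`[1L], n_samples = sum(keep),
             n_groups = length(unique(labels[keep])))
}

#' Covariate variance scan over time bins
#'
#' For each infant time bin and each clinical covariate, runs a univariate
#' [permanova_test()] on the Bray-Curtis dissimilarities of the
#' mother-infant shared-species subtable restricted to that bin's infant
#' samples, then applies BH correction across the whole scan. Covariates
#' whose admissible groups collapse to fewer than two, and bins with fewer
#' than `min_bin_samples` samples, are skipped (with a message).
#'
#' @param table `abund_table`/matrix restricted to the shared-species set
#'   (see [core_shared_set()] / [compute_sharing()]).
#' @param metadata metadata with `time_bin` assigned
#'   (see [assign_time_bins()]).
#' @param covariates metadata column names to scan.
#' @param n_perm,seed forwarded to [permanova_test()].
#' @param min_bin_samples smallest bin analyzed (default 6).
#' @return data.frame with `time_bin`, `covariate`, `r_squared`,
#'   `pseudo_F`, `p_value`, `q_value`, `n_samples`.
#' @export
covariate_variance_scan <- function(table, metadata,
                                    covariates = c("delivery_mode",
                                                   "study_id", "feeding",
                                                   "infant_antibiotics",
                                                   "gestational_age",
                                                   "maternal_age_class",
                                                   "maternal_abx_before_delivery",
                                                   "maternal_intrapartum_abx",
                                                   "birth_weight_class",
                                                   "csection_type",
                                                   "maternal_bmi_class",
                                                   "sex"),
                                    n_perm = 1000, seed = 1,
                                    min_bin_samples = 6) {
  vals <- tab_values(table)
  if (!"time_bin" %in% names(metadata))
    stop("assign time bins before scanning")
  inf <- metadata[metadata$role == "infant" &
                    metadata$time_bin != "unbinned" &
                    metadata$sample_id %in% colnames(vals), ]
  out <- list()
  bins <- intersect(infant_bin_levels(), unique(inf$time_bin))
  for (b in bins) {
    mb <- inf[inf$time_bin == b, ]
    if (nrow(mb) < min_bin_samples) {
      message("skipping bin ", b, ": fewer than ", min_bin_samples,
              " samples")
      next
    }
    sub <- vals[, mb$sample_id, drop = FALSE]
    nz <- colSums(sub) > 0
    sub <- sub[, nz, drop = FALSE]
    mb <- mb[nz, ]
    d <- vegan::vegdist(t(sub), method = "bray")
    for (cv in covariates) {
      lab <- as.character(mb[[cv]])
      res <- tryCatch(
        permanova_test(d, lab, n_perm = n_perm,
                       seed = seed + match(b, bins) * 131L +
                         match(cv, covariates)),
        error = function(e) NULL)
      if (is.null(res)) next
      out[[length(out) + 1L]] <- cbind(
        data.frame(time_bin = b, covariate = cv, stringsAsFactors = FALSE),
        res)
    }
  }
  if (length(out) == 0L)
    return(data.frame(time_bin = character(0), covariate = character(0)))
  scan <- do.call(rbind, out)
  scan$q_value <- bh_fdr(scan$p_value)
  rownames(scan) <- NULL
  scan
}
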