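#' Pair infant samples with a maternal sample from a time window
#'
#' For every infant sample, selects the mother's sample of the same dyad
#' inside `mother_window` (default: the delivery window, postnatal days
#' 0-7). If several maternal samples qualify, the one nearest in time to
#' the infant sample is used, with ties going to the earliest. Dyads whose
#' mother has no sample in the window are excluded (with a message).
#'
#' @param metadata sample metadata.
#' @param mother_window length-2 postnatal day range for maternal samples.
#' @return data.frame with `dyad_id`, `infant_sample`, `mother_sample`,
#'   `infant_day`, `mother_day`, `study_id`.
#' @export
pair_dyads <- function(metadata, mother_window = c(0, 7)) {
  metadata <- validate_metadata(metadata)
  moms <- metadata[metadata$role == "mother" &
                     metadata$day_scale == "postnatal" &
                     metadata$day >= mother_window[1L] &
                     metadata$day <= mother_window[2L], ]
  infs <- metadata[metadata$role == "infant", ]
  dropped <- setdiff(unique(infs$dyad_id), unique(moms$dyad_id))
  if (length(dropped))
    message(length(dropped),
            " dyad(s) excluded: no maternal sample in the window")
  out <- lapply(seq_len(nrow(infs)), function(i) {
    m <- moms[moms$dyad_id == infs$dyad_id[i], ]
    if (nrow(m) == 0L) return(NULL)
    gap <- abs(m$day - infs$day[i])
    m <- m[order(gap, m$day), ]
    data.frame(dyad_id = infs$dyad_id[i],
               infant_sample = infs$sample_id[i],
               mother_sample = m$sample_id[1L],
               infant_day = infs$day[i], mother_day = m$day[1L],
               study_id = infs$study_id[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(dyad_id = character(0), infant_sample = character(0),
                      mother_sample = character(0), infant_day = numeric(0),
                      mother_day = numeric(0), study_id = character(0))
  rownames(out) <- NULL
  out
}

#' Shared features of one mother-infant sample pair
#'
#' Sharing is presence/absence: a feature is shared when its abundance is
#' strictly positive in both members, irrespective of abundance.
#'
#' @param mother_profile,infant_profile named non-negative vectors over the
#'   same feature space.
#' @return list: `shared_features`, `n_shared`, `infant_feature_count`,
#'   `mother_feature_count`, `shared_fraction_infant` (infant-referenced
#'   denominator; 0 when the infant has no features) and
#'   `shared_fraction_mother`.
#' @export
shared_features <- function(mother_profile, infant_profile) {
  if (length(mother_profile) != length(infant_profile))
    stop("profiles must share one feature space")
  pm <- mother_profile > 0
  pi_ <- infant_profile > 0
  sh <- pm & pi_
  nm <- names(mother_profile)[sh]
  list(shared_features = nm,
       n_shared = sum(sh),
       infant_feature_count = sum(pi_),
       mother_feature_count = sum(pm),
       shared_fraction_infant = if (sum(pi_) == 0) 0 else sum(sh) / sum(pi_),
       shared_fraction_mother = if (sum(pm) == 0) 0 else sum(sh) / sum(pm))
}

#' Compute sharing records for all paired samples
#'
#' @param table `abund_table` or features x samples matrix.
#' @param pairing output of [pair_dyads()].
#' @param feature_kind label stored with the records.
#' @return list of class `sharing_records`: `pairs` (one row per
#'   mother-infant sample pair with counts and fractions) and `features`
#'   (long data.frame of shared occurrences: `dyad_id`, `infant_sample`,
#'   `feature_id`).
#' @export
compute_sharing <- function(table, pairing, feature_kind = NULL) {
  vals <- tab_values(table)
  if (is.null(feature_kind))
    feature_kind <- if (inherits(table, "abund_table")) table$feature_kind
                    else "taxon"
  miss <- setdiff(unique(c(pairing$mother_sample, pairing$infant_sample)),
                  colnames(vals))
  if (length(miss)) stop("paired samples missing from table: ", miss[1L])
  pres <- vals > 0
  pairs <- pairing
  pairs$n_shared <- 0L
  pairs$infant_feature_count <- 0L
  pairs$mother_feature_count <- 0L
  feats <- vector("list", nrow(pairing))
  for (i in seq_len(nrow(pairing))) {
    pm <- pres[, pairing$mother_sample[i]]
    pi_ <- pres[, pairing$infant_sample[i]]
    sh <- pm & pi_
    pairs$n_shared[i] <- sum(sh)
    pairs$infant_feature_count[i] <- sum(pi_)
    pairs$mother_feature_count[i] <- sum(pm)
    if (any(sh))
      feats[[i]] <- data.frame(dyad_id = pairing$dyad_id[i],
                               infant_sample = pairing$infant_sample[i],
                               feature_id = rownames(vals)[sh],
                               stringsAsFactors = FALSE)
  }
  pairs$shared_fraction_infant <-
    ifelse(pairs$infant_feature_count == 0, 0,
           pairs$n_shared / pairs$infant_feature_count)
  pairs$shared_fraction_mother <-
    ifelse(pairs$mother_feature_count == 0, 0,
           pairs$n_shared / pairs$mother_feature_count)
  feats <- do.call(rbind, feats)
  if (is.null(feats))
    feats <- data.frame(dyad_id = character(0), infant_sample = character(0),
                        feature_id = character(0))
  structure(list(pairs = pairs, features = feats,
                 feature_kind = feature_kind),
            class = "sharing_records")
}

#' Related vs unrelated mother-infant compositional similarity
#'
#' Bray-Curtis dissimilarity of every infant sample against its own
#' (windowed) maternal sample versus against every other dyad's windowed
#' maternal sample, with a Wilcoxon rank-sum comparison of the two
#' distributions.
#'
#' @param table species table.
#' @param pairing output of [pair_dyads()] (needs >= 2 dyads).
#' @param alternative passed to `stats::wilcox.test`; `"less"` tests that
#'   related dissimilarities are stochastically smaller.
#' @return list: `related`, `unrelated` (numeric vectors), `test`
#'   (`htest`).
#' @export
related_vs_unrelated_similarity <- function(table, pairing,
                                            alternative = "two.sided") {
  if (length(unique(pairing$dyad_id)) < 2L)
    stop("need at least two dyads")
  vals <- tab_values(table)
  mother_of <- tapply(pairing$mother_sample, pairing$dyad_id,
                      function(x) x[1L])
  related <- numeric(nrow(pairing))
  unrel <- list()
  for (i in seq_len(nrow(pairing))) {
    inf <- vals[, pairing$infant_sample[i]]
    related[i] <- bray_curtis(vals[, pairing$mother_sample[i]], inf)
    others <- mother_of[names(mother_of) != pairing$dyad_id[i]]
    unrel[[i]] <- vapply(others, function(ms) bray_curtis(vals[, ms], inf),
                         numeric(1))
  }
  unrelated <- unlist(unrel, use.names = FALSE)
  test <- stats::wilcox.test(related, unrelated, alternative = alternative,
                             exact = FALSE)
  list(related = related, unrelated = unrelated, test = test)
}

#' Cross-cohort core set of shared species
#'
#' A species enters the core set when it is shared in at least
#' `min_dyads_per_study` dyads in *every* study (a dyad shares a species if
#' any of its mother-infant sample pairs shares it). Also reports the
#' species x study dyad-count matrix and each species' prevalence across
#' all dyads.
#'
#' @param sharing `sharing_records` from [compute_sharing()].
#' @param min_dyads_per_study minimum sharing dyads per study (default 1).
#' @return list of class `core_set`: `core_species`,
#'   `per_study_dyad_counts`, `prevalence_across_dyads`, `n_dyads`.
#' @export
core_shared_set <- function(sharing, min_dyads_per_study = 1) {
  pairs <- sharing$pairs
  studies <- sort(unique(pairs$study_id))
  if (length(studies) < 2L) stop("need at least two studies")
  study_of <- tapply(pairs$study_id, pairs$dyad_id, function(x) x[1L])
  f <- unique(sharing$features[c("dyad_id", "feature_id")])
  f$study <- study_of[f$dyad_id]
  counts <- table(factor(f$feature_id), factor(f$study, levels = studies))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  core <- rownames(counts)[apply(counts >= min_dyads_per_study, 1L, all)]
  n_dyads <- length(unique(pairs$dyad_id))
  prev <- rowSums(table(factor(f$feature_id), factor(f$dyad_id)) > 0) /
    n_dyads
  structure(list(core_species = core, per_study_dyad_counts = counts,
                 prevalence_across_dyads = prev, n_dyads = n_dyads),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core shared set: %d species across %d studies (%d dyads)\n",
              length(x$core_species), ncol(x$per_study_dyad_counts),
              x$n_dyads))
  invisible(x)
}

#' Shared-fraction dynamics across infant time bins
#'
#' Mean infant-referenced shared fraction per time bin with a 95% normal
#' confidence interval, per feature kind (species and, if provided,
#' pathways). Optionally augments each kind with the quadratic fit of
#' fraction on infant age.
#'
#' @param sharing_list named list of `sharing_records` (e.g.
#'   `list(species = ..., pathways = ...)`).
#' @param metadata metadata with `time_bin` assigned.
#' @param quadratic_fit also return per-kind quadratic regression of the
#'   fraction on infant age in days.
#' @return list: `by_bin` data.frame (`kind`, `time_bin`, `n_pairs`,
#'   `mean_fraction`, `ci_lo`, `ci_hi`), and `fits` (when requested).
#' @export
shared_fraction_dynamics <- function(sharing_list, metadata,
                                     quadratic_fit = FALSE) {
  if (is.null(names(sharing_list)))
    names(sharing_list) <- vapply(sharing_list, `[[`, character(1),
                                  "feature_kind")
  if (!"time_bin" %in% names(metadata))
    stop("assign time bins before computing dynamics")
  bin_of <- stats::setNames(metadata$time_bin, metadata$sample_id)
  rows <- list()
  fits <- list()
  for (kind in names(sharing_list)) {
    p <- sharing_list[[kind]]$pairs
    p$time_bin <- bin_of[p$infant_sample]
    p <- p[!is.na(p$time_bin) & p$time_bin != "unbinned", ]
    for (b in intersect(infant_bin_levels(), unique(p$time_bin))) {
      x <- p$shared_fraction_infant[p$time_bin == b]
      se <- stats::sd(x) / sqrt(length(x))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, time_bin = b, n_pairs = length(x),
        mean_fraction = mean(x),
        ci_lo = mean(x) - 1.96 * se, ci_hi = mean(x) + 1.96 * se,
        stringsAsFactors = FALSE)
    }
    if (quadratic_fit && nrow(p) >= 3L)
      fits[[kind]] <- stats::lm(shared_fraction_infant ~ infant_day +
                                  I(infant_day^2), data = p)
  }
  out <- list(by_bin = do.call(rbind, rows))
  if (quadratic_fit) out$fits <- fits
  out
}

#' Shared-species counts against infant age
#'
#' Per infant sample, the number of features shared with the mother, with
#' an ordinary least-squares fit of count on age in days.
#'
#' @param sharing `sharing_records`.
#' @return list: `points` data.frame (`infant_sample`, `age_days`,
#'   `n_shared`), `slope`, `p_value`, `fit` (the `lm`, `NULL` with < 3
#'   points).
#' @export
shared_count_vs_age <- function(sharing) {
  p <- sharing$pairs
  pts <- data.frame(infant_sample = p$infant_sample, age_days = p$infant_day,
                    n_shared = p$n_shared, stringsAsFactors = FALSE)
  if (nrow(pts) < 3L)
    return(list(points = pts, slope = NA_real_, p_value = NA_real_,
                fit = NULL))
  fit <- stats::lm(n_shared ~ age_days, data = pts)
  sm <- summary(fit)$coefficients
  list(points = pts, slope = sm["age_days", "Estimate"],
       p_value = sm["age_days", "Pr(>|t|)"], fit = fit)
}
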