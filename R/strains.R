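#' SNP-haplotype similarity of two aligned sequences
#'
#' Fraction of identical positions among the comparable positions, where a
#' position is comparable when neither sequence has a gap (pairwise
#' deletion). Returns `NA` (with a warning) when no position is comparable.
#'
#' @param seq_a,seq_b equal-length aligned sequences (character strings,
#'   alphabet A/C/G/T/-).
#' @return fraction in `[0, 1]`, or `NA`.
#' @export
haplotype_similarity <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences differ in length")
  a <- strsplit(toupper(seq_a), "")[[1L]]
  b <- strsplit(toupper(seq_b), "")[[1L]]
  comparable <- a != "-" & b != "-"
  if (!any(comparable)) {
    warning("no comparable (both non-gap) positions")
    return(NA_real_)
  }
  sum(a[comparable] == b[comparable]) / sum(comparable)
}

#' Pairwise p-distance matrix of a haplotype alignment
#'
#' `1 - similarity` for every sample pair, computed with pairwise deletion
#' of gap positions (via `ape::dist.dna`, raw model).
#'
#' @param alignment a `haplotype_alignment` with >= 2 records.
#' @return symmetric zero-diagonal matrix; `NaN` for pairs with no
#'   comparable positions.
#' @export
p_distance_matrix <- function(alignment) {
  seqs <- alignment$sequences
  if (length(seqs) < 2L) stop("need at least two records")
  chars <- do.call(rbind, strsplit(tolower(seqs), ""))
  rownames(chars) <- names(seqs)
  dna <- ape::as.DNAbin(chars)
  d <- ape::dist.dna(dna, model = "raw", pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  d[names(seqs), names(seqs)]
}

#' Neighbor-joining strain tree
#'
#' Saitou-Nei neighbor joining on a haplotype distance matrix (via
#' `ape::nj`). Negative branch lengths, which NJ can produce on
#' non-additive input, are clamped to zero with the residual pushed onto
#' the sibling branch so leaf-to-leaf path lengths through the parent are
#' preserved.
#'
#' @param d symmetric distance matrix (>= 3 leaves) with leaf names.
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least three leaves; use p-distances")
  tree <- ape::nj(stats::as.dist(d))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1L]
    sib <- which(tree$edge[, 1L] == parent & seq_along(tree$edge[, 1L]) != e)
    if (length(sib)) {
      tree$edge.length[sib[1L]] <- tree$edge.length[sib[1L]] +
        tree$edge.length[e]
      tree$edge.length[sib[1L]] <- max(tree$edge.length[sib[1L]], 0)
    }
    tree$edge.length[e] <- 0
  }
  tree
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths along the unique path between two leaves.
#'
#' @param tree `phylo` tree.
#' @param leaf_a,leaf_b tip labels.
#' @return non-negative number.
#' @export
patristic_distance <- function(tree, leaf_a, leaf_b) {
  if (!all(c(leaf_a, leaf_b) %in% tree$tip.label))
    stop("unknown leaf label")
  if (leaf_a == leaf_b) return(0)
  D <- stats::cophenetic(tree)
  D[leaf_a, leaf_b]
}

# normalization constant of a patristic matrix
strain_norm_const <- function(D, normalization) {
  switch(normalization,
         max_pair = max(D),
         total_branch = NA,  # caller supplies tree-based value
         median_pair = stats::median(D[upper.tri(D)]),
         stop("unknown normalization"))
}

#' Normalized strain distance between two samples
#'
#' The patristic distance between two leaves divided by a species-level
#' normalization constant: the maximum leaf-pair patristic distance
#' (default, bounding values in `[0, 1]` so the fixed 0.1 sharing threshold
#' is meaningful), the total branch length, or the median leaf-pair
#' distance. When every pair is identical (zero constant) the distance is
#' defined as 0.
#'
#' @param tree `phylo` tree (>= 2 leaves).
#' @param leaf_a,leaf_b tip labels.
#' @param normalization `"max_pair"`, `"total_branch"` or `"median_pair"`.
#' @return normalized distance (in `[0, 1]` for `"max_pair"`).
#' @export
normalized_strain_distance <- function(tree, leaf_a, leaf_b,
                                       normalization = "max_pair") {
  D <- stats::cophenetic(tree)
  nc <- if (normalization == "total_branch") sum(tree$edge.length)
        else strain_norm_const(D, normalization)
  if (!is.finite(nc) || nc <= 0) return(0)
  D[leaf_a, leaf_b] / nc
}

#' Call mother-to-infant strain transmission
#'
#' For each species, builds the strain distance structure from its
#' haplotype alignment (neighbor-joining tree and patristic distances for
#' >= 3 records; plain p-distances normalized by the species' maximum
#' pairwise p-distance for fewer) and emits one call per paired
#' (mother sample, infant sample) in which both members carry a haplotype:
#' the strain is *shared* (vertically transmitted) when the normalized
#' distance is strictly below `threshold` (default 0.1, the conservative
#' sharing threshold). Pairs in which either member lacks the species give
#' no call.
#'
#' @param haplotypes named list of `haplotype_alignment` (or a single one).
#' @param pairing output of [pair_dyads()].
#' @param threshold strict sharing threshold on the normalized distance.
#' @param normalization see [normalized_strain_distance()].
#' @return data.frame of class `transmission_calls`: `dyad_id`, `species`,
#'   `mother_sample`, `infant_sample`, `normalized_distance`, `threshold`,
#'   `shared`.
#' @export
call_transmission <- function(haplotypes, pairing, threshold = 0.1,
                              normalization = "max_pair") {
  if (inherits(haplotypes, "haplotype_alignment"))
    haplotypes <- stats::setNames(list(haplotypes), haplotypes$species)
  out <- list()
  for (al in haplotypes) {
    samples <- names(al$sequences)
    hit <- pairing$mother_sample %in% samples &
      pairing$infant_sample %in% samples
    if (!any(hit)) next
    pr <- pairing[hit, ]
    if (length(samples) >= 3L) {
      pd <- p_distance_matrix(al)
      if (any(!is.finite(pd))) pd[!is.finite(pd)] <- max(pd, na.rm = TRUE)
      tree <- nj_tree(pd)
      D <- stats::cophenetic(tree)[samples, samples]
      nc <- if (normalization == "total_branch") sum(tree$edge.length)
            else strain_norm_const(D, normalization)
    } else if (length(samples) == 2L) {
      D <- p_distance_matrix(al)
      nc <- max(D)
    } else next
    nd <- if (nc > 0) D[cbind(pr$mother_sample, pr$infant_sample)] / nc
          else rep(0, nrow(pr))
    out[[length(out) + 1L]] <- data.frame(
      dyad_id = pr$dyad_id, species = al$species,
      mother_sample = pr$mother_sample, infant_sample = pr$infant_sample,
      normalized_distance = nd, threshold = threshold,
      shared = nd < threshold, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out)
  if (is.null(calls))
    calls <- data.frame(dyad_id = character(0), species = character(0),
                        mother_sample = character(0),
                        infant_sample = character(0),
                        normalized_distance = numeric(0),
                        threshold = numeric(0), shared = logical(0))
  rownames(calls) <- NULL
  class(calls) <- c("transmission_calls", "data.frame")
  calls
}

#' Intra-subject strain heterogeneity
#'
#' All within-subject, cross-timepoint SNP-haplotype similarities per
#' species, stratified into intra-mother and intra-infant comparisons.
#' Species are retained only with at least `min_comparisons` comparisons in
#' *both* strata; per-species Wilcoxon rank-sum tests of the two strata are
#' BH-corrected.
#'
#' @param haplotypes named list of `haplotype_alignment`.
#' @param metadata sample metadata.
#' @param min_comparisons stratum size cutoff (default 10).
#' @return list: `values` (long data.frame: `species`, `subject_id`,
#'   `role`, `similarity`), `tests` (per retained species: stratum means,
#'   `p_value`, `q_value`).
#' @export
intra_subject_heterogeneity <- function(haplotypes, metadata,
                                        min_comparisons = 10) {
  role_of <- stats::setNames(metadata$role, metadata$sample_id)
  subj_of <- stats::setNames(metadata$subject_id, metadata$sample_id)
  vals <- list()
  for (al in haplotypes) {
    ss <- names(al$sequences)
    ss <- ss[ss %in% names(subj_of)]
    for (subj in unique(subj_of[ss])) {
      sub <- ss[subj_of[ss] == subj]
      if (length(sub) < 2L) next
      cmb <- utils::combn(sub, 2L)
      for (j in seq_len(ncol(cmb))) {
        sim <- haplotype_similarity(al$sequences[[cmb[1L, j]]],
                                    al$sequences[[cmb[2L, j]]])
        vals[[length(vals) + 1L]] <- data.frame(
          species = al$species, subject_id = subj,
          role = unname(role_of[cmb[1L, j]]), similarity = sim,
          stringsAsFactors = FALSE)
      }
    }
  }
  values <- do.call(rbind, vals)
  if (is.null(values))
    return(list(values = data.frame(), tests = data.frame()))
  tests <- list()
  for (sp in unique(values$species)) {
    v <- values[values$species == sp & !is.na(values$similarity), ]
    nm <- sum(v$role == "mother"); ni <- sum(v$role == "infant")
    if (nm < min_comparisons || ni < min_comparisons) {
      message("skipping ", sp, ": fewer than ", min_comparisons,
              " comparisons in a stratum")
      next
    }
    wt <- stats::wilcox.test(similarity ~ role, data = v, exact = FALSE)
    tests[[length(tests) + 1L]] <- data.frame(
      species = sp, n_mother = nm, n_infant = ni,
      mean_mother = mean(v$similarity[v$role == "mother"]),
      mean_infant = mean(v$similarity[v$role == "infant"]),
      statistic = unname(wt$statistic), p_value = wt$p.value,
      stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, tests)
  if (!is.null(tests)) tests$q_value <- bh_fdr(tests$p_value)
  else tests <- data.frame()
  list(values = values, tests = tests)
}

#' Shared-strain dynamics across infant time bins
#'
#' Per time bin and species: the fraction of evaluable infant samples
#' (those with a transmission call for the species) whose strain is shared;
#' per infant sample: the count of shared strains, with an OLS trend of
#' count on infant age.
#'
#' @param calls `transmission_calls`.
#' @param metadata metadata with `time_bin` assigned.
#' @param min_display_prevalence species are reported when their shared
#'   prevalence reaches this fraction in at least one bin (default 0.1).
#' @return list: `prevalence` (`time_bin`, `species`, `n_evaluable`,
#'   `prevalence`), `counts` (`infant_sample`, `age_days`, `n_shared`),
#'   `slope`, `p_value`.
#' @export
shared_strain_dynamics <- function(calls, metadata,
                                   min_display_prevalence = 0.1) {
  bin_of <- stats::setNames(metadata$time_bin, metadata$sample_id)
  day_of <- stats::setNames(metadata$day, metadata$sample_id)
  cc <- calls[!is.na(calls$shared), ]
  cc$time_bin <- bin_of[cc$infant_sample]
  cc <- cc[!is.na(cc$time_bin) & cc$time_bin != "unbinned", ]
  prev <- stats::aggregate(shared ~ time_bin + species, data = cc,
                           FUN = function(x) mean(x))
  nev <- stats::aggregate(shared ~ time_bin + species, data = cc,
                          FUN = length)
  prev <- data.frame(time_bin = prev$time_bin, species = prev$species,
                     n_evaluable = nev$shared, prevalence = prev$shared,
                     stringsAsFactors = FALSE)
  keep_sp <- unique(prev$species[prev$prevalence >= min_display_prevalence])
  prev <- prev[prev$species %in% keep_sp, ]
  counts <- stats::aggregate(shared ~ infant_sample, data = cc, FUN = sum)
  names(counts) <- c("infant_sample", "n_shared")
  counts$age_days <- unname(day_of[counts$infant_sample])
  slope <- NA_real_; pv <- NA_real_
  if (nrow(counts) >= 3L) {
    fit <- summary(stats::lm(n_shared ~ age_days, data = counts))$coefficients
    slope <- fit["age_days", "Estimate"]
    pv <- fit["age_days", "Pr(>|t|)"]
  }
  list(prevalence = prev, counts = counts, slope = slope, p_value = pv)
}

#' Functional contrast of shared vs non-shared species
#'
#' Splits species-stratified pathway abundance in each infant sample into
#' the part attributed to mother-shared species (a shared transmission call
#' for that infant sample) and the part attributed to non-shared species,
#' then compares the two groups per pathway with a study-blocked Wilcoxon
#' test and BH correction.
#'
#' @param calls `transmission_calls`.
#' @param stratified matrix of stratified pathway rows
#'   (`PWY|g__...s__Species` rownames) x samples.
#' @param metadata sample metadata (for the study block).
#' @return data.frame per pathway: `pathway`, `mean_shared`,
#'   `mean_nonshared`, `statistic`, `p_value`, `q_value`; empty (with a
#'   message) when no stratified rows are available.
#' @export
shared_function_contrast <- function(calls, stratified, metadata) {
  strat_sp <- sub("^.*s__", "", rownames(stratified))
  pw <- sub("\\|.*$", "", rownames(stratified))
  if (nrow(stratified) == 0L) {
    message("no stratified pathway rows; skipping contrast")
    return(data.frame())
  }
  study_of <- stats::setNames(metadata$study_id, metadata$sample_id)
  cc <- calls[!is.na(calls$shared), ]
  samples <- intersect(unique(cc$infant_sample), colnames(stratified))
  if (length(samples) == 0L) return(data.frame())
  sp_all <- unique(strat_sp)
  shared_ind <- matrix(FALSE, length(sp_all), length(samples),
                       dimnames = list(sp_all, samples))
  nonshared_ind <- shared_ind
  for (i in seq_len(nrow(cc))) {
    s <- cc$infant_sample[i]
    if (!s %in% samples || !cc$species[i] %in% sp_all) next
    if (cc$shared[i]) shared_ind[cc$species[i], s] <- TRUE
    else nonshared_ind[cc$species[i], s] <- TRUE
  }
  sub <- stratified[, samples, drop = FALSE]
  attr_shared <- sub * shared_ind[strat_sp, , drop = FALSE]
  attr_non <- sub * nonshared_ind[strat_sp, , drop = FALSE]
  sh <- rowsum(attr_shared, pw)
  ns <- rowsum(attr_non, pw)
  res <- list()
  for (p in rownames(sh)) {
    x <- c(sh[p, ], ns[p, ])
    g <- rep(c("shared", "nonshared"), each = length(samples))
    blk <- rep(unname(study_of[samples]), 2L)
    if (all(x == 0)) next
    bt <- blocked_wilcoxon(x, g, blk)
    res[[length(res) + 1L]] <- data.frame(
      pathway = p, mean_shared = mean(sh[p, ]), mean_nonshared = mean(ns[p, ]),
      statistic = bt$statistic, p_value = bt$p_value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame())
  out$q_value <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}
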