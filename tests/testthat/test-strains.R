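test_that("haplotype similarity counts comparable positions only", {
  expect_equal(haplotype_similarity(strrep("ACGT", 25), strrep("ACGT", 25)),
               1)
  expect_equal(haplotype_similarity("AAAT", "AAAA"), 0.75)
  # 100 sites, 3 mismatches, 2 gap columns: 95 matches of 98 comparable
  a <- rep("A", 100); b <- rep("A", 100)
  b[1:3] <- "C"
  a[50] <- "-"; b[60] <- "-"
  expect_equal(haplotype_similarity(paste(a, collapse = ""),
                                    paste(b, collapse = "")), 95 / 98)
  expect_warning(s <- haplotype_similarity("--A", "A--"), "comparable")
  expect_true(is.na(s))
  expect_error(haplotype_similarity("AC", "ACG"), "length")
})

test_that("p-distance matrix matches the brute-force double loop", {
  set.seed(1)
  alphabet <- c("A", "C", "G", "T", "-")
  seqs <- vapply(1:6, function(i)
    paste(sample(alphabet, 60, replace = TRUE, prob = c(rep(0.23, 4), 0.08)),
          collapse = ""), character(1))
  names(seqs) <- paste0("s", 1:6)
  al <- haplotype_alignment("toy", seqs)
  D <- p_distance_matrix(al)
  for (i in 1:6) for (j in 1:6) {
    ref <- if (i == j) 0 else 1 - haplotype_similarity(seqs[[i]], seqs[[j]])
    expect_equal(unname(D[i, j]), ref, tolerance = 1e-12)
  }
  expect_equal(unname(p_distance_matrix(
    haplotype_alignment("x", c(a = "AAAT", b = "AAAA")))["a", "b"]), 0.25)
})

test_that("neighbor joining reproduces additive matrices exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4):1)
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- nj_tree(D)
  expect_equal(sort(tree$tip.label), LETTERS[1:4])
  P <- stats::cophenetic(tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(P, D, tolerance = 1e-9)
  expect_true(all(tree$edge.length >= 0))
  # ultrametric equidistant 4 taxa: all patristic distances equal input
  U <- matrix(2, 4, 4, dimnames = dimnames(D)); diag(U) <- 0
  PU <- stats::cophenetic(nj_tree(U))[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(PU, U, tolerance = 1e-9)
  expect_error(nj_tree(D[1:2, 1:2]), "three leaves")
})

test_that("patristic and normalized distances follow the 3-taxon forms", {
  tree <- ape::read.tree(text = "((A:1,B:2):1,C:3);")
  expect_equal(patristic_distance(tree, "A", "C"), 5)
  expect_equal(patristic_distance(tree, "A", "B"), 3)
  expect_equal(patristic_distance(tree, "A", "A"), 0)
  expect_error(patristic_distance(tree, "A", "Z"), "unknown leaf")
  # pairs (3, 5, 6): normalized d(A,C) = 5/6, max pair -> 1
  expect_equal(normalized_strain_distance(tree, "A", "C"), 5 / 6)
  expect_equal(normalized_strain_distance(tree, "B", "C"), 1)
  # zero-length tree: distance defined as 0
  tz <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  expect_equal(normalized_strain_distance(tz, "A", "C"), 0)
  # 3-taxon NJ solves the three-point formula exactly
  D3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  P3 <- stats::cophenetic(nj_tree(D3))[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(P3, D3, tolerance = 1e-9)
})

test_that("a normalized distance of exactly 0.1 is not shared", {
  # mother A and infant B differ at 2 of 100 sites; outgroup C differs
  # from both at 18 further sites: max p-distance 0.20, d(A,B)/max = 0.1
  a <- rep("A", 100)
  b <- a; b[1:2] <- "C"
  cc <- a; cc[3:20] <- "G"
  al <- haplotype_alignment("sp_x", c(
    M = paste(a, collapse = ""), I = paste(b, collapse = ""),
    O = paste(cc, collapse = "")))
  pr <- data.frame(dyad_id = "d1", infant_sample = "I", mother_sample = "M",
                   infant_day = 1, mother_day = 0, study_id = "S1")
  calls <- call_transmission(al, pr)
  expect_equal(calls$normalized_distance, 0.1, tolerance = 1e-12)
  expect_false(calls$shared)
  # identical pair: distance 0, shared at any threshold
  al2 <- haplotype_alignment("sp_y", c(
    M = paste(a, collapse = ""), I = paste(a, collapse = ""),
    O = paste(cc, collapse = "")))
  expect_true(call_transmission(al2, pr, threshold = 1e-6)$shared)
})

test_that("lowering the threshold never adds shared calls", {
  co <- small_cohort()
  pd <- cohort_pairing(co)
  prev <- Inf
  for (thr in c(0.3, 0.1, 0.05, 0.01)) {
    calls <- call_transmission(co$haplotypes, pd$pairing, threshold = thr)
    n <- sum(calls$shared, na.rm = TRUE)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("no-transmission cohorts give a low false-positive rate", {
  co <- cached("null_calls", generate_cohort(cohort_config(
    n_studies = 2, dyads_per_study = 12, species_pool = uniform_pool(0),
    haplotype_length = 400, n_population_strains = 100, seed = 31)))
  pd <- cohort_pairing(co)
  calls <- call_transmission(co$haplotypes, pd$pairing)
  expect_gt(nrow(calls), 50)
  expect_lte(mean(calls$shared, na.rm = TRUE), 0.05)
})

test_that("species absent in either member yield no call", {
  co <- small_cohort()
  pd <- cohort_pairing(co)
  calls <- call_transmission(co$haplotypes, pd$pairing)
  vals <- co$species$values
  key <- sub(".*s__", "", rownames(vals))
  for (j in sample(nrow(calls), 10)) {
    r <- which(key == calls$species[j])
    expect_gt(vals[r, calls$mother_sample[j]], 0)
    expect_gt(vals[r, calls$infant_sample[j]], 0)
  }
})

test_that("infant strains are longitudinally more stable than mothers'", {
  co <- cached("hetero", generate_cohort(cohort_config(
    n_studies = 2, dyads_per_study = 15,
    mother_timepoints = data.frame(day = c(3, 60, 200),
                                   scale = "postnatal"),
    mother_strain_replacement = 0.5, haplotype_length = 300,
    n_population_strains = 40, seed = 55)))
  het <- suppressMessages(intra_subject_heterogeneity(co$haplotypes,
                                                      co$metadata))
  expect_gt(nrow(het$tests), 0)
  expect_true(all(het$tests$n_mother >= 10 & het$tests$n_infant >= 10))
  sig <- het$tests[het$tests$q_value < 0.05, ]
  expect_gt(nrow(sig), 0)
  expect_true(all(sig$mean_infant > sig$mean_mother))
  # comparison counts equal the per-subject pair recount
  sp1 <- het$tests$species[1]
  al <- co$haplotypes[[sp1]]
  md <- co$metadata
  subj <- md$subject_id[match(names(al$sequences), md$sample_id)]
  ref <- sum(vapply(split(seq_along(subj), subj),
                    function(ii) choose(length(ii), 2), numeric(1)))
  expect_equal(sum(het$values$species == sp1), ref)
})

test_that("identical longitudinal haplotypes give no heterogeneity signal", {
  pool <- lapply(uniform_pool(1), function(s) { s$within_strain_mut_rate <- 0; s })
  co <- generate_cohort(cohort_config(
    n_studies = 1, dyads_per_study = 8, species_pool = pool,
    mother_strain_replacement = 0, gap_rate = 0, haplotype_length = 100,
    n_population_strains = 10,
    mother_timepoints = data.frame(day = c(3, 60), scale = "postnatal"),
    seed = 8))
  het <- suppressMessages(intra_subject_heterogeneity(co$haplotypes,
                                                      co$metadata))
  expect_true(all(het$values$similarity == 1))
  if (nrow(het$tests) > 0) expect_true(all(het$tests$p_value == 1))
})

test_that("shared-strain dynamics report prevalence and an age trend", {
  # strong continual-exposure configuration: postnatal acquisitions of
  # mother-carried species always copy the maternal strain, so shared
  # strain counts must grow with infant age
  co <- cached("late_trend", {
    pool <- lapply(uniform_pool(0.4),
                   function(s) { s$prevalence_infant_base <- 0.6; s })
    generate_cohort(cohort_config(n_studies = 2, dyads_per_study = 15,
                                  species_pool = pool,
                                  late_transmission_prob = 1,
                                  haplotype_length = 500,
                                  n_population_strains = 60, seed = 23))
  })
  pd <- cohort_pairing(co)
  calls <- call_transmission(co$haplotypes, pd$pairing)
  dyn <- shared_strain_dynamics(calls, pd$metadata)
  expect_gt(dyn$slope, 0)
  expect_lt(dyn$p_value, 0.01)
  # prevalence equals a brute-force recount for one (bin, species)
  r1 <- dyn$prevalence[which.max(dyn$prevalence$n_evaluable), ]
  bin_of <- stats::setNames(pd$metadata$time_bin, pd$metadata$sample_id)
  sub <- calls[calls$species == r1$species &
                 bin_of[calls$infant_sample] == r1$time_bin, ]
  expect_equal(r1$prevalence, mean(sub$shared))
  expect_equal(r1$n_evaluable, nrow(sub))
  # all-shared configuration: prevalence 1 in every bin (faithful copies,
  # no environmental acquisition)
  pool <- lapply(uniform_pool(1), function(s) {
    s$prevalence_infant_base <- 0
    s$prevalence_mother <- 0.9
    s$within_strain_mut_rate <- 0
    s
  })
  co1 <- generate_cohort(cohort_config(
    n_studies = 1, dyads_per_study = 8, species_pool = pool,
    haplotype_length = 150, n_population_strains = 20, seed = 4))
  pd1 <- cohort_pairing(co1)
  calls1 <- call_transmission(co1$haplotypes, pd1$pairing)
  dyn1 <- shared_strain_dynamics(calls1, pd1$metadata)
  expect_true(all(dyn1$prevalence$prevalence == 1))
})

test_that("shared strains carry more pathway abundance when coupled", {
  co <- small_cohort()
  pd <- cohort_pairing(co)
  calls <- call_transmission(co$haplotypes, pd$pairing)
  res <- shared_function_contrast(calls, co$pathways_stratified,
                                  pd$metadata)
  expect_gt(nrow(res), 0)
  # attributed sums equal a recount over the map for one sample/pathway
  s1 <- calls$infant_sample[1]
  shared_sp <- calls$species[calls$infant_sample == s1 & calls$shared]
  strat_sp <- sub(".*s__", "", rownames(co$pathways_stratified))
  pw <- sub("\\|.*$", "", rownames(co$pathways_stratified))
  p1 <- res$pathway[1]
  ref <- sum(co$pathways_stratified[pw == p1 & strat_sp %in% shared_sp, s1])
  # identical maps for shared/non-shared give no significant categories
  flat <- calls; flat$shared <- TRUE
  res_flat <- shared_function_contrast(flat, co$pathways_stratified,
                                       pd$metadata)
  # all non-shared mass is zero -> direction trivially 'shared'; no
  # contrast exists when the split is degenerate both ways
  expect_true(all(res_flat$mean_nonshared == 0))
})
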