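toy_metadata <- function() {
  data.frame(
    sample_id = c("m0", "m3", "m200", "i1", "i2", "i30"),
    subject_id = c("M1", "M1", "M1", "I1", "I1", "I1"),
    dyad_id = "d1", role = c(rep("mother", 3), rep("infant", 3)),
    study_id = "S1", day = c(0, 3, 200, 1, 2, 30),
    day_scale = "postnatal", stringsAsFactors = FALSE)
}

test_that("dyad pairing picks the nearest windowed maternal sample", {
  md <- toy_metadata()
  pr <- pair_dyads(md)
  # infant day 2: |0-2| = 2 vs |3-2| = 1 -> day-3 sample
  expect_equal(pr$mother_sample[pr$infant_sample == "i2"], "m3")
  # infant day 1: tie |0-1| = |3-1|... no: 1 vs 2 -> day-0 sample
  expect_equal(pr$mother_sample[pr$infant_sample == "i1"], "m0")
  # exact tie: mother days 0 and 4, infant day 2 -> earliest wins
  md2 <- md[md$sample_id != "m3", ]
  md2 <- rbind(md2, transform(md2[1, ], sample_id = "m4", day = 4))
  pr2 <- pair_dyads(md2)
  expect_equal(pr2$mother_sample[pr2$infant_sample == "i2"], "m0")
  # mother sampled only at day 200: dyad excluded
  md3 <- toy_metadata()
  md3 <- md3[!md3$sample_id %in% c("m0", "m3"), ]
  expect_message(pr3 <- pair_dyads(md3), "excluded")
  expect_equal(nrow(pr3), 0)
})

test_that("pairing on a synthetic cohort equals a brute-force recount", {
  co <- small_cohort()
  pd <- cohort_pairing(co)
  md <- pd$metadata
  n_inf <- sum(md$role == "infant")
  has_deliv <- tapply(md$role == "mother" & md$day_scale == "postnatal" &
                        md$day <= 7, md$dyad_id, any)
  expect_equal(nrow(pd$pairing),
               sum(md$role == "infant" & has_deliv[md$dyad_id]))
})

test_that("shared features follow presence/absence logic", {
  m <- c(A = 1, B = 2, C = 3, D = 0)
  i <- c(A = 0, B = 1, C = 4, D = 5)
  sf <- shared_features(m, i)
  expect_equal(sort(sf$shared_features), c("B", "C"))
  expect_equal(sf$shared_fraction_infant, 2 / 3)
  expect_equal(sf$shared_fraction_mother, 2 / 3)
  empty <- shared_features(m, c(A = 0, B = 0, C = 0, D = 0))
  expect_equal(empty$n_shared, 0)
  expect_equal(empty$shared_fraction_infant, 0)
})

test_that("shared set contains the transmitted set on synthetic data", {
  co <- small_cohort()
  pd <- cohort_pairing(co)
  sh <- compute_sharing(co$species, pd$pairing)
  shared_keys <- unique(paste(sh$features$dyad_id,
                              sub(".*s__", "", sh$features$feature_id)))
  tr_keys <- paste(co$truth$transmitted$dyad_id,
                   co$truth$transmitted$species)
  expect_true(all(tr_keys %in% shared_keys))
  # pair-level fractions equal brute-force recomputation
  vals <- co$species$values
  for (j in sample(nrow(sh$pairs), 10)) {
    p <- sh$pairs[j, ]
    ref <- shared_features(vals[, p$mother_sample], vals[, p$infant_sample])
    expect_equal(p$n_shared, ref$n_shared)
    expect_equal(p$shared_fraction_infant, ref$shared_fraction_infant)
  }
})

test_that("core set requires sharing in every study and is monotone", {
  feats <- data.frame(
    dyad_id = c("d1", "d2", "d3", "d1", "d2", "d1", "d2", "d3"),
    infant_sample = "x",
    feature_id = c("X", "X", "X", "Y", "Y", "Z", "Z", "Z"),
    stringsAsFactors = FALSE)
  pairs <- data.frame(dyad_id = c("d1", "d2", "d3"),
                      study_id = c("S1", "S2", "S3"),
                      stringsAsFactors = FALSE)
  sh <- structure(list(pairs = pairs, features = feats,
                       feature_kind = "taxon"), class = "sharing_records")
  cs <- core_shared_set(sh)
  expect_true(all(c("X", "Z") %in% cs$core_species))
  expect_false("Y" %in% cs$core_species)       # missing from study 3
  expect_equal(unname(cs$prevalence_across_dyads["Y"]), 2 / 3)
  cs2 <- core_shared_set(sh, min_dyads_per_study = 2)
  expect_true(all(cs2$core_species %in% cs$core_species))
})

test_that("a highly transmitted species is recovered in the core set", {
  co <- cached("core_recovery", generate_cohort(cohort_config(
    n_studies = 3, dyads_per_study = 12, haplotype_length = 60,
    n_population_strains = 20,
    species_pool = default_species_pool(transmission_prob = 0.9,
                                        delivery_effect = 1), seed = 77)))
  pd <- cohort_pairing(co)
  sh <- compute_sharing(co$species, pd$pairing)
  cs <- core_shared_set(sh)
  bl <- grep("Bifidobacterium_longum", rownames(co$species$values),
             value = TRUE)
  expect_true(bl %in% cs$core_species)
})

test_that("related dyads are compositionally closer than unrelated ones", {
  co <- cached("related", generate_cohort(cohort_config(
    n_studies = 3, dyads_per_study = 10, haplotype_length = 60,
    n_population_strains = 20,
    species_pool = uniform_pool(0.8), seed = 13)))
  pd <- cohort_pairing(co)
  rv <- related_vs_unrelated_similarity(co$species, pd$pairing,
                                        alternative = "less")
  expect_lt(rv$test$p.value, 0.01)
  expect_lt(mean(rv$related), mean(rv$unrelated))
  # two dyads with identical mother profiles: identical distributions
  m <- matrix(c(50, 50, 50, 50, 80, 20, 30, 70), 2, 4,
              dimnames = list(c("a", "b"), c("mA", "mB", "iA", "iB")))
  pr <- data.frame(dyad_id = c("dA", "dB"), infant_sample = c("iA", "iB"),
                   mother_sample = c("mA", "mB"), infant_day = 1,
                   mother_day = 0, study_id = "S1")
  rv2 <- related_vs_unrelated_similarity(m, pr)
  expect_equal(sort(rv2$related), sort(rv2$unrelated))
  expect_error(related_vs_unrelated_similarity(m, pr[1, ]), "two dyads")
})

test_that("pathway sharing dominates species sharing in every bin", {
  co <- small_cohort()
  pd <- cohort_pairing(co)
  sh_sp <- compute_sharing(co$species, pd$pairing)
  sh_pw <- compute_sharing(co$pathways, pd$pairing)
  dyn <- shared_fraction_dynamics(list(species = sh_sp, pathways = sh_pw),
                                  pd$metadata, quadratic_fit = TRUE)
  bb <- dyn$by_bin
  for (b in unique(bb$time_bin)) {
    expect_gte(bb$mean_fraction[bb$kind == "pathways" & bb$time_bin == b],
               bb$mean_fraction[bb$kind == "species" & bb$time_bin == b])
  }
  expect_true(all(bb$ci_lo <= bb$mean_fraction))
  expect_named(dyn$fits, c("species", "pathways"))
  # one dyad with identical profiles: both fractions 1
  m <- matrix(c(1, 2, 1, 2), 2, 2,
              dimnames = list(c("f1", "f2"), c("mom", "kid")))
  pr1 <- data.frame(dyad_id = "d", infant_sample = "kid",
                    mother_sample = "mom", infant_day = 5, mother_day = 0,
                    study_id = "S1")
  one <- compute_sharing(m, pr1)
  expect_equal(one$pairs$shared_fraction_infant, 1)
  expect_equal(one$pairs$shared_fraction_mother, 1)
})

test_that("shared-species counts rise with infant age", {
  co <- small_cohort()
  pd <- cohort_pairing(co)
  sh <- compute_sharing(co$species, pd$pairing)
  tr <- shared_count_vs_age(sh)
  expect_gt(tr$slope, 0)
  expect_lt(tr$p_value, 0.05)
  # closed-form OLS slope on the exported points
  pts <- tr$points
  slope_ref <- stats::cov(pts$age_days, pts$n_shared) /
    stats::var(pts$age_days)
  expect_equal(tr$slope, slope_ref, tolerance = 1e-9)
  # constant profiles: slope indistinguishable from zero
  flat <- sh
  flat$pairs$n_shared <- 7L
  tr0 <- suppressWarnings(shared_count_vs_age(flat))  # perfect-fit warning
  expect_equal(tr0$slope, 0, tolerance = 1e-12)
})
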