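# Shared fixture cohorts, generated once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small fast cohort with default (heterogeneous) species pool
small_cohort <- function() cached("small", {
  generate_cohort(cohort_config(n_studies = 2, dyads_per_study = 10,
                                haplotype_length = 300,
                                n_population_strains = 60, seed = 101))
})

# uniform calibration pool: every species transmits at `p`, no
# delivery-mode modifier
uniform_pool <- function(p) default_species_pool(transmission_prob = p,
                                                 delivery_effect = 1)

# the transmission-calibration study conditions: 3 studies x 50 dyads,
# within-strain mutation 0.001, between-strain divergence 0.05,
# transmission probability 0.6
# The late-transmission (continual exposure) channel is off so that the
# single configured birth-transmission rate is the quantity estimated.
calibration_cohort <- function() cached("calibration", {
  generate_cohort(cohort_config(n_studies = 3, dyads_per_study = 50,
                                species_pool = uniform_pool(0.6),
                                late_transmission_prob = 0,
                                seed = 2024))
})

# convenience: binned metadata + delivery-window pairing for a cohort
cohort_pairing <- function(cohort) {
  md <- assign_time_bins(cohort$metadata)
  list(metadata = md, pairing = suppressMessages(pair_dyads(md)))
}

# strong maternal signal: carriers almost always transmit
signal_task <- function() cached("signal_task", {
  co <- generate_cohort(cohort_config(
    n_studies = 3, dyads_per_study = 15,
    species_pool = uniform_pool(0.95), haplotype_length = 60,
    n_population_strains = 20, seed = 19))
  pd <- cohort_pairing(co)
  sh <- compute_sharing(co$species, pd$pairing)
  suppressMessages(prediction_tasks(co$species, pd$pairing, sh,
                                    pd$metadata))
})

# dyad-level aggregation of transmission calls: shared at any infant
# timepoint
calls_by_dyad <- function(calls) {
  agg <- stats::aggregate(shared ~ dyad_id + species,
                          data = calls[!is.na(calls$shared), ], FUN = any)
  agg
}

# Brute-force oracle for the blocked rank-sum test: exhaustive within-block
# reassignment of group-1 positions, two-sided p for the centred rank-sum.
brute_blocked_p <- function(values, groups, blocks) {
  lev <- sort(unique(groups))
  idx <- split(seq_along(values), blocks)
  block_stats <- lapply(idx, function(ii) {
    v <- values[ii]; n1 <- sum(groups[ii] == lev[1])
    r <- rank(v)
    list(r = r, n1 = n1, E = n1 * (length(ii) + 1) / 2)
  })
  obs <- sum(vapply(seq_along(idx), function(b) {
    ii <- idx[[b]]
    sum(rank(values[ii])[groups[ii] == lev[1]]) - block_stats[[b]]$E
  }, numeric(1)))
  per_block <- lapply(block_stats, function(bs) {
    cmb <- utils::combn(length(bs$r), bs$n1)
    apply(cmb, 2, function(j) sum(bs$r[j]) - bs$E)
  })
  grid <- do.call(expand.grid, per_block)
  tot <- rowSums(as.matrix(grid))
  mean(abs(tot) >= abs(obs) - 1e-9)
}
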