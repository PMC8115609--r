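#' Specify one species of the synthetic cohort
#'
#' Parameters of the generative model for a single species: how often mothers
#' and infants carry it, its log-normal relative-abundance distribution, the
#' probability that a mother-carried species seeds her infant at birth
#' (vertical transmission), the per-site substitution rates that separate a
#' faithfully transmitted haplotype copy (`within_strain_mut_rate`) from
#' unrelated population strains (`between_strain_divergence`), and the
#' covariate modifiers: `delivery_effect` multiplies the transmission
#' probability for C-section births (and scales early infant abundance with
#' an effect that decays linearly to nothing by day 365), `feeding_effect`
#' multiplies environmental colonization for non-exclusively breastfed
#' infants.
#'
#' @param name full MetaPhlAn-style clade string ending in `s__...`.
#' @param prevalence_mother,prevalence_infant_base carriage probabilities.
#' @param abundance_logmean,abundance_logsd log-scale normal parameters of
#'   the (pre-normalization) abundance draw.
#' @param transmission_prob probability a mother-carried species is
#'   vertically transmitted.
#' @param within_strain_mut_rate per-site substitution probability applied to
#'   each sampled copy of a strain (sequencing/drift noise and transmission
#'   bottleneck combined).
#' @param between_strain_divergence per-site divergence of unrelated
#'   population strains from the species ancestor; must exceed
#'   `within_strain_mut_rate` (separability assumption, checked at
#'   generation).
#' @param delivery_effect,feeding_effect covariate multipliers (see above).
#' @return a `species_spec` list.
#' @export
species_spec <- function(name,
                         prevalence_mother = 0.5,
                         prevalence_infant_base = 0.2,
                         abundance_logmean = 0,
                         abundance_logsd = 1,
                         transmission_prob = 0.5,
                         within_strain_mut_rate = 0.001,
                         between_strain_divergence = 0.05,
                         delivery_effect = 1,
                         feeding_effect = 1) {
  probs <- c(prevalence_mother = prevalence_mother,
             prevalence_infant_base = prevalence_infant_base,
             transmission_prob = transmission_prob,
             within_strain_mut_rate = within_strain_mut_rate,
             between_strain_divergence = between_strain_divergence)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1] for species ", name)
  if (delivery_effect < 0 || feeding_effect < 0)
    stop("effect multipliers must be non-negative")
  structure(list(name = name,
                 prevalence_mother = prevalence_mother,
                 prevalence_infant_base = prevalence_infant_base,
                 abundance_logmean = abundance_logmean,
                 abundance_logsd = abundance_logsd,
                 transmission_prob = transmission_prob,
                 within_strain_mut_rate = within_strain_mut_rate,
                 between_strain_divergence = between_strain_divergence,
                 delivery_effect = delivery_effect,
                 feeding_effect = feeding_effect),
            class = "species_spec")
}

# Fixed taxonomy scaffold used by the default pool.
.tax <- function(phylum, class, order, family, genus, species) {
  sprintf("k__Bacteria|p__%s|c__%s|o__%s|f__%s|g__%s|s__%s_%s",
          phylum, class, order, family, genus, genus, species)
}

#' Default species pool
#'
#' A fixed pool of 32 species mirroring the taxa that dominate mother-infant
#' gut studies: Bacteroides and Bifidobacterium species with high maternal
#' prevalence and high transmission, suppressed under C-section
#' (`delivery_effect` < 1); skin/hospital-associated taxa (Staphylococcus,
#' Klebsiella, Veillonella, Haemophilus, Clostridium, Rothia) enriched under
#' C-section (`delivery_effect` > 1, applied to infant abundance only since
#' transmission probabilities are capped at 1); and adult-gut commensals
#' (Faecalibacterium, Eubacterium, Alistipes, Roseburia, Subdoligranulum)
#' common in mothers but rarely transmitted.
#'
#' @param transmission_prob optional single value overriding every species'
#'   transmission probability (used for calibration studies).
#' @param delivery_effect optional single value overriding every species'
#'   delivery-mode multiplier.
#' @return list of [species_spec()] objects.
#' @export
default_species_pool <- function(transmission_prob = NULL,
                                 delivery_effect = NULL) {
  bac <- function(sp, prev, tr) species_spec(
    .tax("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Bacteroidaceae",
         "Bacteroides", sp),
    prevalence_mother = prev, prevalence_infant_base = 0.15,
    abundance_logmean = 1.2, abundance_logsd = 1,
    transmission_prob = tr, delivery_effect = 0.3)
  bif <- function(sp, prev, tr) species_spec(
    .tax("Actinobacteria", "Actinobacteria", "Bifidobacteriales",
         "Bifidobacteriaceae", "Bifidobacterium", sp),
    prevalence_mother = prev, prevalence_infant_base = 0.35,
    abundance_logmean = 1.5, abundance_logsd = 1,
    transmission_prob = tr, delivery_effect = 0.35)
  csa <- function(phy, cls, ord, fam, gen, sp, prev, base) species_spec(
    .tax(phy, cls, ord, fam, gen, sp),
    prevalence_mother = prev, prevalence_infant_base = base,
    abundance_logmean = 0.5, abundance_logsd = 1,
    transmission_prob = 0.2, delivery_effect = 1.8)
  adu <- function(phy, cls, ord, fam, gen, sp, prev) species_spec(
    .tax(phy, cls, ord, fam, gen, sp),
    prevalence_mother = prev, prevalence_infant_base = 0.08,
    abundance_logmean = 0.8, abundance_logsd = 1,
    transmission_prob = 0.15, delivery_effect = 1)
  pool <- c(
    list(bac("uniformis", 0.75, 0.7), bac("vulgatus", 0.7, 0.7),
         bac("dorei", 0.6, 0.6), bac("fragilis", 0.45, 0.6),
         bac("ovatus", 0.55, 0.55), bac("thetaiotaomicron", 0.5, 0.5),
         bac("caccae", 0.4, 0.5), bac("stercoris", 0.25, 0.4),
         bif("longum", 0.75, 0.75), bif("bifidum", 0.5, 0.6),
         bif("breve", 0.4, 0.6), bif("adolescentis", 0.6, 0.55),
         bif("pseudocatenulatum", 0.45, 0.55)),
    list(
      species_spec(.tax("Proteobacteria", "Gammaproteobacteria",
                        "Enterobacteriales", "Enterobacteriaceae",
                        "Escherichia", "coli"),
                   prevalence_mother = 0.65, prevalence_infant_base = 0.5,
                   abundance_logmean = 1, abundance_logsd = 1.2,
                   transmission_prob = 0.65, delivery_effect = 0.5),
      species_spec(.tax("Firmicutes", "Bacilli", "Lactobacillales",
                        "Enterococcaceae", "Enterococcus", "faecalis"),
                   prevalence_mother = 0.35, prevalence_infant_base = 0.45,
                   abundance_logmean = 0.5, abundance_logsd = 1,
                   transmission_prob = 0.45),
      species_spec(.tax("Firmicutes", "Bacilli", "Lactobacillales",
                        "Streptococcaceae", "Streptococcus", "salivarius"),
                   prevalence_mother = 0.7, prevalence_infant_base = 0.6,
                   abundance_logmean = 0.8, abundance_logsd = 0.9,
                   transmission_prob = 0.6),
      species_spec(.tax("Firmicutes", "Bacilli", "Lactobacillales",
                        "Streptococcaceae", "Streptococcus", "parasanguinis"),
                   prevalence_mother = 0.5, prevalence_infant_base = 0.45,
                   abundance_logmean = 0.3, abundance_logsd = 0.9,
                   transmission_prob = 0.5),
      species_spec(.tax("Bacteroidetes", "Bacteroidia", "Bacteroidales",
                        "Porphyromonadaceae", "Parabacteroides",
                        "distasonis"),
                   prevalence_mother = 0.6, prevalence_infant_base = 0.12,
                   abundance_logmean = 0.8, abundance_logsd = 1,
                   transmission_prob = 0.6, delivery_effect = 0.3),
      species_spec(.tax("Bacteroidetes", "Bacteroidia", "Bacteroidales",
                        "Porphyromonadaceae", "Parabacteroides", "merdae"),
                   prevalence_mother = 0.5, prevalence_infant_base = 0.1,
                   abundance_logmean = 0.6, abundance_logsd = 1,
                   transmission_prob = 0.55, delivery_effect = 0.3),
      species_spec(.tax("Actinobacteria", "Coriobacteriia",
                        "Coriobacteriales", "Coriobacteriaceae",
                        "Collinsella", "aerofaciens"),
                   prevalence_mother = 0.55, prevalence_infant_base = 0.15,
                   abundance_logmean = 0.5, abundance_logsd = 1,
                   transmission_prob = 0.5),
      species_spec(.tax("Verrucomicrobia", "Verrucomicrobiae",
                        "Verrucomicrobiales", "Verrucomicrobiaceae",
                        "Akkermansia", "muciniphila"),
                   prevalence_mother = 0.35, prevalence_infant_base = 0.08,
                   abundance_logmean = 0.4, abundance_logsd = 1,
                   transmission_prob = 0.35)),
    list(
      csa("Firmicutes", "Bacilli", "Bacillales", "Staphylococcaceae",
          "Staphylococcus", "epidermidis", 0.15, 0.5),
      csa("Proteobacteria", "Gammaproteobacteria", "Enterobacteriales",
          "Enterobacteriaceae", "Klebsiella", "pneumoniae", 0.2, 0.4),
      csa("Firmicutes", "Negativicutes", "Selenomonadales",
          "Veillonellaceae", "Veillonella", "parvula", 0.4, 0.45),
      csa("Proteobacteria", "Gammaproteobacteria", "Pasteurellales",
          "Pasteurellaceae", "Haemophilus", "parainfluenzae", 0.3, 0.4),
      csa("Firmicutes", "Clostridia", "Clostridiales", "Clostridiaceae",
          "Clostridium", "bolteae", 0.3, 0.35),
      csa("Actinobacteria", "Actinobacteria", "Actinomycetales",
          "Micrococcaceae", "Rothia", "mucilaginosa", 0.15, 0.3)),
    list(
      adu("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae",
          "Faecalibacterium", "prausnitzii", 0.8),
      adu("Firmicutes", "Clostridia", "Clostridiales", "Eubacteriaceae",
          "Eubacterium", "rectale", 0.7),
      adu("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Rikenellaceae",
          "Alistipes", "finegoldii", 0.55),
      adu("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae",
          "Roseburia", "inulinivorans", 0.5),
      adu("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae",
          "Subdoligranulum", "variabile", 0.6),
      adu("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae",
          "Blautia", "wexlerae", 0.65),
      adu("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae",
          "Ruminococcus", "torques", 0.6)))
  if (!is.null(transmission_prob))
    pool <- lapply(pool, function(s) { s$transmission_prob <- transmission_prob; s })
  if (!is.null(delivery_effect))
    pool <- lapply(pool, function(s) { s$delivery_effect <- delivery_effect; s })
  pool
}

#' Configure a synthetic multi-study dyad cohort
#'
#' @param n_studies number of studies (cohorts); each gets its own
#'   species-abundance intercepts so studies are distinguishable.
#' @param dyads_per_study mother-infant pairs per study (one infant each).
#' @param infant_timepoints postnatal sampling days per infant.
#' @param mother_timepoints data.frame with columns `day`, `scale`
#'   (gestational/postnatal) of maternal sampling; the default samples each
#'   mother in pregnancy (gestational day 200) and at delivery (postnatal
#'   day 3).
#' @param species_pool list of [species_spec()].
#' @param pathway_map optional data.frame (`species` key, `pathway`,
#'   `weight`) coupling pathways to carrier species; generated from the seed
#'   when `NULL`.
#' @param n_pathways number of pathways when generating the map.
#' @param pathway_prob probability a given pathway is encoded by a given
#'   species in the generated map.
#' @param haplotype_length aligned marker-gene SNP-haplotype length (sites).
#' @param n_population_strains size of the circulating strain population per
#'   species from which unrelated strains are drawn.
#' @param p_csection per-dyad probability of Cesarean delivery.
#' @param p_exclusive_bf per-infant probability of exclusive breastfeeding.
#' @param mother_strain_replacement probability that a mother's dominant
#'   strain of a species is replaced by an unrelated strain between
#'   consecutive maternal timepoints (infant strains are stable).
#' @param late_transmission_prob continual-exposure channel: when an infant
#'   acquires a mother-carried species postnatally (the environmental
#'   onset model), the acquired strain is a copy of the mother's strain
#'   with probability `late_transmission_prob * transmission_prob` of the
#'   species; such events count as vertical transmission in the ground
#'   truth and make shared-strain counts grow with infant age. Set to 0 to
#'   isolate birth transmission (the calibration setting).
#' @param gap_rate per-site probability that a haplotype position is masked
#'   as a gap (missing SNP call) in an emitted record.
#' @param seed integer; fully determines the generated cohort.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_studies = 3,
                          dyads_per_study = 30,
                          infant_timepoints = c(1, 5, 21, 60, 120, 330),
                          mother_timepoints = data.frame(
                            day = c(200, 3),
                            scale = c("gestational", "postnatal"),
                            stringsAsFactors = FALSE),
                          species_pool = default_species_pool(),
                          pathway_map = NULL,
                          n_pathways = 120,
                          pathway_prob = 0.15,
                          haplotype_length = 1000,
                          n_population_strains = 200,
                          p_csection = 0.3,
                          p_exclusive_bf = 0.6,
                          mother_strain_replacement = 0.3,
                          late_transmission_prob = 0.5,
                          gap_rate = 0.01,
                          seed = 1) {
  if (n_studies < 1 || dyads_per_study < 1)
    stop("need at least one study and one dyad per study")
  if (length(species_pool) == 0) stop("empty species pool")
  if (!all(vapply(species_pool, inherits, logical(1), "species_spec")))
    stop("species_pool must be a list of species_spec objects")
  if (any(infant_timepoints < 0) || any(mother_timepoints$day < 0))
    stop("sampling days must be non-negative")
  if (!all(mother_timepoints$scale %in% c("gestational", "postnatal")))
    stop("mother timepoint scale must be gestational or postnatal")
  probs <- c(p_csection, p_exclusive_bf, mother_strain_replacement,
             late_transmission_prob, gap_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(n_studies = n_studies, dyads_per_study = dyads_per_study,
                 infant_timepoints = sort(infant_timepoints),
                 mother_timepoints = mother_timepoints,
                 species_pool = species_pool, pathway_map = pathway_map,
                 n_pathways = n_pathways, pathway_prob = pathway_prob,
                 haplotype_length = haplotype_length,
                 n_population_strains = n_population_strains,
                 p_csection = p_csection, p_exclusive_bf = p_exclusive_bf,
                 mother_strain_replacement = mother_strain_replacement,
                 late_transmission_prob = late_transmission_prob,
                 gap_rate = gap_rate, seed = as.integer(seed)),
            class = "cohort_config")
}

# per-site substitution at `rate`; integer alphabet 1..4
mutate_seq <- function(x, rate) {
  if (rate <= 0) return(x)
  nm <- stats::rbinom(1L, length(x), rate)
  if (nm == 0L) return(x)
  sites <- sample.int(length(x), nm)
  x[sites] <- 1L + (x[sites] - 1L + sample.int(3L, nm, replace = TRUE)) %% 4L
  x
}

int_to_hap <- function(x) {
  paste(c("-", "A", "C", "G", "T")[x + 1L], collapse = "")
}

#' Generate a synthetic mother-infant cohort
#'
#' Simulates a multi-study cohort of mother-infant dyads with known ground
#' truth. Mothers carry species per `prevalence_mother`; each mother-carried
#' species is vertically transmitted to the infant with probability
#' `transmission_prob` (times `delivery_effect` for C-section births), in
#' which case the infant's dominant-strain haplotype is a copy of the
#' mother's delivery-sample haplotype mutated at `within_strain_mut_rate`.
#' Non-transmitted colonization draws an unrelated strain from the species'
#' circulating population and starts at a uniformly distributed onset age,
#' so infant richness and mother-infant sharing grow with age. Abundances
#' are log-normal with per-study intercepts and are renormalized to percent.
#' Pathway profiles are derived from species profiles through the pathway
#' map, giving the species-to-function coupling that makes shared-pathway
#' fractions dominate shared-species fractions.
#'
#' @param config a [cohort_config()].
#' @return a `dyad_cohort` list with elements `species` (abund_table,
#'   percent), `pathways` (community-level abund_table, percent),
#'   `pathways_stratified` (matrix with `|g__...s__...` suffixed rows on the
#'   community percent scale), `haplotypes` (named list of
#'   `haplotype_alignment`, one per species observed in at least one
#'   sample), `metadata` (data.frame), `truth` (list: `transmitted`
#'   data.frame of dyad_id/species, `strain_identity` data.frame of
#'   sample_id/species/lineage, `transmission_prob` named per-species
#'   vector), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  pool <- config$species_pool
  S <- length(pool)
  for (sp in pool)
    if (sp$within_strain_mut_rate >= sp$between_strain_divergence)
      stop("separability violated for ", sp$name,
           ": within_strain_mut_rate must be < between_strain_divergence")
  set.seed(config$seed)
  clade <- vapply(pool, `[[`, character(1), "name")
  skey <- species_key(clade)
  genus <- vapply(strsplit(clade, "|", fixed = TRUE),
                  function(p) sub("^g__", "", p[6L]), character(1))
  L <- config$haplotype_length
  K <- config$n_population_strains

  # pathway map: species -> weighted pathway set
  pmap <- config$pathway_map
  if (is.null(pmap)) {
    pw <- sprintf("PWY-%04d", 1000 + seq_len(config$n_pathways))
    carry <- matrix(stats::runif(S * config$n_pathways) < config$pathway_prob,
                    nrow = S)
    for (s in seq_len(S))  # every species encodes at least 3 pathways
      if (sum(carry[s, ]) < 3L)
        carry[s, sample.int(config$n_pathways, 3L)] <- TRUE
    idx <- which(carry, arr.ind = TRUE)
    pmap <- data.frame(species = skey[idx[, 1L]], pathway = pw[idx[, 2L]],
                       weight = stats::runif(nrow(idx), 0.5, 1.5),
                       stringsAsFactors = FALSE)
  }
  if (!all(pmap$species %in% skey))
    stop("pathway_map references unknown species")

  # circulating strain population: ancestral sequence per species, K strains
  lineage_seqs <- vector("list", S)
  for (s in seq_len(S)) {
    anc <- sample.int(4L, L, replace = TRUE)
    m <- matrix(0L, nrow = K, ncol = L)
    for (k in seq_len(K))
      m[k, ] <- mutate_seq(anc, pool[[s]]$between_strain_divergence)
    lineage_seqs[[s]] <- m
  }

  # per-study x species abundance intercepts (cohort effects)
  study_ids <- sprintf("S%d", seq_len(config$n_studies))
  study_shift <- matrix(stats::rnorm(config$n_studies * S, 0, 0.6),
                        nrow = config$n_studies,
                        dimnames = list(study_ids, skey))

  mt <- config$mother_timepoints
  # chronological order: gestational sampling precedes postnatal
  mt <- mt[order(ifelse(mt$scale == "gestational", mt$day - 1e6, mt$day)), ,
           drop = FALSE]
  n_mt <- nrow(mt)
  it <- config$infant_timepoints
  n_it <- length(it)
  # index of the maternal delivery-window sample used as transmission source
  post <- which(mt$scale == "postnatal")
  deliv_idx <- if (length(post)) post[which.min(mt$day[post])] else n_mt
  max_it <- max(it)

  n_dyads <- config$n_studies * config$dyads_per_study
  n_samples <- n_dyads * (n_mt + n_it)
  ab <- matrix(0, nrow = S, ncol = n_samples)
  sample_ids <- character(n_samples)
  meta_rows <- list()
  hap_seqs <- lapply(seq_len(S), function(s) list())
  hap_lineage <- lapply(seq_len(S), function(s) list())
  transmitted <- vector("list", n_dyads)

  prev_m <- vapply(pool, `[[`, numeric(1), "prevalence_mother")
  col <- 0L
  di <- 0L
  for (st in seq_len(config$n_studies)) for (d in seq_len(config$dyads_per_study)) {
    di <- di + 1L
    dyad <- sprintf("%s.D%02d", study_ids[st], d)
    csec <- stats::runif(1) < config$p_csection
    excl_bf <- stats::runif(1) < config$p_exclusive_bf
    cov <- list(
      delivery_mode = if (csec) "cesarean" else "vaginal",
      csection_type = if (csec) sample(c("elective", "emergency"), 1) else NA,
      feeding = if (excl_bf) "exclusive_bf" else "non_exclusive_bf",
      infant_antibiotics = stats::runif(1) < 0.2,
      gestational_age = sample(c("full-term", "preterm"), 1,
                               prob = c(0.9, 0.1)),
      maternal_age_class = sample(c("19-29", "30-34", "35-39", "40-50"), 1,
                                  prob = c(0.3, 0.35, 0.25, 0.1)),
      maternal_abx_before_delivery = stats::runif(1) < 0.15,
      maternal_intrapartum_abx = stats::runif(1) < (if (csec) 0.6 else 0.15),
      birth_weight_class = sample(c("low", "normal", "high"), 1,
                                  prob = c(0.1, 0.8, 0.1)),
      maternal_bmi_class = sample(c("normal", "owob"), 1, prob = c(0.7, 0.3)),
      sex = sample(c("F", "M"), 1))

    carrier <- stats::runif(S) < prev_m
    if (!any(carrier)) carrier[which.max(prev_m)] <- TRUE

    # maternal strain path across timepoints (possible replacement)
    m_lineage <- matrix(NA_integer_, nrow = n_mt, ncol = S)
    m_hap <- vector("list", S)
    for (s in which(carrier)) {
      lin <- sample.int(K, 1L)
      haps <- vector("list", n_mt)
      for (t in seq_len(n_mt)) {
        if (t > 1L && stats::runif(1) < config$mother_strain_replacement)
          lin <- sample.int(K, 1L)
        m_lineage[t, s] <- lin
        haps[[t]] <- mutate_seq(lineage_seqs[[s]][lin, ],
                                pool[[s]]$within_strain_mut_rate)
      }
      m_hap[[s]] <- haps
    }

    # transmission + environmental colonization of the infant
    trans <- logical(S)
    i_found <- vector("list", S)
    i_lineage <- rep(NA_integer_, S)
    onset <- rep(Inf, S)
    for (s in seq_len(S)) {
      spx <- pool[[s]]
      if (carrier[s]) {
        p_t <- spx$transmission_prob *
          (if (csec) spx$delivery_effect else 1)
        p_t <- min(max(p_t, 0), 1)
        trans[s] <- stats::runif(1) < p_t
      }
      if (trans[s]) {
        onset[s] <- 0
        i_lineage[s] <- m_lineage[deliv_idx, s]
        i_found[[s]] <- mutate_seq(m_hap[[s]][[deliv_idx]],
                                   spx$within_strain_mut_rate)
      } else {
        p_env <- spx$prevalence_infant_base *
          (if (!excl_bf) spx$feeding_effect else 1)
        if (stats::runif(1) < min(p_env, 1)) {
          onset[s] <- stats::runif(1, 0, max_it)
          late <- carrier[s] && stats::runif(1) <
            config$late_transmission_prob * spx$transmission_prob
          if (late) {
            # continual exposure: postnatal acquisition of the mother's
            # own strain; a vertical-transmission event with onset > 0
            trans[s] <- TRUE
            i_lineage[s] <- m_lineage[deliv_idx, s]
            i_found[[s]] <- mutate_seq(m_hap[[s]][[deliv_idx]],
                                       spx$within_strain_mut_rate)
          } else {
            lin <- sample.int(K, 1L)
            i_lineage[s] <- lin
            i_found[[s]] <- mutate_seq(lineage_seqs[[s]][lin, ],
                                       spx$within_strain_mut_rate)
          }
        }
      }
    }
    if (!any(onset <= it[1L])) {
      # guarantee a pioneer colonizer so no infant sample is empty
      s0 <- sample.int(S, 1L, prob = vapply(pool, `[[`, numeric(1),
                                            "prevalence_infant_base"))
      onset[s0] <- 0
      if (is.null(i_found[[s0]])) {
        lin <- sample.int(K, 1L)
        i_lineage[s0] <- lin
        i_found[[s0]] <- mutate_seq(lineage_seqs[[s0]][lin, ],
                                    pool[[s0]]$within_strain_mut_rate)
      }
    }
    transmitted[[di]] <- which(trans)

    emit <- function(sample_id, present, hap_of, lineage_of, day_for_decay,
                     is_infant) {
      col <<- col + 1L
      sample_ids[col] <<- sample_id
      vals <- numeric(S)
      for (s in which(present)) {
        v <- exp(stats::rnorm(1, pool[[s]]$abundance_logmean +
                                study_shift[st, s],
                              pool[[s]]$abundance_logsd))
        de <- pool[[s]]$delivery_effect
        if (is_infant && csec && de != 1) {
          frac <- min(day_for_decay, 365) / 365
          v <- v * (de + (1 - de) * frac)
        }
        vals[s] <- v
        hap <- hap_of(s)
        if (config$gap_rate > 0) {
          ng <- stats::rbinom(1L, L, config$gap_rate)
          if (ng > 0L) hap[sample.int(L, ng)] <- 0L
        }
        hap_seqs[[s]][[sample_id]] <<- hap
        hap_lineage[[s]][[sample_id]] <<- lineage_of(s)
      }
      ab[, col] <<- vals
    }

    msub <- paste0(dyad, ".M")
    for (t in seq_len(n_mt)) {
      sid <- sprintf("%s.%s%03d", msub,
                     if (mt$scale[t] == "gestational") "g" else "p",
                     mt$day[t])
      emit(sid, carrier, function(s) m_hap[[s]][[t]],
           function(s) m_lineage[t, s], 0, FALSE)
      meta_rows[[length(meta_rows) + 1L]] <- c(
        list(sample_id = sid, subject_id = msub, dyad_id = dyad,
             role = "mother", study_id = study_ids[st], day = mt$day[t],
             day_scale = mt$scale[t]), cov)
    }
    isub <- paste0(dyad, ".I")
    for (t in seq_len(n_it)) {
      sid <- sprintf("%s.p%03d", isub, it[t])
      present <- onset <= it[t]
      emit(sid, present,
           function(s) mutate_seq(i_found[[s]],
                                  pool[[s]]$within_strain_mut_rate),
           function(s) i_lineage[s], it[t], TRUE)
      meta_rows[[length(meta_rows) + 1L]] <- c(
        list(sample_id = sid, subject_id = isub, dyad_id = dyad,
             role = "infant", study_id = study_ids[st], day = it[t],
             day_scale = "postnatal"), cov)
    }
  }

  # percent-normalized species table
  cs <- colSums(ab)
  stopifnot(all(cs > 0))
  ab <- sweep(ab, 2L, cs, "/") * 100
  dimnames(ab) <- list(clade, sample_ids)
  species_tab <- abund_table(ab, "taxon")

  metadata <- do.call(rbind, lapply(meta_rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  metadata$sequencing_depth <- round(stats::rlnorm(nrow(metadata),
                                                   log(2e7), 0.4))

  # pathway tables derived from species profiles through the map
  W <- matrix(0, nrow = S, ncol = length(unique(pmap$pathway)),
              dimnames = list(skey, sort(unique(pmap$pathway))))
  W[cbind(match(pmap$species, skey), match(pmap$pathway, colnames(W)))] <-
    pmap$weight
  pa <- t(W) %*% ab
  pcs <- colSums(pa)
  pcs[pcs == 0] <- 1
  pa_norm <- sweep(pa, 2L, pcs, "/") * 100
  pathways_tab <- abund_table(pa_norm, "pathway")
  strat_rows <- sprintf("%s|g__%s.s__%s", pmap$pathway,
                        genus[match(pmap$species, skey)], pmap$species)
  strat <- (ab[match(pmap$species, skey), , drop = FALSE] * pmap$weight)
  strat <- sweep(strat, 2L, pcs, "/") * 100
  rownames(strat) <- strat_rows

  # haplotype alignments (character form), ground truth
  haplotypes <- list()
  ident <- list()
  for (s in seq_len(S)) {
    if (length(hap_seqs[[s]]) == 0L) next
    seqs <- vapply(hap_seqs[[s]], int_to_hap, character(1))
    haplotypes[[skey[s]]] <- haplotype_alignment(skey[s], seqs)
    ident[[skey[s]]] <- data.frame(
      sample_id = names(hap_lineage[[s]]),
      species = skey[s],
      lineage = sprintf("%s.L%03d", skey[s],
                        unlist(hap_lineage[[s]], use.names = FALSE)),
      stringsAsFactors = FALSE)
  }
  dyad_ids <- unique(metadata$dyad_id)
  tr_df <- do.call(rbind, lapply(seq_len(n_dyads), function(i) {
    if (length(transmitted[[i]]) == 0L) return(NULL)
    data.frame(dyad_id = dyad_ids[i], species = skey[transmitted[[i]]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(tr_df))
    tr_df <- data.frame(dyad_id = character(0), species = character(0),
                        stringsAsFactors = FALSE)

  structure(list(
    species = species_tab,
    pathways = pathways_tab,
    pathways_stratified = strat,
    haplotypes = haplotypes,
    metadata = metadata,
    truth = list(transmitted = tr_df,
                 strain_identity = do.call(rbind, ident),
                 transmission_prob = stats::setNames(
                   vapply(pool, `[[`, numeric(1), "transmission_prob"),
                   skey)),
    pathway_map = pmap,
    config = config), class = "dyad_cohort")
}

#' @export
print.dyad_cohort <- function(x, ...) {
  cat(sprintf(paste0("dyad_cohort: %d studies, %d dyads, %d samples, ",
                     "%d species, %d pathways\n"),
              x$config$n_studies,
              length(unique(x$metadata$dyad_id)),
              nrow(x$metadata), nrow(x$species$values),
              nrow(x$pathways$values)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits `species.tsv` (MetaPhlAn merged dialect), `pathways.tsv` (HUMAnN
#' joined dialect, community plus species-stratified rows), `metadata.tsv`,
#' `truth_transmitted.tsv`, `truth_strain_identity.tsv` and one aligned
#' FASTA per species under `haplotypes/`. Output is byte-identical for
#' identical cohorts.
#'
#' @param cohort a `dyad_cohort`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "dyad_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_metaphlan(cohort$species, file.path(out_dir, "species.tsv"))
  comb <- rbind(cohort$pathways$values, cohort$pathways_stratified)
  write_humann_pathways(comb, file.path(out_dir, "pathways.tsv"))
  write_sample_metadata(cohort$metadata, file.path(out_dir, "metadata.tsv"))
  utils::write.table(cohort$truth$transmitted,
                     file.path(out_dir, "truth_transmitted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$strain_identity,
                     file.path(out_dir, "truth_strain_identity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hd <- file.path(out_dir, "haplotypes")
  dir.create(hd, showWarnings = FALSE)
  for (al in cohort$haplotypes)
    write_haplotype_fasta(al, file.path(hd, paste0(al$species, ".aln.fasta")))
  invisible(out_dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list with `species`, `pathways` (community), `pathways_stratified`,
#'   `haplotypes`, `metadata`, `truth`.
#' @export
read_cohort <- function(dir) {
  haps <- list()
  hd <- file.path(dir, "haplotypes")
  for (f in list.files(hd, pattern = "\\.aln\\.fasta$", full.names = TRUE)) {
    al <- read_haplotype_fasta(f)
    haps[[al$species]] <- al
  }
  list(
    species = read_metaphlan(file.path(dir, "species.tsv")),
    pathways = read_humann_pathways(file.path(dir, "pathways.tsv"),
                                    drop_stratified = TRUE),
    pathways_stratified = read_humann_pathways(
      file.path(dir, "pathways.tsv"), stratified_only = TRUE)$values,
    haplotypes = haps,
    metadata = read_sample_metadata(file.path(dir, "metadata.tsv")),
    truth = list(
      transmitted = utils::read.delim(
        file.path(dir, "truth_transmitted.tsv"), stringsAsFactors = FALSE),
      strain_identity = utils::read.delim(
        file.path(dir, "truth_strain_identity.tsv"),
        stringsAsFactors = FALSE)))
}
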