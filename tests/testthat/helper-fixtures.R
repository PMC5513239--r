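# in-code fixtures shared across test files

# quick panel from allele matrices (rows = individuals)
quick_panel <- function(ids, sex, year, a1, a2, roles = NULL) {
  a1 <- matrix(a1, nrow = length(ids))
  a2 <- matrix(a2, nrow = length(ids))
  loci <- tibble::tibble(
    locus = paste0("L", seq_len(ncol(a1))),
    role = if (is.null(roles)) rep("primary", ncol(a1)) else roles)
  colnames(a1) <- colnames(a2) <- loci$locus
  geno_panel(tibble::tibble(id = ids, sex = sex, year = year,
                            sampled = TRUE), a1, a2, loci)
}

# uniform frequency table over n_alleles for n_loci loci named L1..Ln
uniform_freqs <- function(n_loci, n_alleles, start = 101L, step = 2L) {
  alleles <- start + step * (seq_len(n_alleles) - 1L)
  out <- rep(list(stats::setNames(rep(1 / n_alleles, n_alleles), alleles)),
             n_loci)
  names(out) <- paste0("L", seq_len(n_loci))
  attr(out, "loci") <- tibble::tibble(locus = names(out), role = "primary")
  class(out) <- "allele_freqs"
  out
}

# a small clean two-generation scenario with planted unsampled males
planted_scenario <- function(seed, n_plant = 2, age = 2, plant_sex = "male",
                             error_rate = 0, offspring_per_planted = 6,
                             n_adults = 30, n_offspring = 120) {
  cfg <- sim_config(
    years = c(2007L, 2007L + age)[c(1, 2)],
    n_females = n_adults, n_males = n_adults, n_offspring = n_offspring,
    loci = locus_spec(),
    error_rate = error_rate,
    plantings = if (n_plant > 0) {
      data.frame(sex = plant_sex, age = age, cohort = 2007, n = n_plant)
    },
    offspring_per_planted = offspring_per_planted, seed = seed)
  simulate_population(cfg)
}

# run the gtrio funnel (parentage -> pairs -> candidates -> confirmed ->
# retained) on a simulated scenario
gtrio_funnel <- function(sim, budget = 1, min_loci = 9) {
  asn <- assign_parents(sim$adults, sim$offspring, budget = budget,
                        min_loci = min_loci)
  pairs <- extract_mate_pairs(asn)
  cand <- find_gtrios(pairs, asn, sim$adults, sim$offspring)
  conf <- confirm_gtrios(cand, sim$adults, sim$offspring)
  res <- resolve_ambiguities(conf)
  list(assignments = asn, pairs = pairs, candidates = cand,
       confirmed = conf, retained = res$retained, resolved = res)
}

# fraction of planted adults recovered with correct sex, cohort and age
recovery_rate <- function(sim, funnel) {
  adults <- infer_unsampled_adults(funnel$retained)
  roster <- sim$truth$roster
  hit <- 0L
  for (i in seq_len(nrow(roster))) {
    m <- adults[adults$gp_female == roster$gp_female[i] &
                adults$gp_male == roster$gp_male[i], ]
    if (nrow(m) == 1 && m$sex == roster$sex[i] &&
        m$cohort == roster$cohort[i] && m$age == roster$age[i]) {
      hit <- hit + 1L
    }
  }
  hit / nrow(roster)
}
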