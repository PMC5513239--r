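#' @importFrom dplyr .data
NULL

# minimal one-cohort pedigree: HW founders + uniform-success offspring
sim_simple_pedigree <- function(freqs, n_mothers, n_fathers, n_offspring,
                                loci = NULL, year = 1L) {
  if (is.null(loci)) {
    loci <- attr(freqs, "loci")
    if (is.null(loci)) loci <- tibble::tibble(locus = names(freqs),
                                              role = "primary")
  }
  fem <- hw_draw(freqs, sprintf("F%04d", seq_len(n_mothers)), "female", year,
                 loci)
  mal <- hw_draw(freqs, sprintf("M%04d", seq_len(n_fathers)), "male", year,
                 loci)
  mi <- sample.int(n_mothers, n_offspring, replace = TRUE)
  fi <- sample.int(n_fathers, n_offspring, replace = TRUE)
  cross <- mendel_cross(fem$a1[mi, , drop = FALSE], fem$a2[mi, , drop = FALSE],
                        mal$a1[fi, , drop = FALSE], mal$a2[fi, , drop = FALSE])
  oid <- sprintf("J%05d", seq_len(n_offspring))
  list(adults = rbind_panels(fem, mal),
       offspring = geno_panel(tibble::tibble(id = oid, sex = "unknown",
                                             year = year, sampled = TRUE),
                              cross$a1, cross$a2, loci),
       parents = tibble::tibble(offspring = oid, mother = fem$ind$id[mi],
                                father = mal$ind$id[fi], year = year))
}

percent_one_unassigned <- function(assignments) {
  100 * mean(assignments$category %in%
             c("mother_unassigned", "father_unassigned"))
}

#' Expected percent of offspring with one unassigned parent due to
#' genotyping error
#'
#' Per replicate: simulate a clean single-cohort pedigree under uniform
#' reproductive success, inject genotyping error into both the adult and
#' offspring panels, run [assign_parents()], and record the percent of
#' offspring with *exactly* one unassigned parent (offspring missing both
#' parents are not counted). Returns the mean and Monte-Carlo SE over
#' replicates.
#'
#' @param freqs An `allele_freqs` table (e.g. [spec_frequencies()] or
#'   [allele_frequencies()]).
#' @param n_mothers,n_fathers,n_offspring Pedigree dimensions.
#' @param error_rate Per-allele error rate in \[0, 1\].
#' @param reps Replicates (default 100).
#' @param seed Integer seed.
#' @param budget,min_loci Passed to [assign_parents()].
#' @return Tibble: `hypothesis`, `percent` (mean), `se`, `reps`.
#' @export
simulate_h1 <- function(freqs, n_mothers, n_fathers, n_offspring,
                        error_rate, reps = 100, seed, budget = 1,
                        min_loci = 9) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  withr::with_seed(seed, {
    pct <- vapply(seq_len(reps), function(r) {
      ped <- sim_simple_pedigree(freqs, n_mothers, n_fathers, n_offspring)
      adults <- apply_genotyping_error(ped$adults, error_rate, freqs)
      off <- apply_genotyping_error(ped$offspring, error_rate, freqs)
      percent_one_unassigned(
        assign_parents(adults, off, budget = budget, min_loci = min_loci,
                       loci = NULL))
    }, numeric(1))
    tibble::tibble(hypothesis = "H1", percent = mean(pct),
                   se = stats::sd(pct) / sqrt(reps), reps = reps)
  })
}

#' Expected percent of offspring with one unassigned parent due to missing
#' adult genotypes
#'
#' Per replicate: simulate a clean pedigree, remove the genotypes of
#' randomly chosen adults (missing tissue / failed genotypes), reassign,
#' and record the percent of offspring with exactly one unassigned parent.
#'
#' @inheritParams simulate_h1
#' @param n_remove_female,n_remove_male Adults removed per replicate.
#' @return Tibble: `hypothesis`, `percent`, `se`, `reps`.
#' @export
simulate_h2 <- function(freqs, n_mothers, n_fathers, n_offspring,
                        n_remove_female, n_remove_male, reps = 100, seed,
                        budget = 1, min_loci = 9) {
  if (n_remove_female > n_mothers || n_remove_male > n_fathers) {
    stop("cannot remove more adults than the census contains")
  }
  withr::with_seed(seed, {
    pct <- vapply(seq_len(reps), function(r) {
      ped <- sim_simple_pedigree(freqs, n_mothers, n_fathers, n_offspring)
      adults <- degrade_panel(ped$adults,
                              remove = c(female = n_remove_female,
                                         male = n_remove_male))$panel
      percent_one_unassigned(
        assign_parents(adults, ped$offspring, budget = budget,
                       min_loci = min_loci, loci = NULL))
    }, numeric(1))
    tibble::tibble(hypothesis = "H2", percent = mean(pct),
                   se = stats::sd(pct) / sqrt(reps), reps = reps)
  })
}

#' Compare observed and expected percentages across pedigrees
#'
#' Observed per-pedigree percentages of offspring with one unassigned
#' parent versus the percentages a hypothesis explains, via either the
#' unpaired rank-sum test or the paired signed-rank test (both exposed
#' because either reading is defensible for per-pedigree comparisons).
#'
#' @param observed,expected Numeric vectors of percentages (>= 3 values;
#'   equal length required for `signed_rank`).
#' @param mode `"rank_sum"` or `"signed_rank"`.
#' @return Tibble: `test`, `statistic`, `p_value`.
#' @export
compare_observed_expected <- function(observed, expected,
                                      mode = c("rank_sum", "signed_rank")) {
  mode <- match.arg(mode)
  if (length(observed) < 3 || length(expected) < 3) {
    stop("need at least 3 values per group")
  }
  if (mode == "rank_sum") {
    r <- rank_sum_test(observed, expected)
    tibble::tibble(test = "rank_sum", statistic = r$statistic,
                   p_value = r$p_value)
  } else {
    if (length(observed) != length(expected)) {
      stop("signed_rank mode requires equal-length vectors")
    }
    r <- signed_rank_test(observed, expected)
    tibble::tibble(test = "signed_rank", statistic = r$statistic,
                   p_value = r$p_value)
  }
}
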