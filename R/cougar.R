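#' Published reference tables: Chinook salmon reintroduction above Cougar
#' Dam
#'
#' Small reference tables from the grandparentage study of the Chinook
#' salmon trap-and-haul reintroduction above Cougar Dam (South Fork
#' McKenzie River, Oregon), used in worked examples and validation. They
#' are built in code — the study deposited scripts, not genotypes.
#'
#' `cougar_census()`: reintroduced anadromous adults per year and sex,
#' with counts of missing tissue samples and of adults missing more than
#' one genotype.
#'
#' `cougar_unsampled_counts()`: unsampled adults identified by
#' grandparentage, by cohort (year produced), sex and spawning age.
#'
#' `cougar_unsampled_adults()`: the same counts expanded to one row per
#' adult with the life-history tactic attached — the input shape for
#' [summarize_adults()] and [compare_ages()].
#'
#' `cougar_gtrio_strata()`: per (pedigree year x grandparent mating year x
#' unassigned side) stratum, the expected number of false Gtrios and the
#' observed Gtrios at 11 and at 15 loci.
#'
#' `cougar_base_crr()`: published female cohort replacement rates for the
#' 2007 and 2008 cohorts based on anadromous returns only.
#'
#' @return Tibbles; see the per-function descriptions.
#' @name cougar_reference
NULL

#' @rdname cougar_reference
#' @export
cougar_census <- function() {
  tibble::tribble(
    ~year, ~sex, ~n, ~missing_tissue, ~gt_multi_missing,
    2007L, "female", 318L, 0L, 0L,
    2007L, "male",   428L, 0L, 3L,
    2008L, "female", 288L, 0L, 0L,
    2008L, "male",   585L, 0L, 0L,
    2009L, "female", 604L, 0L, 3L,
    2009L, "male",   782L, 1L, 10L,
    2010L, "female", 264L, 0L, 4L,
    2010L, "male",   484L, 1L, 6L,
    2011L, "female", 324L, 1L, 5L,
    2011L, "male",   407L, 0L, 1L,
    2012L, "female", 439L, 0L, 1L,
    2012L, "male",   509L, 0L, 1L,
    2013L, "female", 337L, 0L, 2L,
    2013L, "male",   350L, 1L, 0L)
}

#' @rdname cougar_reference
#' @export
cougar_unsampled_counts <- function() {
  tibble::tribble(
    ~cohort, ~sex, ~age, ~n,
    2007L, "female", 4L,  8L,
    2007L, "female", 5L, 13L,
    2007L, "male",   1L,  1L,
    2007L, "male",   2L,  2L,
    2007L, "male",   4L,  7L,
    2007L, "male",   5L,  3L,
    2008L, "female", 4L, 11L,
    2008L, "female", 5L,  1L,
    2008L, "male",   2L, 10L,
    2008L, "male",   4L,  3L,
    2009L, "female", 4L,  1L,
    2009L, "male",   1L,  1L,
    2009L, "male",   2L,  4L,
    2009L, "male",   4L,  1L,
    2010L, "male",   2L,  4L,
    2011L, "male",   2L,  9L)
}

#' @rdname cougar_reference
#' @export
cougar_unsampled_adults <- function() {
  counts <- cougar_unsampled_counts()
  adults <- counts[rep(seq_len(nrow(counts)), counts$n),
                   c("cohort", "sex", "age")]
  adults$tactic <- classify_tactic(adults$sex, adults$age)
  tibble::as_tibble(adults)
}

#' @rdname cougar_reference
#' @export
cougar_gtrio_strata <- function() {
  cols <- c("parent_year", "gp_year", "age",
            "father_exp_false", "father_obs_11", "father_obs_15",
            "mother_exp_false", "mother_obs_11", "mother_obs_15")
  m <- matrix(c(
    2008, 2007, 1,  4,  1,  1,  4,  0,  0,
    2009, 2007, 2,  4,  3,  2,  4,  0,  0,
    2009, 2008, 1,  9,  0,  0, 13,  0,  0,
    2010, 2007, 3,  2,  0,  0, 10,  0,  0,
    2010, 2008, 2,  4, 17, 17, 20,  0,  0,
    2010, 2009, 1,  3,  2,  2, 18,  0,  0,
    2011, 2007, 4,  6,  9,  9,  9, 27, 25,
    2011, 2008, 3, 12,  0,  0, 18,  0,  0,
    2011, 2009, 2, 11, 12,  9, 19,  0,  0,
    2011, 2010, 1,  7,  0,  0, 11,  0,  0,
    2012, 2007, 5,  4,  7,  6,  8, 46, 45,
    2012, 2008, 4, 10, 22, 22, 18, 37, 36,
    2012, 2009, 3,  9,  0,  0, 17,  0,  0,
    2012, 2010, 2,  5,  8,  8,  9,  0,  0,
    2012, 2011, 1,  5,  0,  0, 10,  0,  0,
    2013, 2007, 6,  1,  0,  0,  2,  0,  0,
    2013, 2008, 5,  3,  0,  0,  4,  2,  2,
    2013, 2009, 4,  3,  1,  1,  3, 28, 27,
    2013, 2010, 3,  2,  0,  0,  2,  0,  0,
    2013, 2011, 2,  1, 22, 15,  2,  0,  0,
    2013, 2012, 1,  3,  0,  0,  3,  0,  0), ncol = 9, byrow = TRUE)
  colnames(m) <- cols
  tibble::as_tibble(m)
}

#' @rdname cougar_reference
#' @export
cougar_base_crr <- function() {
  tibble::tibble(cohort = c(2007L, 2008L), base_crr = c(0.40, 0.31))
}

#' Aggregate a Gtrio stratum table
#'
#' Sums the observed-Gtrio columns of a stratum table shaped like
#' [cougar_gtrio_strata()] and computes the share of assignments on each
#' unassigned side at both locus depths.
#'
#' @param strata Tibble with `father_obs_11`, `father_obs_15`,
#'   `mother_obs_11`, `mother_obs_15` (and the expected-false columns).
#' @return List: `total_11`, `total_15`, `mother_share_15_pct`,
#'   `father_share_15_pct` (half-up integer percents), and
#'   `expected_false_total`.
#' @export
summarize_gtrio_strata <- function(strata) {
  t11 <- sum(strata$father_obs_11) + sum(strata$mother_obs_11)
  t15 <- sum(strata$father_obs_15) + sum(strata$mother_obs_15)
  list(total_11 = t11, total_15 = t15,
       mother_share_15_pct = round_half_up(100 * sum(strata$mother_obs_15) / t15),
       father_share_15_pct = round_half_up(100 * sum(strata$father_obs_15) / t15),
       expected_false_total = sum(strata$father_exp_false) +
         sum(strata$mother_exp_false))
}
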