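#' Infer deduplicated unsampled adults from retained Gtrios
#'
#' Each unique (grandparent pair, unassigned side) is conservatively
#' assumed to have produced exactly one unsampled adult. Sex follows the
#' unassigned side (father -> male); the cohort is the grandparent mating
#' year; each supporting Gtrio contributes an observed spawning age =
#' pedigree year of the grandoffspring - grandparent mating year; the
#' assigned age is the earliest observed spawning age (all observed ages
#' are retained).
#'
#' @param retained Retained Gtrios ([resolve_ambiguities()] `$retained`,
#'   sides already corrected).
#' @return Tibble: `gp_female`, `gp_male`, `cohort`, `sex`, `ages_observed`
#'   (list column), `age` (assigned), `tactic`, `n_grandoffspring`.
#' @export
infer_unsampled_adults <- function(retained) {
  if (!nrow(retained)) {
    return(tibble::tibble(gp_female = character(0), gp_male = character(0),
                          cohort = integer(0), sex = character(0),
                          ages_observed = list(), age = integer(0),
                          tactic = character(0), n_grandoffspring = integer(0)))
  }
  age <- retained$year - retained$gp_year
  if (any(age <= 0)) {
    stop("nonpositive inferred spawning age: pedigree year precedes the ",
         "grandparent mating year")
  }
  retained$.age <- age
  grp <- dplyr::group_by(retained, .data$gp_female, .data$gp_male,
                         .data$gp_year, .data$side)
  adults <- dplyr::summarise(
    grp,
    ages_observed = list(sort(unique(.data$.age))),
    age = min(.data$.age),
    n_grandoffspring = dplyr::n(), .groups = "drop")
  adults$sex <- ifelse(adults$side == "father", "male", "female")
  adults$cohort <- adults$gp_year
  adults$tactic <- classify_tactic(adults$sex, adults$age)
  adults[, c("gp_female", "gp_male", "cohort", "sex", "ages_observed",
             "age", "tactic", "n_grandoffspring")]
}

#' Classify the life-history tactic of an unsampled adult
#'
#' Males maturing at age 1-2 are precocial residents; everything else is
#' adfluvial (freshwater-maturing, reservoir-reared). A female below age 3
#' is a data inconsistency — female Chinook salmon cannot mature prior to
#' age 3 — and raises an error.
#'
#' @param sex `"male"` / `"female"` (vectorized).
#' @param age Assigned spawning age in years (>= 1).
#' @return Character vector: `"precocial"` or `"adfluvial"`.
#' @export
classify_tactic <- function(sex, age) {
  stopifnot(length(sex) == length(age))
  if (any(age < 1)) stop("age must be >= 1")
  if (any(sex == "female" & age < 3)) {
    stop("females cannot mature prior to age 3")
  }
  ifelse(sex == "male" & age <= 2, "precocial", "adfluvial")
}

#' Summarize unsampled adults by cohort, sex and age
#'
#' @param adults [infer_unsampled_adults()] output (or any tibble with
#'   `cohort`, `sex`, `age`, `tactic`).
#' @return List: `table` (tibble cohort x sex x age -> n) and `totals`
#'   (`precocial`, `adfluvial`, `total`).
#' @export
summarize_adults <- function(adults) {
  if (!nrow(adults)) {
    return(list(table = tibble::tibble(cohort = integer(0),
                                       sex = character(0), age = integer(0),
                                       n = integer(0)),
                totals = list(precocial = 0L, adfluvial = 0L, total = 0L)))
  }
  tab <- dplyr::summarise(dplyr::group_by(adults, .data$cohort, .data$sex,
                                          .data$age),
                          n = dplyr::n(), .groups = "drop")
  list(table = tab,
       totals = list(precocial = sum(adults$tactic == "precocial"),
                     adfluvial = sum(adults$tactic == "adfluvial"),
                     total = nrow(adults)))
}

#' Compare spawning ages of unsampled males and females
#'
#' Rank-sum comparison of assigned ages with females as the first group and
#' mid-ranked ties.
#'
#' @param adults [infer_unsampled_adults()] output; both sexes required.
#' @return List: `male_median`, `female_median`, `statistic` (females-first
#'   U), `p_value`.
#' @export
compare_ages <- function(adults) {
  f <- adults$age[adults$sex == "female"]
  m <- adults$age[adults$sex == "male"]
  if (!length(f) || !length(m)) stop("both sexes required for comparison")
  r <- rank_sum_test(f, m)
  list(male_median = stats::median(m), female_median = stats::median(f),
       statistic = r$statistic, p_value = r$p_value)
}

round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Update a cohort replacement rate with inferred adfluvial females
#'
#' CRR is offspring (future adults) per reintroduced female of the cohort.
#' Each adfluvial female inferred by grandparentage adds one matured adult
#' to the cohort's production: `updated = base + n_adfluvial / n_females`,
#' and the percent increase is `100 * (n_adfluvial / n_females) / base`.
#' Rounded values use half-up rounding (2 decimals for CRR, integer
#' percent); unrounded values are always reported alongside.
#'
#' @param base Base CRR (> 0), from anadromous returns only.
#' @param n_females Reintroduced female census of the cohort (> 0).
#' @param n_adfluvial_females Adfluvial females credited to the cohort.
#' @return Tibble: `base`, `n_females`, `n_adfluvial_females`, `updated`,
#'   `updated_rounded`, `pct_increase`, `pct_increase_rounded`.
#' @export
update_crr <- function(base, n_females, n_adfluvial_females) {
  stopifnot(base > 0, n_adfluvial_females >= 0)
  if (n_females <= 0) stop("n_females must be positive")
  gain <- n_adfluvial_females / n_females
  tibble::tibble(base = base, n_females = n_females,
                 n_adfluvial_females = n_adfluvial_females,
                 updated = base + gain,
                 updated_rounded = round_half_up(base + gain, 2),
                 pct_increase = 100 * gain / base,
                 pct_increase_rounded = round_half_up(100 * gain / base))
}
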