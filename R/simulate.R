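#' Locus panel specification for the simulator
#'
#' Defaults emulate a highly polymorphic Chinook salmon microsatellite
#' panel: 11 primary loci with ~34 alleles and observed heterozygosity near
#' 0.92, plus 4 confirmation loci with ~16 alleles and heterozygosity near
#' 0.83. Frequency shapes: `"uniform"` (equifrequent), `"geometric"`
#' (skewed; the decay rate is solved per locus so expected heterozygosity
#' matches the configured target) or `"empirical"` (caller-supplied
#' [allele_frequencies()] table).
#'
#' @param n_primary,n_confirmation Locus counts per role.
#' @param A_primary,A_confirmation Alleles per locus.
#' @param ho_primary,ho_confirmation Target expected heterozygosity
#'   (geometric shape only).
#' @param shape `"geometric"`, `"uniform"` or `"empirical"`.
#' @param empirical Frequency table when `shape = "empirical"`.
#' @return List of class `locus_spec`.
#' @export
locus_spec <- function(n_primary = 11, n_confirmation = 4,
                       A_primary = 34, A_confirmation = 16,
                       ho_primary = 0.92, ho_confirmation = 0.83,
                       shape = c("geometric", "uniform", "empirical"),
                       empirical = NULL) {
  shape <- match.arg(shape)
  if (shape == "empirical" && is.null(empirical)) {
    stop("shape = 'empirical' requires an allele-frequency table")
  }
  structure(list(n_primary = n_primary, n_confirmation = n_confirmation,
                 A_primary = A_primary, A_confirmation = A_confirmation,
                 ho_primary = ho_primary, ho_confirmation = ho_confirmation,
                 shape = shape, empirical = empirical),
            class = "locus_spec")
}

# geometric decay rate whose expected heterozygosity 1 - sum(p^2) hits ho
solve_geom_rate <- function(A, ho) {
  ho_max <- 1 - 1 / A
  if (ho >= ho_max) return(1)          # uniform limit
  h <- function(r) {
    p <- r^(seq_len(A) - 1); p <- p / sum(p)
    (1 - sum(p^2)) - ho
  }
  stats::uniroot(h, c(1e-6, 1 - 1e-9), tol = 1e-12)$root
}

#' Build simulator allele-frequency tables from a locus spec
#'
#' Allele labels are fragment-size-like integers (100, 104, 108, ...).
#'
#' @param spec A [locus_spec()].
#' @return An `allele_freqs` table plus a matching loci tibble in
#'   `attr(, "loci")`.
#' @export
spec_frequencies <- function(spec) {
  if (spec$shape == "empirical") return(spec$empirical)
  build <- function(n, A, ho, prefix) {
    if (n == 0) return(stats::setNames(list(), character(0)))
    out <- vector("list", n)
    for (i in seq_len(n)) {
      p <- if (spec$shape == "uniform") rep(1 / A, A) else {
        r <- solve_geom_rate(A, ho)
        q <- r^(seq_len(A) - 1); q / sum(q)
      }
      out[[i]] <- stats::setNames(p, 100 + 4 * (seq_len(A) - 1))
    }
    names(out) <- paste0(prefix, seq_len(n))
    out
  }
  prim <- build(spec$n_primary, spec$A_primary, spec$ho_primary, "Ots")
  conf <- build(spec$n_confirmation, spec$A_confirmation,
                spec$ho_confirmation, "Conf")
  out <- c(prim, conf)
  attr(out, "loci") <- tibble::tibble(
    locus = names(out),
    role = rep(c("primary", "confirmation"),
               c(spec$n_primary, spec$n_confirmation)))
  class(out) <- "allele_freqs"
  out
}

#' Simulation configuration
#'
#' The defaults describe the study conditions the simulator emulates: annual
#' cohorts of several hundred reintroduced adults per sex, ~10x as many
#' sampled age-0 offspring as females, a uniform reproductive-success model,
#' and the [locus_spec()] default panel. Planted unsampled spawners are rows
#' of `plantings` (`sex`, `age`, `cohort`, `n`): precocial males may be age
#' 1-2, adfluvial adults age >= 3; females below age 3 are rejected because
#' female Chinook salmon cannot mature before age 3.
#'
#' @param years Cohort (mating) years simulated.
#' @param n_females,n_males,n_offspring Scalars or per-year vectors.
#' @param loci A [locus_spec()].
#' @param rs_model Reproductive success: `"uniform"` (every adult equal
#'   expected offspring) or `"overdispersed"` (gamma-weighted parent draw,
#'   negative-binomial family offspring counts).
#' @param rs_dispersion Gamma shape for `"overdispersed"`; smaller = more
#'   skew.
#' @param error_rate Per-allele genotyping error applied to adult and
#'   offspring panels.
#' @param remove_females,remove_males Whole genotypes dropped per year
#'   (missing tissue).
#' @param blank_females,blank_males Individuals per year with
#'   `blank_n_loci` loci blanked (failed genotypes).
#' @param blank_n_loci Loci blanked per degraded individual (> 1).
#' @param mis_sexed Recorded-sex flips per year.
#' @param plantings Data frame of planted unsampled spawners (see above).
#' @param offspring_per_planted Sampled grandoffspring per planted adult.
#' @param seed Mandatory integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(years, n_females, n_males, n_offspring,
                       loci = locus_spec(),
                       rs_model = c("uniform", "overdispersed"),
                       rs_dispersion = 0.5,
                       error_rate = 0,
                       remove_females = 0, remove_males = 0,
                       blank_females = 0, blank_males = 0, blank_n_loci = 2,
                       mis_sexed = 0,
                       plantings = NULL, offspring_per_planted = 5,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  rs_model <- match.arg(rs_model)
  rep_year <- function(x) if (length(x) == 1) rep(x, length(years)) else x
  n_females <- rep_year(n_females); n_males <- rep_year(n_males)
  n_offspring <- rep_year(n_offspring)
  stopifnot(length(n_females) == length(years),
            length(n_males) == length(years),
            length(n_offspring) == length(years),
            all(n_females > 0), all(n_males > 0),
            error_rate >= 0, error_rate <= 1, blank_n_loci >= 2)
  if (!is.null(plantings)) {
    plantings <- tibble::as_tibble(plantings)
    stopifnot(all(c("sex", "age", "cohort", "n") %in% names(plantings)))
    if (any(plantings$age < 1)) stop("planted adult age must be >= 1")
    if (any(plantings$sex == "female" & plantings$age < 3)) {
      stop("females cannot mature prior to age 3")
    }
  }
  structure(list(years = as.integer(years), n_females = n_females,
                 n_males = n_males, n_offspring = n_offspring, loci = loci,
                 rs_model = rs_model, rs_dispersion = rs_dispersion,
                 error_rate = error_rate,
                 remove_females = remove_females, remove_males = remove_males,
                 blank_females = blank_females, blank_males = blank_males,
                 blank_n_loci = blank_n_loci, mis_sexed = mis_sexed,
                 plantings = plantings,
                 offspring_per_planted = offspring_per_planted,
                 seed = as.integer(seed)),
            class = "sim_config")
}

hw_draw <- function(freqs, ids, sex, year, loci, sampled = TRUE) {
  n <- length(ids)
  a1 <- matrix(NA_integer_, n, nrow(loci))
  a2 <- a1
  for (j in seq_len(nrow(loci))) {
    f <- freqs[[loci$locus[j]]]
    alleles <- as.integer(names(f))
    a1[, j] <- sample_vec(alleles, n, replace = TRUE, prob = f)
    a2[, j] <- sample_vec(alleles, n, replace = TRUE, prob = f)
  }
  geno_panel(tibble::tibble(id = ids, sex = sex, year = year,
                            sampled = sampled), a1, a2, loci)
}

# one uniformly chosen allele per parent per locus
mendel_cross <- function(m1, m2, f1, f2) {
  pick_m <- matrix(stats::runif(length(m1)) < 0.5, nrow(m1))
  pick_f <- matrix(stats::runif(length(f1)) < 0.5, nrow(f1))
  list(a1 = ifelse(pick_m, m1, m2), a2 = ifelse(pick_f, f1, f2))
}

draw_parent_idx <- function(n_adults, n_off, rs_model, dispersion) {
  if (rs_model == "uniform") {
    sample.int(n_adults, n_off, replace = TRUE)
  } else {
    w <- stats::rgamma(n_adults, shape = dispersion, rate = dispersion)
    sample.int(n_adults, n_off, replace = TRUE, prob = w)
  }
}

#' Simulate a multi-cohort reintroduction pedigree
#'
#' Founder adults are drawn under Hardy-Weinberg from the configured locus
#' frequencies; offspring are Mendelian crosses of a mother and father drawn
#' per the reproductive-success model; planted unsampled spawners and panel
#' degradation (missing tissue, blanked loci, mis-sexed adults) and
#' genotyping error are then applied. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `adults` and `offspring` (`geno_panel`s) and `truth`:
#'   `parents` (offspring, mother, father, year), `mate_pairs`, `roster` of
#'   planted unsampled adults, `unsampled_panel` (their genotypes, never in
#'   the sampled panels), and degradation/error `events`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(config) {
  freqs <- spec_frequencies(config$loci)
  loci <- attr(freqs, "loci")
  if (is.null(loci)) {
    loci <- tibble::tibble(locus = names(freqs), role = "primary")
  }
  adults <- list(); offspring <- list(); parents <- list()
  for (k in seq_along(config$years)) {
    y <- config$years[k]
    Fi <- config$n_females[k]; Mi <- config$n_males[k]
    fem <- hw_draw(freqs, sprintf("F%d_%04d", y, seq_len(Fi)), "female", y, loci)
    mal <- hw_draw(freqs, sprintf("M%d_%04d", y, seq_len(Mi)), "male", y, loci)
    no <- config$n_offspring[k]
    mi <- draw_parent_idx(Fi, no, config$rs_model, config$rs_dispersion)
    fi <- draw_parent_idx(Mi, no, config$rs_model, config$rs_dispersion)
    cross <- mendel_cross(fem$a1[mi, , drop = FALSE], fem$a2[mi, , drop = FALSE],
                          mal$a1[fi, , drop = FALSE], mal$a2[fi, , drop = FALSE])
    oid <- sprintf("J%d_%05d", y, seq_len(no))
    off <- geno_panel(tibble::tibble(id = oid, sex = "unknown", year = y,
                                     sampled = TRUE),
                      cross$a1, cross$a2, loci)
    adults[[k]] <- rbind_panels(fem, mal)
    offspring[[k]] <- off
    parents[[k]] <- tibble::tibble(offspring = oid,
                                   mother = fem$ind$id[mi],
                                   father = mal$ind$id[fi], year = y)
  }
  adults <- Reduce(rbind_panels, adults)
  offspring <- Reduce(rbind_panels, offspring)
  parents <- dplyr::bind_rows(parents)
  truth <- list(parents = parents,
                mate_pairs = true_mate_pairs(parents),
                roster = tibble::tibble(),
                unsampled_panel = NULL,
                events = tibble::tibble())
  if (!is.null(config$plantings) && nrow(config$plantings)) {
    planted <- plant_unsampled_adults(adults, offspring, truth,
                                      config$plantings,
                                      config$offspring_per_planted)
    offspring <- planted$offspring
    truth <- planted$truth
  }
  if (config$error_rate > 0) {
    adults <- apply_genotyping_error(adults, config$error_rate, freqs)
    offspring <- apply_genotyping_error(offspring, config$error_rate, freqs)
  }
  if (config$remove_females + config$remove_males + config$blank_females +
      config$blank_males + config$mis_sexed > 0) {
    parts <- lapply(config$years, function(y) {
      degrade_panel(panel_subset(adults, years = y),
                    remove = c(female = config$remove_females,
                               male = config$remove_males),
                    blank = c(female = config$blank_females,
                              male = config$blank_males),
                    blank_n_loci = config$blank_n_loci,
                    sexflip = config$mis_sexed)
    })
    adults <- Reduce(rbind_panels, lapply(parts, `[[`, "panel"))
    truth$events <- dplyr::bind_rows(truth$events,
                                     lapply(parts, `[[`, "events"))
  }
  list(adults = adults, offspring = offspring, truth = truth,
       freqs = freqs)
}

rbind_panels <- function(p, q) {
  stopifnot(identical(p$loci$locus, q$loci$locus))
  geno_panel(dplyr::bind_rows(p$ind, q$ind),
             rbind(p$a1, q$a1), rbind(p$a2, q$a2), p$loci)
}

true_mate_pairs <- function(parents) {
  dplyr::summarise(dplyr::group_by(parents, .data$mother, .data$father,
                                   .data$year),
                   n_offspring = dplyr::n(), .groups = "drop") |>
    dplyr::rename(female = "mother", male = "father")
}

#' Plant unsampled spawners into a simulated pedigree
#'
#' Each planted adult is a Mendelian offspring of a true mate pair from its
#' cohort (grandparent mating) year. Its own genotype never enters a sampled
#' panel; instead it is mated, in year `cohort + age`, with a randomly
#' chosen sampled adult of the opposite sex, and their sampled offspring are
#' appended to the offspring panel. Distinct planted adults use distinct
#' grandparent pairs. Female plantings below age 3 are rejected (females
#' cannot mature prior to age 3).
#'
#' @param adults,offspring `geno_panel`s from [simulate_population()].
#' @param truth Truth-table list (`parents`, `mate_pairs`, ...).
#' @param plantings Data frame with `sex`, `age`, `cohort`, `n`.
#' @param offspring_per_planted Sampled grandoffspring per planted adult.
#' @param seed Optional integer seed.
#' @return List with updated `offspring` and `truth` (roster rows and the
#'   `unsampled_panel` holding planted genotypes).
#' @export
plant_unsampled_adults <- function(adults, offspring, truth, plantings,
                                   offspring_per_planted = 5, seed = NULL) {
  run <- function() {
    plantings <- tibble::as_tibble(plantings)
    if (any(plantings$sex == "female" & plantings$age < 3)) {
      stop("females cannot mature prior to age 3")
    }
    loci <- adults$loci
    used_pairs <- character(0)
    roster <- list(); new_off <- list(); new_parents <- list()
    up_ind <- list(); up_a1 <- list(); up_a2 <- list()
    counter <- 0L
    for (r in seq_len(nrow(plantings))) {
      pl <- plantings[r, ]
      pool <- truth$mate_pairs[truth$mate_pairs$year == pl$cohort, ]
      pool <- pool[!paste(pool$female, pool$male) %in% used_pairs, ]
      if (nrow(pool) < pl$n) {
        stop("infeasible plantings: ", pl$n, " adult(s) requested for cohort ",
             pl$cohort, " but only ", nrow(pool), " unused mate pair(s) exist")
      }
      picks <- pool[sample.int(nrow(pool), pl$n), , drop = FALSE]
      spawn_year <- pl$cohort + pl$age
      partner_sex <- if (pl$sex == "male") "female" else "male"
      partners <- adults$ind$id[adults$ind$year == spawn_year &
                                adults$ind$sex == partner_sex &
                                adults$ind$sampled]
      if (!length(partners)) {
        stop("no sampled ", partner_sex, " adults available in year ",
             spawn_year, " for planting")
      }
      for (i in seq_len(pl$n)) {
        counter <- counter + 1L
        used_pairs <- c(used_pairs, paste(picks$female[i], picks$male[i]))
        gm <- panel_genotype(adults, picks$female[i])
        gf <- panel_genotype(adults, picks$male[i])
        g <- mendel_cross(matrix(gm$a1, 1), matrix(gm$a2, 1),
                          matrix(gf$a1, 1), matrix(gf$a2, 1))
        uid <- sprintf("U%s%d_%03d", toupper(substr(pl$sex, 1, 1)),
                       pl$cohort, counter)
        partner <- sample_vec(partners, 1)
        gp <- panel_genotype(adults, partner)
        no <- offspring_per_planted
        if (pl$sex == "male") {
          cross <- mendel_cross(matrix(rep(gp$a1, each = no), no),
                                matrix(rep(gp$a2, each = no), no),
                                matrix(rep(g$a1, each = no), no),
                                matrix(rep(g$a2, each = no), no))
          mo <- partner; fa <- uid
        } else {
          cross <- mendel_cross(matrix(rep(g$a1, each = no), no),
                                matrix(rep(g$a2, each = no), no),
                                matrix(rep(gp$a1, each = no), no),
                                matrix(rep(gp$a2, each = no), no))
          mo <- uid; fa <- partner
        }
        oid <- sprintf("JU%d_%03d_%02d", spawn_year, counter, seq_len(no))
        new_off[[length(new_off) + 1L]] <-
          geno_panel(tibble::tibble(id = oid, sex = "unknown",
                                    year = spawn_year, sampled = TRUE),
                     cross$a1, cross$a2, loci)
        new_parents[[length(new_parents) + 1L]] <-
          tibble::tibble(offspring = oid, mother = mo, father = fa,
                         year = spawn_year)
        roster[[length(roster) + 1L]] <-
          tibble::tibble(id = uid, sex = pl$sex, age = pl$age,
                         cohort = pl$cohort, spawn_year = spawn_year,
                         gp_female = picks$female[i], gp_male = picks$male[i],
                         partner = partner, n_offspring = no)
        up_ind[[counter]] <- tibble::tibble(id = uid, sex = pl$sex,
                                            year = spawn_year,
                                            sampled = FALSE)
        up_a1[[counter]] <- g$a1; up_a2[[counter]] <- g$a2
      }
    }
    if (counter == 0L) return(list(offspring = offspring, truth = truth))
    offspring <- Reduce(rbind_panels, c(list(offspring), new_off))
    truth$parents <- dplyr::bind_rows(truth$parents,
                                      dplyr::bind_rows(new_parents))
    truth$mate_pairs <- true_mate_pairs(truth$parents)
    truth$roster <- dplyr::bind_rows(truth$roster, dplyr::bind_rows(roster))
    truth$unsampled_panel <- geno_panel(dplyr::bind_rows(up_ind),
                                        do.call(rbind, up_a1),
                                        do.call(rbind, up_a2), loci)
    list(offspring = offspring, truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Degrade an adult panel
#'
#' Emulates the human-error processes seen in real reintroduction rosters:
#' whole genotypes removed (missing tissue), several loci blanked (failed
#' amplification) and recorded sexes flipped (sex-marker error). All events
#' are logged.
#'
#' @param panel Adult `geno_panel`.
#' @param remove Named counts `c(female =, male =)` of genotypes to drop.
#' @param blank Named counts of individuals to blank at `blank_n_loci` loci.
#' @param blank_n_loci Loci blanked per individual (> 1).
#' @param sexflip Number of recorded-sex flips.
#' @param seed Optional integer seed.
#' @return List with the degraded `panel` and an `events` tibble
#'   (id, year, event, detail).
#' @export
degrade_panel <- function(panel, remove = c(female = 0, male = 0),
                          blank = c(female = 0, male = 0),
                          blank_n_loci = 2, sexflip = 0, seed = NULL) {
  run <- function() {
    events <- list()
    pick_sex <- function(sex, n, excluded = character(0)) {
      pool <- panel$ind$id[panel$ind$sex == sex & !panel$ind$id %in% excluded]
      if (n > length(pool)) {
        stop("cannot degrade ", n, " ", sex, "(s): only ", length(pool),
             " available")
      }
      if (n == 0) character(0) else sample_vec(pool, n)
    }
    removed <- c(pick_sex("female", remove[["female"]]),
                 pick_sex("male", remove[["male"]]))
    blanked <- c(pick_sex("female", blank[["female"]], removed),
                 pick_sex("male", blank[["male"]], removed))
    a1 <- panel$a1; a2 <- panel$a2; ind <- panel$ind
    for (id in blanked) {
      i <- match(id, ind$id)
      js <- sample.int(ncol(a1), blank_n_loci)
      a1[i, js] <- NA; a2[i, js] <- NA
      events[[length(events) + 1L]] <-
        tibble::tibble(id = id, year = ind$year[i], event = "blanked",
                       detail = paste(panel$loci$locus[js], collapse = ","))
    }
    if (sexflip > 0) {
      pool <- ind$id[ind$sex %in% c("female", "male") &
                     !ind$id %in% removed]
      flips <- sample_vec(pool, sexflip)
      for (id in flips) {
        i <- match(id, ind$id)
        old <- ind$sex[i]
        ind$sex[i] <- if (old == "female") "male" else "female"
        events[[length(events) + 1L]] <-
          tibble::tibble(id = id, year = ind$year[i], event = "sexflip",
                         detail = paste(old, "->", ind$sex[i]))
      }
    }
    for (id in removed) {
      i <- match(id, panel$ind$id)
      events[[length(events) + 1L]] <-
        tibble::tibble(id = id, year = panel$ind$year[i], event = "removed",
                       detail = panel$ind$sex[i])
    }
    keep <- !ind$id %in% removed
    list(panel = geno_panel(ind[keep, ], a1[keep, , drop = FALSE],
                            a2[keep, , drop = FALSE], panel$loci),
         events = if (length(events)) dplyr::bind_rows(events)
                  else tibble::tibble())
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
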