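#' Offspring alleles unexplained by the known parent
#'
#' With one parent assigned, grandparentage only needs to explain the
#' offspring allele that did *not* come from the known parent. For an
#' offspring genotype \{x, y\}: y is unexplained iff the parent carries x,
#' and x is unexplained iff the parent carries y; when the parent carries
#' neither (the tolerated mismatch locus) or the parent genotype is
#' missing, both alleles are retained as unexplained.
#'
#' @param offspring Length-2 integer vector (one locus), no NA.
#' @param parent Length-2 integer vector, or NA/NULL for a missing
#'   parental genotype.
#' @return Integer vector of unexplained alleles (1 or 2 values).
#' @export
unexplained_alleles <- function(offspring, parent) {
  stopifnot(length(offspring) == 2, !anyNA(offspring))
  x <- offspring[1]; y <- offspring[2]
  if (is.null(parent) || anyNA(parent)) return(unique(c(x, y)))
  has_x <- x %in% parent; has_y <- y %in% parent
  if (has_x && !has_y) return(y)
  if (has_y && !has_x) return(x)
  unique(c(x, y))            # both explainable, or mismatch locus
}

# per-offspring unexplained-allele pair matrices over all loci
# (u2 NA when U is a single allele; both NA when offspring untyped)
unexplained_matrix <- function(offspring_geno, parent_geno) {
  x <- offspring_geno$a1; y <- offspring_geno$a2
  p1 <- parent_geno$a1; p2 <- parent_geno$a2
  has_x <- !is.na(p1) & (x == p1 | x == p2)
  has_y <- !is.na(p1) & (y == p1 | y == p2)
  has_x[is.na(has_x)] <- FALSE; has_y[is.na(has_y)] <- FALSE
  u1 <- ifelse(has_x & !has_y, y, x)
  u2 <- ifelse(has_x == has_y, y, NA_integer_)   # both or neither explained
  u1[is.na(x)] <- NA_integer_; u2[is.na(x)] <- NA_integer_
  list(u1 = u1, u2 = u2, untyped = is.na(x))
}

one_parent_rows <- function(assignments) {
  one <- assignments[assignments$category %in%
                     c("mother_unassigned", "father_unassigned"), ]
  one$side <- ifelse(one$category == "mother_unassigned", "mother", "father")
  one$known_parent <- ifelse(one$side == "mother", one$father, one$mother)
  one
}

# grandparent-pair allele matrices (n_pairs x L), NA-padded
pair_allele_matrices <- function(pairs, adults) {
  gi <- match(pairs$female, adults$ind$id)
  gj <- match(pairs$male, adults$ind$id)
  if (anyNA(gi) || anyNA(gj)) {
    stop("grandparent pair member(s) absent from adult panel")
  }
  list(g1 = adults$a1[gi, , drop = FALSE], g2 = adults$a2[gi, , drop = FALSE],
       g3 = adults$a1[gj, , drop = FALSE], g4 = adults$a2[gj, , drop = FALSE])
}

# candidate test for one offspring (U matrices) against all pairs;
# returns list(ok = logical n_pairs, skipped = integer n_pairs)
candidate_vs_pairs <- function(u, g, idx, allow_skip) {
  n_pairs <- nrow(g$g1)
  ok <- rep(TRUE, n_pairs); skipped <- integer(n_pairs)
  for (j in idx) {
    if (u$untyped[j]) {                       # offspring untyped: no U
      if (allow_skip) skipped <- skipped + 1L else ok[] <- FALSE
      next
    }
    gp_any <- !is.na(g$g1[, j]) | !is.na(g$g3[, j])
    hit <- function(a) {
      if (is.na(a)) return(rep(FALSE, n_pairs))
      h <- g$g1[, j] == a | g$g2[, j] == a | g$g3[, j] == a | g$g4[, j] == a
      h[is.na(h)] <- FALSE      # NA | TRUE is TRUE, so partial pairs still hit
      h
    }
    m <- hit(u$u1[j]) | hit(u$u2[j])
    if (allow_skip) {
      skipped <- skipped + as.integer(!gp_any)
      ok <- ok & (m | !gp_any)
    } else {
      ok <- ok & m & gp_any
    }
  }
  if (allow_skip) ok <- ok & skipped <= 1L   # still >= (total - 1) loci
  list(ok = ok, skipped = skipped)
}

#' Find candidate grandparent-pair / grandoffspring trios (Gtrios)
#'
#' A grandparent pair shares one in four of its alleles per locus with a
#' grandchild; with one parent known, the offspring allele unexplained by
#' that parent must be present in the pair's allele union at *every*
#' primary locus for the trio to be a candidate. Comparisons are restricted
#' to pedigree-evidenced mate pairs that mated *before* the offspring's
#' pedigree year — an unsampled parent must be at least age 1 when it
#' spawns, so later or same-year matings are never comparable.
#'
#' @param pairs Mate-pair tibble (`female`, `male`, `year`) from
#'   [extract_mate_pairs()] — used as grandparent pairs.
#' @param assignments [assign_parents()] output; only offspring with
#'   exactly one assigned parent are compared.
#' @param adults,offspring `geno_panel`s holding all genotypes.
#' @param loci Locus subset (default `"primary"`).
#' @param allow_skip If `TRUE`, a locus at which *both* grandparents are
#'   missing (or the offspring is untyped) is skipped (at most one such
#'   locus, and the trio is flagged); default `FALSE` requires complete
#'   matches, mirroring the strict criterion used on real data.
#' @return Tibble of candidate Gtrios: `offspring`, `year`, `side`
#'   (unassigned mother/father), `known_parent`, `gp_female`, `gp_male`,
#'   `gp_year`, `loci_compared`, `n_skipped`, `status = "candidate"`.
#' @export
find_gtrios <- function(pairs, assignments, adults, offspring,
                        loci = "primary", allow_skip = FALSE) {
  idx <- locus_index(adults, loci)
  one <- one_parent_rows(assignments)
  empty <- tibble::tibble(offspring = character(0), year = integer(0),
                          side = character(0), known_parent = character(0),
                          gp_female = character(0), gp_male = character(0),
                          gp_year = integer(0), loci_compared = integer(0),
                          n_skipped = integer(0), status = character(0))
  if (!nrow(one) || !nrow(pairs)) return(empty)
  g <- pair_allele_matrices(pairs, adults)
  out <- list()
  for (k in seq_len(nrow(one))) {
    og <- panel_genotype(offspring, one$offspring[k])
    kg <- panel_genotype(adults, one$known_parent[k])
    u <- unexplained_matrix(og, kg)
    res <- candidate_vs_pairs(u, g, idx, allow_skip)
    hits <- which(res$ok & pairs$year < one$year[k])
    for (p in hits) {
      out[[length(out) + 1L]] <- tibble::tibble(
        offspring = one$offspring[k], year = one$year[k], side = one$side[k],
        known_parent = one$known_parent[k],
        gp_female = pairs$female[p], gp_male = pairs$male[p],
        gp_year = pairs$year[p],
        loci_compared = length(idx) - res$skipped[p],
        n_skipped = res$skipped[p], status = "candidate")
    }
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

#' Confirm candidate Gtrios at the additional loci
#'
#' Candidates are re-tested at the confirmation loci. A trio is confirmed
#' only when all four individuals (grandoffspring, known parent and both
#' grandparents) are fully typed at the confirmation loci and the
#' unexplained-allele criterion holds at every one of them; a trio with any
#' missing confirmation genotype is excluded with reason
#' `missing_extra_genotype`, an incompatible one with reason
#' `extra_locus_mismatch`.
#'
#' @param candidates [find_gtrios()] output.
#' @param adults,offspring `geno_panel`s carrying the confirmation loci.
#' @param loci Confirmation locus subset (default `"confirmation"`).
#' @return The input tibble with `status` updated to `confirmed` /
#'   `excluded` and a `reason` column.
#' @export
confirm_gtrios <- function(candidates, adults, offspring,
                           loci = "confirmation") {
  idx <- locus_index(adults, loci)
  candidates$reason <- NA_character_
  if (!nrow(candidates)) {
    candidates$status <- character(0)
    return(candidates)
  }
  for (k in seq_len(nrow(candidates))) {
    og <- panel_genotype(offspring, candidates$offspring[k])
    kg <- panel_genotype(adults, candidates$known_parent[k])
    gm <- panel_genotype(adults, candidates$gp_female[k])
    gf <- panel_genotype(adults, candidates$gp_male[k])
    if (anyNA(og$a1[idx]) || anyNA(kg$a1[idx]) ||
        anyNA(gm$a1[idx]) || anyNA(gf$a1[idx])) {
      candidates$status[k] <- "excluded"
      candidates$reason[k] <- "missing_extra_genotype"
      next
    }
    ok <- TRUE
    for (j in idx) {
      U <- unexplained_alleles(c(og$a1[j], og$a2[j]), c(kg$a1[j], kg$a2[j]))
      if (!any(U %in% c(gm$a1[j], gm$a2[j], gf$a1[j], gf$a2[j]))) {
        ok <- FALSE
        break
      }
    }
    candidates$status[k] <- if (ok) "confirmed" else "excluded"
    if (!ok) candidates$reason[k] <- "extra_locus_mismatch"
  }
  candidates
}

#' Exclude grandoffspring that assign to more than one grandparent pair
#'
#' An unsampled parent has exactly one parental pair, so a grandoffspring
#' whose unassigned side matches several distinct grandparent pairs cannot
#' be resolved; all of its confirmed Gtrios are excluded and the offspring
#' tallied once.
#'
#' @param gtrios Confirmed Gtrios ([confirm_gtrios()] output).
#' @return List: `retained`, `excluded` tibbles and
#'   `n_ambiguous_offspring`.
#' @export
resolve_ambiguities <- function(gtrios) {
  conf <- gtrios[gtrios$status == "confirmed", ]
  if (!nrow(conf)) {
    return(list(retained = conf, excluded = conf, n_ambiguous_offspring = 0L))
  }
  key <- paste(conf$offspring, conf$side)
  pair_id <- paste(conf$gp_female, conf$gp_male, conf$gp_year)
  n_pairs <- tapply(pair_id, key, function(p) length(unique(p)))
  ambi <- names(n_pairs)[n_pairs > 1]
  excl <- conf[key %in% ambi, ]
  if (nrow(excl)) {
    excl$status <- "excluded"
    excl$reason <- "ambiguous"
  }
  list(retained = conf[!key %in% ambi, ], excluded = excl,
       n_ambiguous_offspring = length(unique(excl$offspring)))
}

# P(chance match at locus j) for one offspring against all pairs, treating
# the unsampled-side transmitted allele as a frequency-random draw
locus_chance_vs_pairs <- function(og, kg, g, j, f) {
  n_pairs <- nrow(g$g1)
  if (is.na(og$a1[j])) return(rep(0, n_pairs))       # strict: untyped fails
  support <- as.integer(names(f))
  x <- og$a1[j]; y <- og$a2[j]
  p1 <- kg$a1[j]; p2 <- kg$a2[j]
  parent_has <- function(a) !is.na(p1) & (a == p1 | a == p2)
  has_x <- parent_has(x); has_y <- parent_has(y)
  ks <- if (has_x && !has_y) x else if (has_y && !has_x) y else c(x, y)
  has_a <- parent_has(support)                        # vector over support
  out <- numeric(n_pairs)
  for (p in seq_len(n_pairs)) {
    union <- c(g$g1[p, j], g$g2[p, j], g$g3[p, j], g$g4[p, j])
    union <- unique(union[!is.na(union)])
    if (!length(union)) { out[p] <- 0; next }         # strict: both gp missing
    a_in <- support %in% union
    pk <- vapply(ks, function(k) {
      has_k <- parent_has(k)
      k_in <- k %in% union
      match <- if (is.na(p1)) a_in | k_in
               else ifelse(has_k | has_a, (has_k & a_in) | (has_a & k_in),
                           a_in | k_in)
      sum(f * match)
    }, numeric(1))
    out[p] <- mean(pk)
  }
  out
}

#' Expected number of false Gtrios
#'
#' For each (grandparent pair, one-parent offspring) comparison, the chance
#' that an unrelated pair passes the unexplained-allele criterion at every
#' locus is modelled by treating the offspring's unsampled-side transmitted
#' allele as a frequency-random draw at each locus; offspring genotypes,
#' the known parent and the pair are held fixed. `"analytic"` sums the
#' exact per-locus probabilities over the allele support and multiplies
#' across loci; `"monte_carlo"` redraws the unsampled-side alleles `reps`
#' times and counts full-panel matches — the two agree in expectation and
#' the Monte-Carlo mode serves as the internal oracle for the analytic
#' reconstruction.
#'
#' @inheritParams find_gtrios
#' @param freqs Allele-frequency table for the loci used.
#' @param method `"analytic"` or `"monte_carlo"`.
#' @param reps Monte-Carlo replicates (default 1000).
#' @param seed Integer seed (Monte-Carlo mode).
#' @return List: `expectation`, `se` (NA for analytic), `n_pairs`,
#'   `n_offspring`, `method`.
#' @export
expected_false_gtrios <- function(pairs, assignments, adults, offspring,
                                  freqs, loci = "primary",
                                  method = c("analytic", "monte_carlo"),
                                  reps = 1000, seed = NULL) {
  method <- match.arg(method)
  idx <- locus_index(adults, loci)
  one <- one_parent_rows(assignments)
  if (!nrow(one) || !nrow(pairs)) {
    return(list(expectation = 0, se = NA_real_, n_pairs = nrow(pairs),
                n_offspring = nrow(one), method = method))
  }
  g <- pair_allele_matrices(pairs, adults)
  loc_names <- adults$loci$locus
  if (method == "analytic") {
    total <- 0
    for (k in seq_len(nrow(one))) {
      og <- panel_genotype(offspring, one$offspring[k])
      kg <- panel_genotype(adults, one$known_parent[k])
      pmat <- as.numeric(pairs$year < one$year[k])  # age >= 1 restriction
      for (j in idx) {
        pmat <- pmat * locus_chance_vs_pairs(og, kg, g, j,
                                             freqs[[loc_names[j]]])
      }
      total <- total + sum(pmat)
    }
    return(list(expectation = total, se = NA_real_, n_pairs = nrow(pairs),
                n_offspring = nrow(one), method = "analytic"))
  }
  run <- function() {
    counts <- vapply(seq_len(reps), function(r) {
      n_match <- 0L
      for (k in seq_len(nrow(one))) {
        og <- panel_genotype(offspring, one$offspring[k])
        kg <- panel_genotype(adults, one$known_parent[k])
        # redraw the unsampled-side transmitted allele at every locus
        for (j in idx) {
          if (is.na(og$a1[j])) next
          x <- og$a1[j]; y <- og$a2[j]
          p1 <- kg$a1[j]; p2 <- kg$a2[j]
          has_x <- !is.na(p1) && (x == p1 || x == p2)
          has_y <- !is.na(p1) && (y == p1 || y == p2)
          keep <- if (has_x && !has_y) x
                  else if (has_y && !has_x) y
                  else sample_vec(c(x, y), 1)
          f <- freqs[[loc_names[j]]]
          draw <- sample_vec(as.integer(names(f)), 1, prob = f)
          og$a1[j] <- min(keep, draw); og$a2[j] <- max(keep, draw)
        }
        u <- unexplained_matrix(og, kg)
        n_match <- n_match + sum(candidate_vs_pairs(u, g, idx, FALSE)$ok &
                                   pairs$year < one$year[k])
      }
      as.numeric(n_match)
    }, numeric(1))
    list(expectation = mean(counts),
         se = stats::sd(counts) / sqrt(reps),
         n_pairs = nrow(pairs), n_offspring = nrow(one),
         method = "monte_carlo")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Relabel the unassigned side of Gtrios after sex-marker corrections
#'
#' When genotyping error at a sex-linked marker mislabels the known
#' parent's sex, a Gtrio that apparently identifies an unsampled mother may
#' actually identify an unsampled father (or vice versa). Corrections
#' relabel the side; the original side is kept in an audit column.
#'
#' @param gtrios Gtrio tibble.
#' @param corrections Data frame with `offspring`, `from`, `to` (sides,
#'   `from != to`) and optional `note`.
#' @return `gtrios` with sides relabelled and `side_original` /
#'   `correction_note` audit columns.
#' @export
apply_sex_corrections <- function(gtrios, corrections) {
  gtrios$side_original <- gtrios$side
  gtrios$correction_note <- NA_character_
  if (is.null(corrections) || !nrow(corrections)) return(gtrios)
  corrections <- tibble::as_tibble(corrections)
  if (any(corrections$from == corrections$to)) {
    stop("correction must change the side")
  }
  for (k in seq_len(nrow(corrections))) {
    hit <- gtrios$offspring == corrections$offspring[k] &
      gtrios$side == corrections$from[k]
    if (!any(hit)) {
      stop("no Gtrio found for offspring '", corrections$offspring[k],
           "' with side '", corrections$from[k], "'")
    }
    gtrios$side[hit] <- corrections$to[k]
    gtrios$correction_note[hit] <-
      if ("note" %in% names(corrections)) corrections$note[k] else
        "sex-marker correction"
  }
  gtrios
}
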