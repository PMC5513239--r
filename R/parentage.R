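#' Mismatches between a candidate parent and an offspring
#'
#' Exclusion principle: a diploid parent shares at least one of its two
#' alleles with its offspring at every locus, so a locus where the two
#' genotypes share no allele is a mismatch. Loci missing in either genotype
#' are skipped and not counted.
#'
#' @param parent,offspring Multilocus genotypes as returned by
#'   [panel_genotype()] (lists with `a1`, `a2` named by locus).
#' @param loci Optional character vector of loci to compare.
#' @return List with `mismatches` (NA with zero comparable loci — never a
#'   silent 0) and `compared`.
#' @export
pair_mismatches <- function(parent, offspring, loci = NULL) {
  if (is.null(loci)) loci <- names(parent$a1)
  p1 <- parent$a1[loci]; p2 <- parent$a2[loci]
  o1 <- offspring$a1[loci]; o2 <- offspring$a2[loci]
  comp <- !is.na(p1) & !is.na(o1)
  share <- comp & (o1 == p1 | o1 == p2 | o2 == p1 | o2 == p2)
  n_comp <- sum(comp)
  list(mismatches = if (n_comp == 0) NA_integer_ else
         as.integer(sum(comp & !share)),
       compared = as.integer(n_comp))
}

# per-locus mismatch (count) and comparable (count) matrices:
# offspring x adults, over the given locus indices
mismatch_matrices <- function(adults, offspring, idx) {
  n_off <- n_ind(offspring); n_ad <- n_ind(adults)
  M <- matrix(0L, n_off, n_ad); C <- matrix(0L, n_off, n_ad)
  for (j in idx) {
    o1 <- offspring$a1[, j]; o2 <- offspring$a2[, j]
    a1 <- adults$a1[, j]; a2 <- adults$a2[, j]
    comp <- outer(!is.na(o1), !is.na(a1), "&")
    share <- outer(o1, a1, "==") | outer(o1, a2, "==") |
             outer(o2, a1, "==") | outer(o2, a2, "==")
    share[is.na(share)] <- FALSE
    M <- M + (comp & !share)
    C <- C + comp
  }
  list(M = M, C = C)
}

# loci (indices) at which an (offspring, mother, father) trio admits no
# assignment of one offspring allele to each parent; missing loci skipped
trio_incompatible <- function(off, mo, fa, idx) {
  o1 <- off$a1[idx]; o2 <- off$a2[idx]
  m1 <- mo$a1[idx]; m2 <- mo$a2[idx]
  f1 <- fa$a1[idx]; f2 <- fa$a2[idx]
  comp <- !is.na(o1) & !is.na(m1) & !is.na(f1)
  m_has_o1 <- o1 == m1 | o1 == m2; m_has_o2 <- o2 == m1 | o2 == m2
  f_has_o1 <- o1 == f1 | o1 == f2; f_has_o2 <- o2 == f1 | o2 == f2
  ok <- (m_has_o1 & f_has_o2) | (m_has_o2 & f_has_o1)
  list(incompatible = sum(comp & !ok, na.rm = TRUE), compared = sum(comp))
}

#' Exclusion-based parent assignment
#'
#' For each offspring, candidate mothers and fathers are adults (matched on
#' year) whose pairwise mismatch count is within `budget` over at least
#' `min_loci` comparable loci. A (mother, father) pair is assigned only if
#' it is additionally jointly Mendelian-compatible — an assignment of one
#' offspring allele to each parent exists — at all but at most `budget`
#' loci. Ties among minimal solutions are never broken arbitrarily: the
#' ambiguous side is left unassigned and the ambiguity is recorded in the
#' `note` column.
#'
#' @param adults `geno_panel` with recorded sexes; adults of sex
#'   `"unknown"` are candidates for both sides.
#' @param offspring `geno_panel` of offspring (matched to adults by `year`).
#' @param budget Mismatch budget per parent-offspring pair (default 1).
#' @param min_loci Minimum comparable loci for any assignment (default 9).
#' @param loci Locus subset (default `"primary"`).
#' @return Tibble: `offspring`, `year`, `mother`, `father` (NA =
#'   unassigned), per-side mismatch and comparable-locus counts, `category`
#'   (`both`, `mother_unassigned`, `father_unassigned`, `none`) and `note`.
#' @export
assign_parents <- function(adults, offspring, budget = 1, min_loci = 9,
                           loci = "primary") {
  idx <- locus_index(adults, loci)
  min_loci <- min(min_loci, length(idx))
  out <- lapply(sort(unique(offspring$ind$year)), function(y) {
    assign_parents_year(panel_subset(adults, years = y),
                        panel_subset(offspring, years = y),
                        budget, min_loci, idx)
  })
  res <- dplyr::bind_rows(out)
  res[order(match(res$offspring, offspring$ind$id)), ]
}

assign_parents_year <- function(adults, offspring, budget, min_loci, idx) {
  n_off <- n_ind(offspring)
  off_ids <- offspring$ind$id
  off_years <- offspring$ind$year
  blank <- tibble::tibble(offspring = off_ids,
                          year = off_years,
                          mother = NA_character_, father = NA_character_,
                          mother_mismatch = NA_integer_,
                          father_mismatch = NA_integer_,
                          mother_loci = NA_integer_,
                          father_loci = NA_integer_,
                          category = "none", note = "")
  if (n_off == 0 || n_ind(adults) == 0) return(blank)
  mm <- mismatch_matrices(adults, offspring, idx)
  cand <- mm$M <= budget & mm$C >= min_loci
  is_f <- adults$ind$sex %in% c("female", "unknown")
  is_m <- adults$ind$sex %in% c("male", "unknown")
  res <- blank
  for (o in seq_len(n_off)) {
    og <- list(a1 = offspring$a1[o, ], a2 = offspring$a2[o, ])
    cm <- which(cand[o, ] & is_f)
    cf <- which(cand[o, ] & is_m)
    note <- character(0)
    pick_side <- function(side_idx) {
      # unique minimal-mismatch candidate on one side, else NA + ambiguity
      if (!length(side_idx)) return(list(id = NA_character_, i = NA_integer_))
      mins <- side_idx[mm$M[o, side_idx] == min(mm$M[o, side_idx])]
      if (length(mins) > 1) {
        note <<- c(note, "ambiguous")
        return(list(id = NA_character_, i = NA_integer_))
      }
      list(id = adults$ind$id[mins], i = mins)
    }
    mo_i <- NA_integer_; fa_i <- NA_integer_
    if (length(cm) && length(cf)) {
      pairs <- expand.grid(m = cm, f = cf)
      pairs <- pairs[pairs$m != pairs$f, , drop = FALSE]
      score <- vapply(seq_len(nrow(pairs)), function(k) {
        tr <- trio_incompatible(og,
                                list(a1 = adults$a1[pairs$m[k], ],
                                     a2 = adults$a2[pairs$m[k], ]),
                                list(a1 = adults$a1[pairs$f[k], ],
                                     a2 = adults$a2[pairs$f[k], ]),
                                idx)
        if (tr$compared < min_loci || tr$incompatible > budget) NA_real_
        else as.numeric(tr$incompatible)
      }, numeric(1))
      valid <- which(!is.na(score))
      if (length(valid)) {
        best <- valid[score[valid] == min(score[valid])]
        ms <- unique(pairs$m[best]); fs <- unique(pairs$f[best])
        if (length(best) == 1 || (length(ms) == 1 && length(fs) == 1)) {
          mo_i <- ms; fa_i <- fs
        } else {
          if (length(ms) == 1) mo_i <- ms
          if (length(fs) == 1) fa_i <- fs
          note <- c(note, "ambiguous_pair")
        }
      } else {
        # marginal candidates exist on both sides but no joint trio works:
        # keep the lower-mismatch side, drop the other (tie -> neither)
        pm <- pick_side(cm); pf <- pick_side(cf)
        if (!is.na(pm$i) && !is.na(pf$i)) {
          note <- c(note, "joint_incompatible")
          if (mm$M[o, pm$i] < mm$M[o, pf$i]) mo_i <- pm$i
          else if (mm$M[o, pf$i] < mm$M[o, pm$i]) fa_i <- pf$i
        } else if (!is.na(pm$i)) mo_i <- pm$i
        else if (!is.na(pf$i)) fa_i <- pf$i
      }
    } else if (length(cm)) {
      mo_i <- pick_side(cm)$i
    } else if (length(cf)) {
      fa_i <- pick_side(cf)$i
    }
    if (!is.na(mo_i)) {
      res$mother[o] <- adults$ind$id[mo_i]
      res$mother_mismatch[o] <- mm$M[o, mo_i]
      res$mother_loci[o] <- mm$C[o, mo_i]
    }
    if (!is.na(fa_i)) {
      res$father[o] <- adults$ind$id[fa_i]
      res$father_mismatch[o] <- mm$M[o, fa_i]
      res$father_loci[o] <- mm$C[o, fa_i]
    }
    res$note[o] <- paste(unique(note), collapse = ";")
  }
  res$category <- ifelse(!is.na(res$mother) & !is.na(res$father), "both",
                  ifelse(!is.na(res$father), "mother_unassigned",
                  ifelse(!is.na(res$mother), "father_unassigned", "none")))
  res
}

#' Pedigree category summary
#'
#' Partitions assignments into the four exclusive categories (both parents,
#' mother unassigned, father unassigned, none) with counts and fractions.
#'
#' @param assignments Output of [assign_parents()].
#' @return Tibble with `category`, `n`, `fraction` (fractions sum to 1).
#' @export
categorize <- function(assignments) {
  if (!nrow(assignments)) stop("no assignments to categorize")
  lev <- c("both", "mother_unassigned", "father_unassigned", "none")
  n <- unname(vapply(lev, function(l) sum(assignments$category == l),
                     integer(1)))
  tibble::tibble(category = lev, n = n, fraction = n / sum(n))
}

#' Unique mate pairs from a pedigree
#'
#' @param assignments Output of [assign_parents()]; only offspring with
#'   both parents contribute.
#' @return Tibble: `female`, `male`, `year`, `n_offspring`.
#' @export
extract_mate_pairs <- function(assignments) {
  both <- assignments[assignments$category == "both", ]
  if (!nrow(both)) {
    return(tibble::tibble(female = character(0), male = character(0),
                          year = integer(0), n_offspring = integer(0)))
  }
  dplyr::summarise(dplyr::group_by(both, female = .data$mother,
                                   male = .data$father, year = .data$year),
                   n_offspring = dplyr::n(), .groups = "drop")
}

#' Strict one-parent-known search for mis-sexed adults
#'
#' For every offspring with exactly one assigned parent, candidate adults
#' are those recorded with the *same* sex as the known parent (the missing
#' parent may have been mis-sexed) that were not assigned to any offspring
#' in that year's pedigree. A candidate is reported only when the (known
#' parent, candidate, offspring) trio is jointly Mendelian-compatible at
#' every panel locus with no missing data in any of the three genotypes.
#' Parent-offspring pairs carrying missing data are excluded from the
#' search and tallied.
#'
#' @param assignments Output of [assign_parents()].
#' @param adults Adult `geno_panel`.
#' @param offspring Offspring `geno_panel`.
#' @param loci Locus subset used for the strict match (default `"primary"`).
#' @return List with `flips` (tibble: offspring, known_parent, known_side,
#'   candidate, recorded_sex, year) and `tally` per year and side
#'   (included / excluded / assignments).
#' @export
strict_sex_search <- function(assignments, adults, offspring,
                              loci = "primary") {
  idx <- locus_index(adults, loci)
  one <- assignments[assignments$category %in%
                     c("mother_unassigned", "father_unassigned"), ]
  flips <- list(); tally <- list()
  for (y in sort(unique(one$year))) {
    ay <- panel_subset(adults, years = y)
    used <- unique(stats::na.omit(c(
      assignments$mother[assignments$year == y],
      assignments$father[assignments$year == y])))
    for (side in c("father_only", "mother_only")) {
      rows <- one[one$year == y &
                  one$category == (if (side == "father_only")
                    "mother_unassigned" else "father_unassigned"), ]
      included <- 0L; excluded <- 0L; n_assign <- 0L
      for (k in seq_len(nrow(rows))) {
        known_id <- if (side == "father_only") rows$father[k] else
          rows$mother[k]
        og <- panel_genotype(offspring, rows$offspring[k])
        kg <- panel_genotype(adults, known_id)
        if (anyNA(og$a1[idx]) || anyNA(kg$a1[idx])) {
          excluded <- excluded + 1L
          next
        }
        included <- included + 1L
        known_sex <- ay$ind$sex[match(known_id, ay$ind$id)]
        pool <- ay$ind$id[ay$ind$sex == known_sex &
                          !ay$ind$id %in% c(used, known_id)]
        for (cid in pool) {
          cg <- panel_genotype(adults, cid)
          if (anyNA(cg$a1[idx])) next
          tr <- trio_incompatible(og, kg, cg, idx)
          if (tr$incompatible == 0L && tr$compared == length(idx)) {
            n_assign <- n_assign + 1L
            flips[[length(flips) + 1L]] <-
              tibble::tibble(offspring = rows$offspring[k],
                             known_parent = known_id, known_side = side,
                             candidate = cid, recorded_sex = known_sex,
                             year = y)
          }
        }
      }
      tally[[length(tally) + 1L]] <-
        tibble::tibble(year = y, side = side, included = included,
                       excluded = excluded, assignments = n_assign)
    }
  }
  list(flips = if (length(flips)) dplyr::bind_rows(flips) else
         tibble::tibble(offspring = character(0), known_parent = character(0),
                        known_side = character(0), candidate = character(0),
                        recorded_sex = character(0), year = integer(0)),
       tally = if (length(tally)) dplyr::bind_rows(tally) else
         tibble::tibble())
}
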