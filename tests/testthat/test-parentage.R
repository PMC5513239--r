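test_that("pair mismatches follow the shared-allele exclusion rule", {
  p <- quick_panel("P", "female", 2008, a1 = c(101, 101), a2 = c(103, 101))
  o <- quick_panel("O", "unknown", 2008, a1 = c(103, 105), a2 = c(105, 107))
  # locus 1: parent {101,103} vs offspring {103,105} share 103 -> 0
  # locus 2: parent {101,101} vs offspring {105,107} disjoint -> 1
  r <- pair_mismatches(panel_genotype(p, "P"), panel_genotype(o, "O"))
  expect_equal(r$mismatches, 1)
  expect_equal(r$compared, 2)
  # missing loci are skipped, zero comparable loci is a sentinel not a zero
  p2 <- quick_panel("P", "female", 2008, a1 = c(NA, NA), a2 = c(NA, NA))
  r2 <- pair_mismatches(panel_genotype(p2, "P"), panel_genotype(o, "O"))
  expect_true(is.na(r2$mismatches))
  expect_equal(r2$compared, 0)
})

test_that("mismatch counts agree with a per-locus brute force on 11 loci", {
  set.seed(51)
  for (rep in 1:5) {
    pa <- c(sample(101:121, 11, TRUE)); pb <- c(sample(101:121, 11, TRUE))
    oa <- c(sample(101:121, 11, TRUE)); ob <- c(sample(101:121, 11, TRUE))
    p <- quick_panel("P", "female", 2008, pa, pb)
    o <- quick_panel("O", "unknown", 2008, oa, ob)
    brute <- sum(vapply(1:11, function(j) {
      !any(c(oa[j], ob[j]) %in% c(pa[j], pb[j]))
    }, logical(1)))
    r <- pair_mismatches(panel_genotype(p, "P"), panel_genotype(o, "O"))
    expect_equal(r$mismatches, brute)
    expect_equal(r$compared, 11)
  }
})

test_that("a clean trio is recovered and a removed parent side is unassigned", {
  sim <- planted_scenario(seed = 52, n_plant = 0)
  asn <- assign_parents(sim$adults, sim$offspring)
  expect_true(all(asn$category == "both"))
  expect_true(all(asn$mother_mismatch == 0))
  # truth check: precision/recall of the parent pair is 1 at zero error
  tr <- sim$truth$parents[match(asn$offspring, sim$truth$parents$offspring), ]
  expect_identical(asn$mother, tr$mother)
  expect_identical(asn$father, tr$father)
  # remove one true father's genotype: his offspring lose only the father
  fa <- tr$father[1]
  kids <- tr$offspring[tr$father == fa]
  adults2 <- panel_subset(sim$adults, keep = sim$adults$ind$id != fa)
  asn2 <- assign_parents(adults2, sim$offspring)
  expect_true(all(asn2$category[asn2$offspring %in% kids] ==
                    "father_unassigned"))
  expect_identical(asn2$mother[asn2$offspring %in% kids],
                   tr$mother[tr$father == fa])
})

test_that("tied candidates are left unassigned with a logged ambiguity", {
  # two cloned candidate fathers, distinct mother
  mo <- c(101, 111); fa <- c(105, 115)
  off_a1 <- c(101, 111); off_a2 <- c(105, 115)
  adults <- quick_panel(c("MO", "FA1", "FA2"),
                        c("female", "male", "male"), 2008,
                        a1 = c(mo[1], fa[1], fa[1], mo[2], fa[2], fa[2]),
                        a2 = c(mo[1], fa[1], fa[1], mo[2], fa[2], fa[2]))
  off <- quick_panel("O", "unknown", 2008, off_a1, off_a2)
  asn <- assign_parents(adults, off, min_loci = 2)
  expect_true(is.na(asn$father))
  expect_equal(asn$mother, "MO")
  expect_match(asn$note, "ambiguous")
  expect_equal(asn$category, "father_unassigned")
})

test_that("assignment is invariant to adult input order", {
  sim <- planted_scenario(seed = 53, n_plant = 0, n_adults = 15,
                          n_offspring = 40)
  asn1 <- assign_parents(sim$adults, sim$offspring)
  perm <- withr::with_seed(54, sample.int(n_ind(sim$adults)))
  shuffled <- panel_subset(sim$adults)
  shuffled <- geno_panel(shuffled$ind[perm, ], shuffled$a1[perm, ],
                         shuffled$a2[perm, ], shuffled$loci)
  asn2 <- assign_parents(shuffled, sim$offspring)
  expect_identical(asn1$mother, asn2$mother)
  expect_identical(asn1$father, asn2$father)
})

test_that("raising the mismatch budget never lowers the both-parents fraction", {
  sim <- planted_scenario(seed = 55, n_plant = 0, n_adults = 15,
                          n_offspring = 60, error_rate = 0.05)
  frac <- vapply(0:2, function(b) {
    a <- assign_parents(sim$adults, sim$offspring, budget = b)
    categorize(a)$fraction[1]
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
})

test_that("category fractions partition the offspring", {
  sim <- planted_scenario(seed = 56, n_plant = 0, n_adults = 12,
                          n_offspring = 50, error_rate = 0.08)
  asn <- assign_parents(sim$adults, sim$offspring)
  cat <- categorize(asn)
  expect_equal(sum(cat$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(cat$n), nrow(asn))
  # constructed example: 2 both, 1 father-only-assigned, 1 none
  fake <- tibble::tibble(category = c("both", "both", "mother_unassigned",
                                      "none"))
  expect_equal(categorize(fake)$fraction, c(0.5, 0.25, 0, 0.25))
})

test_that("mate pairs deduplicate and recover the simulated truth", {
  fake <- tibble::tibble(
    offspring = c("O1", "O2", "O3", "O4"),
    year = 2008L,
    mother = c("F1", "F1", "F1", NA),
    father = c("M1", "M1", "M2", "M3"),
    category = c("both", "both", "both", "mother_unassigned"))
  mp <- extract_mate_pairs(fake)
  expect_equal(nrow(mp), 2)
  expect_equal(mp$n_offspring[mp$male == "M1"], 2)
  # empty when nothing has both parents
  expect_equal(nrow(extract_mate_pairs(fake[4, ])), 0)
  # all true pairs recovered on clean synthetic data
  sim <- planted_scenario(seed = 57, n_plant = 0)
  asn <- assign_parents(sim$adults, sim$offspring)
  mp2 <- extract_mate_pairs(asn)
  truth <- sim$truth$mate_pairs
  expect_equal(nrow(mp2), nrow(truth))
  expect_setequal(paste(mp2$female, mp2$male, mp2$year),
                  paste(truth$female, truth$male, truth$year))
})

test_that("strict sex search reports a fully typed mis-sexed true parent", {
  set.seed(58)
  L <- 11
  mo_a <- sample(seq(101, 199, 2), L, TRUE)
  mo_b <- sample(seq(101, 199, 2), L, TRUE)
  fa_a <- sample(seq(201, 299, 2), L, TRUE)
  fa_b <- sample(seq(201, 299, 2), L, TRUE)
  # offspring takes one allele from each parent
  adults <- quick_panel(c("MO", "FA", "X1"), c("female", "female", "male"),
                        2008,
                        a1 = c(rbind(mo_a, fa_a, sample(301:399, L, TRUE))),
                        a2 = c(rbind(mo_b, fa_b, sample(301:399, L, TRUE))))
  off <- quick_panel("O1", "unknown", 2008, a1 = mo_a, a2 = fa_a)
  asn <- tibble::tibble(offspring = "O1", year = 2008L, mother = "MO",
                        father = NA_character_, category = "father_unassigned")
  res <- strict_sex_search(asn, adults, off)
  expect_equal(nrow(res$flips), 1)
  expect_equal(res$flips$candidate, "FA")
  expect_equal(res$flips$known_parent, "MO")
  # with one locus missing in the candidate, the pair is still included but
  # yields no assignment; with missing data in the known pair it is excluded
  adults_na <- adults
  a1 <- adults_na$a1; a2 <- adults_na$a2
  a1["FA", 1] <- NA; a2["FA", 1] <- NA
  adults_na <- geno_panel(adults_na$ind, a1, a2, adults_na$loci)
  res2 <- strict_sex_search(asn, adults_na, off)
  expect_equal(nrow(res2$flips), 0)
  o_na <- off
  b1 <- o_na$a1; b2 <- o_na$a2; b1[1, 1] <- NA; b2[1, 1] <- NA
  o_na <- geno_panel(o_na$ind, b1, b2, o_na$loci)
  # the known parent here is the mother, so the pair sits in "mother only"
  res3 <- strict_sex_search(asn, adults, o_na)
  expect_equal(res3$tally$excluded[res3$tally$side == "mother_only"], 1)
  expect_equal(res3$tally$included[res3$tally$side == "mother_only"], 0)
})

test_that("no sex flips arise by chance at 11 high-diversity loci", {
  hits <- 0L
  for (s in 1:8) {
    sim <- planted_scenario(seed = 600 + s, n_plant = 0, n_adults = 20,
                            n_offspring = 60)
    # drop one father to create one-parent offspring, then search
    fa <- sim$truth$parents$father[1]
    adults2 <- panel_subset(sim$adults, keep = sim$adults$ind$id != fa)
    asn <- assign_parents(adults2, sim$offspring)
    res <- strict_sex_search(asn, adults2, sim$offspring)
    hits <- hits + nrow(res$flips)
  }
  expect_equal(hits, 0)
})
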