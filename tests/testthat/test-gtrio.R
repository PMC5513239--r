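test_that("unexplained alleles follow the one-parent-known rule", {
  expect_equal(unexplained_alleles(c(101, 105), c(101, 103)), 105)
  expect_equal(unexplained_alleles(c(101, 105), c(101, 105)), c(101, 105))
  expect_equal(unexplained_alleles(c(101, 105), c(103, 107)), c(101, 105))
  expect_equal(unexplained_alleles(c(101, 105), c(NA, NA)), c(101, 105))
  expect_equal(unexplained_alleles(c(101, 101), c(101, 103)), 101)
})

test_that("the true grandparent pair of a planted adult is found and confirmed", {
  sim <- planted_scenario(seed = 81, n_plant = 2)
  fun <- gtrio_funnel(sim)
  for (i in seq_len(nrow(sim$truth$roster))) {
    ro <- sim$truth$roster[i, ]
    hit <- fun$candidates$gp_female == ro$gp_female &
      fun$candidates$gp_male == ro$gp_male
    expect_true(any(hit))
    ret <- fun$retained[fun$retained$gp_female == ro$gp_female &
                          fun$retained$gp_male == ro$gp_male, ]
    expect_true(nrow(ret) >= 1)
    expect_true(all(ret$side == "father"))   # planted males
  }
  # funnel monotonicity
  expect_gte(nrow(fun$candidates), sum(fun$confirmed$status == "confirmed"))
  expect_gte(sum(fun$confirmed$status == "confirmed"), nrow(fun$retained))
})

test_that("a pair whose union misses the unexplained allele is excluded", {
  # offspring {101,105}, known parent {101,103} -> U = {105};
  # pair union {107,109} u {111,113} cannot explain it
  adults <- quick_panel(c("KP", "GF", "GM"), c("male", "female", "male"),
                        2008,
                        a1 = c(101, 107, 111), a2 = c(103, 109, 113))
  off <- quick_panel("O", "unknown", 2009, a1 = 101, a2 = 105)
  pairs <- tibble::tibble(female = "GF", male = "GM", year = 2008L,
                          n_offspring = 1L)
  asn <- tibble::tibble(offspring = "O", year = 2009L, mother = NA_character_,
                        father = "KP", category = "mother_unassigned")
  expect_equal(nrow(find_gtrios(pairs, asn, adults, off)), 0)
  # flip one grandparent allele to 105: now a candidate on the mother side
  a1 <- adults$a1; a1["GF", 1] <- 105L
  adults2 <- geno_panel(adults$ind, a1, adults$a2, adults$loci)
  g <- find_gtrios(pairs, asn, adults2, off)
  expect_equal(nrow(g), 1)
  expect_equal(g$side, "mother")
  # empty pair list is an empty result, not an error
  expect_equal(nrow(find_gtrios(pairs[0, ], asn, adults, off)), 0)
})

test_that("confirmation demands complete extra-locus genotypes and compatibility", {
  roles <- c("primary", "confirmation")
  adults <- quick_panel(c("KP", "GF", "GM"), c("male", "female", "male"),
                        2008,
                        a1 = c(101, 105, 105, 201, 205, 205),
                        a2 = c(103, 105, 105, 203, 205, 205), roles = roles)
  off <- quick_panel("O", "unknown", 2009, a1 = c(101, 201), a2 = c(105, 205),
                     roles = roles)
  pairs <- tibble::tibble(female = "GF", male = "GM", year = 2008L)
  asn <- tibble::tibble(offspring = "O", year = 2009L, mother = NA_character_,
                        father = "KP", category = "mother_unassigned")
  cand <- find_gtrios(pairs, asn, adults, off)
  expect_equal(nrow(cand), 1)
  conf <- confirm_gtrios(cand, adults, off)
  expect_equal(conf$status, "confirmed")
  # untyped known parent at the extra locus -> excluded(missing)
  a1 <- adults$a1; a2 <- adults$a2
  a1["KP", 2] <- NA; a2["KP", 2] <- NA
  conf2 <- confirm_gtrios(cand, geno_panel(adults$ind, a1, a2, adults$loci),
                          off)
  expect_equal(conf2$status, "excluded")
  expect_equal(conf2$reason, "missing_extra_genotype")
  # incompatible at the extra locus -> excluded(mismatch)
  b1 <- adults$a1; b2 <- adults$a2
  b1["GF", 2] <- 299L; b2["GF", 2] <- 299L
  b1["GM", 2] <- 299L; b2["GM", 2] <- 299L
  conf3 <- confirm_gtrios(cand, geno_panel(adults$ind, b1, b2, adults$loci),
                          off)
  expect_equal(conf3$status, "excluded")
  expect_equal(conf3$reason, "extra_locus_mismatch")
})

test_that("offspring matching several distinct pairs are excluded entirely", {
  g <- tibble::tibble(
    offspring = c("O1", "O2", "O2", "O3", "O3"),
    side = "father",
    gp_female = c("F1", "F2", "F3", "F4", "F4"),
    gp_male = c("M1", "M2", "M3", "M4", "M4"),
    gp_year = 2008L, status = "confirmed")
  res <- resolve_ambiguities(g)
  expect_setequal(res$retained$offspring, c("O1", "O3"))
  # O3 matched the same pair twice (e.g. full-sib planted adults): kept
  expect_equal(res$n_ambiguous_offspring, 1)
  expect_true(all(res$excluded$offspring == "O2"))
  expect_true(all(res$excluded$reason == "ambiguous"))
})

test_that("the analytic false-Gtrio expectation obeys the product rule", {
  # 1 pair, 1 offspring, 2 loci with hand-computable per-locus chances
  freqs <- list(L1 = c("101" = 0.2, "103" = 0.3, "105" = 0.5),
                L2 = c("101" = 0.2, "103" = 0.3, "105" = 0.5))
  class(freqs) <- "allele_freqs"
  # known parent {103, 999}: offspring {101,103} keeps k = 103, U' = {a}
  # unless a is also parental; pair union = {101} u {105}
  adults <- quick_panel(c("KP", "GF", "GM"), c("male", "female", "male"),
                        2008,
                        a1 = c(103, 101, 105, 103, 101, 105),
                        a2 = c(999, 101, 105, 999, 101, 105))
  off <- quick_panel("O", "unknown", 2009,
                     a1 = c(101, 101), a2 = c(103, 103))
  pairs <- tibble::tibble(female = "GF", male = "GM", year = 2008L)
  asn <- tibble::tibble(offspring = "O", year = 2009L, mother = NA_character_,
                        father = "KP", category = "mother_unassigned")
  # per locus: draws 101 (p = .2) and 105 (p = .5) land in the union,
  # 103 gives U' = {103} and misses -> p_locus = 0.7
  res <- expected_false_gtrios(pairs, asn, adults, off, freqs,
                               method = "analytic")
  expect_equal(res$expectation, 0.7 * 0.7, tolerance = 1e-12)
  # zero support overlap: union outside the frequency support and offspring
  pairs_far <- quick_panel(c("KP", "GF", "GM"), c("male", "female", "male"),
                           2008,
                           a1 = c(103, 881, 883, 103, 881, 883),
                           a2 = c(999, 881, 883, 999, 881, 883))
  res0 <- expected_false_gtrios(pairs, asn, pairs_far, off, freqs,
                                method = "analytic")
  expect_equal(res0$expectation, 0)
})

test_that("analytic and Monte-Carlo false-Gtrio modes agree across panels", {
  for (s in 1:4) {
    cfg <- sim_config(years = c(2007, 2009), n_females = 10, n_males = 10,
                      n_offspring = 35,
                      loci = locus_spec(n_primary = 4, n_confirmation = 0,
                                        A_primary = 8, ho_primary = 0.8),
                      remove_males = 2, seed = 820 + s)
    sim <- simulate_population(cfg)
    asn <- assign_parents(sim$adults, sim$offspring, min_loci = 3)
    pairs <- extract_mate_pairs(asn)
    freqs <- allele_frequencies(sim$adults, "primary")
    an <- expected_false_gtrios(pairs, asn, sim$adults, sim$offspring, freqs,
                                method = "analytic")
    mc <- expected_false_gtrios(pairs, asn, sim$adults, sim$offspring, freqs,
                                method = "monte_carlo", reps = 200,
                                seed = 830 + s)
    expect_lt(abs(an$expectation - mc$expectation), 3 * mc$se + 1e-9)
  }
})

test_that("sex corrections relabel sides with an audit trail", {
  g <- tibble::tibble(offspring = c("O1", "O2"), side = c("mother", "father"),
                      gp_female = "F1", gp_male = "M1", gp_year = 2008L,
                      status = "confirmed")
  out <- apply_sex_corrections(g, data.frame(offspring = "O1",
                                             from = "mother", to = "father"))
  expect_equal(out$side, c("father", "father"))
  expect_equal(out$side_original, c("mother", "father"))
  # empty corrections are the identity
  out2 <- apply_sex_corrections(g, NULL)
  expect_equal(out2$side, g$side)
  expect_error(
    apply_sex_corrections(g, data.frame(offspring = "ZZ", from = "mother",
                                        to = "father")), "ZZ")
  expect_error(
    apply_sex_corrections(g, data.frame(offspring = "O1", from = "mother",
                                        to = "mother")), "change the side")
})
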