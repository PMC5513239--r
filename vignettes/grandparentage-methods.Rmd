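---
title: "Grandparentage assignment for near-completely sampled pedigrees: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grandparentage assignment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inference problem

A trap-and-haul reintroduction gives an unusual guarantee: essentially
every anadromous adult that could have spawned above the dam was handled
and tissue-sampled. Juveniles collected upstream should therefore assign to
two sampled parents. The fraction that does not is a diagnostic signal, and
this package implements the chain of methods that decomposes it into human
error (genotyping error, missing adult genotypes, mis-sexed adults) and a
biological remainder: unsampled freshwater-maturing spawners — precocial
resident males (age 1–2) and adfluvial adults (age 3+) — detected by
grandparentage.

## Exclusion parentage with a mismatch budget

`assign_parents()` is pure Mendelian exclusion. A candidate parent is
compatible with an offspring at a locus when the two genotypes share at
least one allele; a candidate is retained when it mismatches at no more
than `budget` loci (default 1, the criterion used on the real pedigrees) over
at least `min_loci` comparable loci (default 9 of 11, bounding false
positives when genotypes have missing loci). A (mother, father) pair is
assigned only when it is additionally *jointly* compatible — an assignment
of one offspring allele to each parent exists — at all but at most `budget`
loci; this blocks trios such as mother \{a,a\}, father \{a,a\}, offspring
\{b,c\} that two marginal checks with a shared budget would admit.

Ties are never broken arbitrarily. If two candidates on a side achieve the
same minimal mismatch count, the side is left unassigned and the ambiguity
is logged in the `note` column. This has one consequence worth knowing
about: a fully typed mis-sexed true parent is *always* a perfect same-sex
co-candidate alongside the true parent of that sex, so under pure exclusion
its offspring land in the `none` category with an `ambiguous` note rather
than in a one-parent category. The likelihood machinery used on the real
data could nominate one parent in that situation; exclusion cannot, and we
prefer the logged ambiguity to a coin flip. `strict_sex_search()` therefore
operates on its contractual input — offspring with exactly one assigned
parent — wherever those arise (typically when the mis-sexed adult also
carries missing or erroneous genotypes), and applies the strict criterion:
candidates recorded with the *same* sex as the known parent, not assigned
to any offspring that year, matching at **all** loci with **no** missing
data in any of the three genotypes. Pairs excluded for missing data are
tallied, mirroring the bookkeeping of the original analysis.

## The Gtrio criterion

A grandparent pair shares one in four of its alleles per locus with a
grandchild. With one parent known, `unexplained_alleles()` strips the
offspring alleles the known parent can account for: for offspring \{x, y\},
y is unexplained iff the parent carries x, x is unexplained iff the parent
carries y, and if the parent carries neither (the tolerated mismatch locus)
or its genotype is missing, both alleles are kept. This is deliberately the
most permissive reading of the mismatch locus — it is conservative toward
*finding* candidates, with the confirmation loci as the specificity
backstop. A pair is a candidate for a grandoffspring when the unexplained
set intersects the pair's allele union at **every** primary locus
(`find_gtrios()`).

Three structural restrictions control false positives:

* comparisons are limited to pedigree-evidenced mate pairs (pairs observed
  to have joint offspring), and to pairs that mated *strictly before* the
  offspring's pedigree year — an unsampled parent must be at least age 1
  when it spawns;
* candidates must additionally match at the 4 confirmation loci with all
  four individuals fully typed there (`confirm_gtrios()`; missing
  confirmation genotypes exclude the trio with reason
  `missing_extra_genotype`);
* a grandoffspring whose unassigned side matches more than one distinct
  grandparent pair is excluded entirely (`resolve_ambiguities()`). We key
  ambiguity on the offspring and side across all grandparent years: two
  pairs from different mating years are still irreconcilable for a single
  unsampled parent. Two planted full-sib unsampled adults from the *same*
  pair do not trigger the rule, because the pair identity is identical.

Missing grandparent data is strict by default, as it was on the real data:
a locus where both grandparents are untyped fails the trio. Setting
`allow_skip = TRUE` relaxes this to at most one skipped locus, flagged in
the output.

## Expected false Gtrios

`expected_false_gtrios()` quantifies how many candidates chance alone would
produce. The model holds the offspring, known parent and pair genotypes
fixed and treats the offspring's *unsampled-side transmitted allele* as a
frequency-random draw at each locus: the explained allele (the one the
known parent carries) is kept, the other allele is replaced by a draw from
the locus frequency table, the unexplained set is recomputed, and the trio
criterion is evaluated. The analytic mode sums the exact per-locus match
probability over the allele support and multiplies across loci (when the
explained allele is itself ambiguous — parent carries both or neither —
the two choices are averaged); the Monte-Carlo mode performs the
replacement literally and counts full-panel matches. The two modes agree in
expectation by construction, and the Monte-Carlo mode is the package's
internal oracle for the analytic reconstruction — the exact formula used in
the original study is cited there to earlier work and not restated, so our
analytic form is validated against simulation, not against the published
expectations.

## From Gtrios to life history and CRR

Each unique (grandparent pair, unassigned side) is conservatively assumed
to correspond to exactly one unsampled adult (`infer_unsampled_adults()`).
Sex follows the unassigned side; the cohort is the pair's mating year; each
supporting grandoffspring contributes an observed spawning age (pedigree
year − mating year); the assigned age is the *earliest* observed spawning
age — the minimal assumption for a possibly repeat-spawning adult — with
all observed ages retained in a list column. Males of age ≤ 2 are
precocial residents; everything else is adfluvial; a female below age 3 is
a hard error, because female Chinook salmon cannot mature before age 3
(`classify_tactic()`). Sex-marker corrections (`apply_sex_corrections()`)
relabel the unassigned side with an audit trail before inference; the
female-maturity check deliberately fires downstream, in classification,
where the corrected sides are known.

CRR (cohort replacement rate) is female-based: offspring credited per
reintroduced female of a cohort. Each inferred adfluvial female adds one
matured adult: `updated = base + n_adfluvial / n_females`, with the percent
increase relative to the base rate. Printed-style values use half-up
rounding (2 decimals for CRR, integer percents); unrounded values are
always emitted alongside. We do not attempt to reproduce the published 2007
updated CRR exactly: under the printed rounded base (0.40) the arithmetic
gives 0.47, so the published 0.46 evidently used an unrounded base from the
companion study that is not available here; the 2008 update (0.31 → 0.35,
+13%) is self-consistent under printed values and is the one the acceptance
script recomputes.

## Rank tests

Per-pedigree percentages are compared with rank tests
(`compare_observed_expected()`). Both the unpaired rank-sum and the paired
signed-rank are exposed and neither is hard-coded: the statistic reported
in the source analysis for the mothers-vs-fathers comparison (V = 28 on six
pedigrees) exceeds the paired signed-rank maximum of 21 for n = 6, so which
test was actually run there is ambiguous, and we leave the choice to the
caller. `rank_sum_test()` reports the Mann-Whitney U of the first group
with mid-ranked ties; two-sided p-values are computed by full enumeration
of the `choose(n1+n2, n1)` labelings when both groups have ≤ 10
observations (exact even under ties, where the classical tables do not
apply) and by the tie-corrected normal approximation with continuity
correction otherwise. `signed_rank_test()` enumerates the `2^n` sign
patterns up to n = 14. Multiple-testing control uses Benjamini-Hochberg
step-up via `stats::p.adjust` behind `bh_fdr()`.

## The simulator and its study conditions

`simulate_population()` emulates the study system: annual cohorts of
reintroduced adults drawn under Hardy-Weinberg from a configurable locus
panel, Mendelian offspring, planted unsampled spawners, and degradation.
Defaults are the observed panel characteristics: 11 primary loci with 34
alleles and observed heterozygosity 0.92, 4 confirmation loci with 16
alleles and heterozygosity 0.83. Frequency shapes are `uniform`,
`geometric` (default, mimicking skewed microsatellite spectra; the decay
rate is solved per locus by `uniroot` so that expected heterozygosity
1 − Σp² hits the configured target) and `empirical`. Reproductive success
is uniform by default — the model used by the original simulations — with a
gamma-weighted `overdispersed` alternative (negative-binomial family
offspring counts) because uniform success is acknowledged not to reflect
salmon biology; how many offspring each pair produced in the original
simulations is not stated, so the per-pair count is left free.
Genotyping error is per-allele replacement by a frequency-weighted draw, so
a replacement can silently coincide with the original allele: the realized
discordance is `rate × (1 − p_same)`, which the tests verify analytically.
The error process is panel-wide, not locus-specific, matching the model
used by the source simulations.

Planted unsampled spawners are Mendelian offspring of a true mate pair of
their cohort year; their genotypes never enter a sampled panel. Each mates
with one randomly chosen sampled anadromous adult of the opposite sex in
year `cohort + age` — the one-parent-known framing; adfluvial × adfluvial
matings are deliberately not generated by default, mirroring the stated
limitation of the grandparentage design. Female plantings below age 3 are
rejected. Degradation removes whole genotypes (missing tissue at the scale
of the published rosters: a few adults per sex-year), blanks ≥ 2 loci for
designated individuals, and flips recorded sexes; every event is logged in
the truth tables.

What the simulator does **not** emulate: overlapping-generation
demographics, selection and fitness differences, locus-specific error
rates, null alleles and allele dropout, family-correlated sampling of
juveniles, and population structure. Passing tests therefore demonstrate
the correctness of the inference chain under the stated generative model,
not the field accuracy of the original study.

## Problem sizes and numerical choices

Tests and the acceptance script run scaled-down study conditions — two to
three cohort years, 60–80 adults and 120–160 sampled offspring per year —
chosen so the full chain (including the Monte-Carlo oracles at a few
hundred replicates) completes in seconds while keeping per-test event
counts (one-parent offspring, mate pairs, chance Gtrios) large enough for
3-SE Monte-Carlo comparisons. Published-table reconstructions use the exact
printed counts. Other numerical conventions: allele labels are opaque
integers with no size binning; genotypes are stored allele-sorted so
comparisons are order-insensitive; duplicate-genotyping discordance counts
the minimum mismatches over allele pairings; seeds are mandatory for every
stochastic stage and all simulator randomness flows through a single
`withr::with_seed` scope, making runs byte-identical.

## Known limitations

* Exclusion is not likelihood: absolute percentages from the H1–H3
  harnesses are labeled as exclusion-based and will differ from
  Bayesian-assignment percentages on the same inputs.
* The strict sex search inherits the stringency of the original criterion
  (complete data, all-locus match) and therefore undercounts mis-sexed
  adults, as the original analysis also acknowledged.
* The analytic false-Gtrio expectation is a reconstruction validated
  against the internal Monte-Carlo oracle only.
* Mate pairs serve as grandparent pairs only in their observed mating
  year; pairs that also mated unobserved in other years are missed.
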