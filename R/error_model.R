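#' Genotyping error rate from re-genotyped individuals
#'
#' Standard blind-duplicate estimate: a subset of individuals is genotyped
#' twice and the rate is the number of discordant alleles divided by the
#' total number of alleles scored in both copies. Per locus the discordance
#' between genotypes \{a,b\} and \{c,d\} is the minimum number of mismatched
#' alleles over the two possible pairings (electropherogram order carries no
#' information), i.e. `2 - |multiset intersection|`. Loci missing in either
#' copy contribute to neither numerator nor denominator.
#'
#' @param original,regenotyped Two `geno_panel`s sharing loci; regenotyped
#'   ids must be a subset of the original ids.
#' @return List with `discordant_alleles`, `total_alleles`, `rate` and a
#'   `per_locus` tibble.
#' @export
estimate_error_rate <- function(original, regenotyped) {
  if (!identical(original$loci$locus, regenotyped$loci$locus)) {
    stop("panels must share the same loci")
  }
  ids <- intersect(regenotyped$ind$id, original$ind$id)
  if (!length(ids)) stop("no overlapping individual ids between panels")
  i1 <- match(ids, original$ind$id)
  i2 <- match(ids, regenotyped$ind$id)
  L <- nrow(original$loci)
  disc <- integer(L); tot <- integer(L)
  for (j in seq_len(L)) {
    ok <- !is.na(original$a1[i1, j]) & !is.na(regenotyped$a1[i2, j])
    if (!any(ok)) next
    x1 <- original$a1[i1, j][ok]; x2 <- original$a2[i1, j][ok]
    y1 <- regenotyped$a1[i2, j][ok]; y2 <- regenotyped$a2[i2, j][ok]
    # alleles stored sorted; multiset intersection of {x1,x2} and {y1,y2}
    shared <- ifelse(x1 == y1 & x2 == y2, 2L,
              ifelse(x1 == y1 | x1 == y2 | x2 == y1 | x2 == y2, 1L, 0L))
    # {a,a} vs {a,b}: sorted equality above marks 1 shared, correct
    disc[j] <- sum(2L - shared)
    tot[j] <- 2L * sum(ok)
  }
  list(discordant_alleles = sum(disc), total_alleles = sum(tot),
       rate = if (sum(tot)) sum(disc) / sum(tot) else NA_real_,
       per_locus = tibble::tibble(locus = original$loci$locus,
                                  discordant = disc, total = tot))
}

#' Inject genotyping error into a panel
#'
#' Each allele copy is independently replaced, with probability `rate`, by a
#' draw from the locus allele-frequency table. A replacement may coincide
#' with the original allele, so the realized discordance rate is
#' `rate * (1 - p_same)` where `p_same` is the frequency-weighted chance of
#' redrawing the same allele.
#'
#' @param panel A `geno_panel`; returned unmodified when `rate = 0`.
#' @param rate Per-allele replacement probability in \[0, 1\].
#' @param freqs An [allele_frequencies()] table covering all panel loci.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A new `geno_panel` with errors applied; missing loci stay missing.
#' @export
apply_genotyping_error <- function(panel, rate, freqs, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  run <- function() {
    if (rate == 0) return(panel)
    a1 <- panel$a1; a2 <- panel$a2
    redraw <- function(col, alleles, f) {
      hit <- !is.na(col) & stats::runif(length(col)) < rate
      if (any(hit)) {
        col[hit] <- sample_vec(alleles, sum(hit), replace = TRUE, prob = f)
      }
      col
    }
    for (j in seq_len(nrow(panel$loci))) {
      loc <- panel$loci$locus[j]
      f <- freqs[[loc]]
      if (is.null(f)) stop("locus '", loc, "' absent from frequency table")
      alleles <- as.integer(names(f))
      a1[, j] <- redraw(a1[, j], alleles, f)
      a2[, j] <- redraw(a2[, j], alleles, f)
    }
    geno_panel(panel$ind, a1, a2, panel$loci)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
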