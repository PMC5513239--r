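# exhaustive enumeration of the one-unassigned-parent probability for the
# 2-locus, 2-allele toy pedigree (1 mother, 1 father, budget 0): enumerate
# parental genotypes, transmission and every per-allele error event, where
# an observed allele flips with probability e/2 (redraw from {1/2, 1/2})
enumerate_toy_probability <- function(e) {
  q <- e / 2
  # per-locus probabilities: marginal parent-offspring compatibility and
  # their joint (pair compatibility never feeds the one-unassigned class:
  # two surviving candidates either pair up -> both, or tie -> none)
  cells <- c(mOK = 0, fOK = 0, both_marg = 0)
  alleles <- c(1L, 2L)
  flip <- function(a, bit) if (bit) 3L - a else a
  for (gm1 in alleles) for (gm2 in alleles) {
    for (gf1 in alleles) for (gf2 in alleles) {
      gm <- c(gm1, gm2); gf <- c(gf1, gf2)
      for (tm in 1:2) for (tf in 1:2) {
        true_copies <- c(gm, gf, gm[tm], gf[tf])
        for (mask in 0:63) {
          bits <- bitwAnd(bitwShiftR(mask, 0:5), 1L) == 1L
          pr <- (1 / 16) * (1 / 4) * prod(ifelse(bits, q, 1 - q))
          obs <- mapply(flip, true_copies, bits)
          mo <- obs[1:2]; fo <- obs[3:4]; oo <- obs[5:6]
          m_ok <- any(oo %in% mo); f_ok <- any(oo %in% fo)
          cells["mOK"] <- cells["mOK"] + pr * m_ok
          cells["fOK"] <- cells["fOK"] + pr * f_ok
          if (m_ok && f_ok) cells["both_marg"] <- cells["both_marg"] + pr
        }
      }
    }
  }
  pm <- cells[["mOK"]]; pf <- cells[["fOK"]]
  pmf <- cells[["both_marg"]]
  # two iid loci, budget 0: candidate on a side needs OK at both loci;
  # one-unassigned-parent = exactly one side remains a candidate
  pm^2 + pf^2 - 2 * pmf^2
}

# full-enumeration two-sided rank-sum p-value, written independently of the
# package implementation (works with ties via mid-ranks)
brute_rank_sum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  rk <- rank(c(x, y))
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  sets <- utils::combn(n, n1)
  u_all <- apply(sets, 2, function(ix) sum(rk[ix])) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
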