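# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: plain lm() fits, double loops and closed forms.

# Single-marker regression oracle: LOD, additive effect and PVE from an
# lm() fit of trait on the +1/-1 genotype score.
oracleMarkerFit <- function(y, alleleVec) {
  x <- ifelse(alleleVec == "B", 1, -1)
  fit1 <- lm(y ~ x)
  fit0 <- lm(y ~ 1)
  rss1 <- sum(resid(fit1)^2)
  rss0 <- sum(resid(fit0)^2)
  list(lod = (length(y) / 2) * log10(rss0 / rss1),
       a = unname(coef(fit1)["x"]),
       pve = 1 - rss1 / rss0)
}

# Brute-force mutual ranks: explicit double loop over ordered pairs.
oracleMutualRanks <- function(compendium) {
  ids <- rownames(compendium)
  n <- length(ids)
  cc <- cor(t(compendium))
  rankAB <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    ord <- order(-cc[i, -i])                    # ties: first in id order
    partners <- ids[-i][ord]
    rankAB[i, partners] <- seq_len(n - 1)
  }
  out <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j) out[i, j] <- sqrt(rankAB[i, j] * rankAB[j, i])
  out
}

# Two-locus selfed-RIL conditional probability by explicit enumeration of
# the transition products over the hidden genotype x.
oracleGenoprob <- function(gL, gR, dL, dR) {
  trans <- function(g1, g2, d) {
    r <- 0.5 * (1 - exp(-2 * d / 100))
    R <- 2 * r / (1 + 2 * r)
    if (g1 == g2) 1 - R else R
  }
  num <- trans(gL, "B", dL) * trans("B", gR, dR)
  den <- num + trans(gL, "S", dL) * trans("S", gR, dR)
  num / den
}

# Default small map used by several scan tests: 5 chromosomes, 24 markers,
# 100 cM each.
smallMap <- function() makeMap(5, 24, 100)

# Line-level trait directly at the index scale: genotype score at a marker
# times effect plus N(0, sd) noise.  Bypasses the plant-level machinery for
# scan-only experiments.
lineTrait <- function(geno, markerId, effect, sd, seed) {
  set.seed(seed)
  g <- ifelse(alleles(geno)[, markerId] == "B", 1, -1)
  setNames(g * effect + rnorm(length(g), 0, sd), rownames(alleles(geno)))
}
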