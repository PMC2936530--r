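#' Haldane map function and selfed-RIL transition probability
#'
#' \code{haldaneR} converts a map distance in cM to a single-meiosis
#' recombination fraction assuming no interference,
#' r = (1 - exp(-2 d / 100)) / 2.  \code{rilTransition} expands it to the
#' probability that two linked markers carry different parental genotypes in
#' a recombinant inbred line derived by repeated selfing,
#' R = 2 r / (1 + 2 r).
#'
#' @param d map distance in centiMorgan (vectorized).
#' @return numeric vector of probabilities in [0, 0.5].
#' @examples
#' haldaneR(10)       # ~0.0906
#' rilTransition(10)  # ~0.1534
#' @export
haldaneR <- function(d) {
  stopifnot(all(d >= 0))
  0.5 * (1 - exp(-2 * d / 100))
}

#' @rdname haldaneR
#' @export
rilTransition <- function(d) {
  r <- haldaneR(d)
  2 * r / (1 + 2 * r)
}

#' Anchor genetic positions to physical coordinates
#'
#' Linear interpolation between marker anchors of a \linkS4class{GeneticMap},
#' clamped to the chromosome's first/last marker outside the mapped range.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param chromosome integer chromosome.
#' @param cM numeric positions to convert.
#' @return numeric bp positions (rounded to integer values).
#' @export
cMToBp <- function(map, chromosome, cM) {
  m <- markers(map)
  sub <- m[m$chromosome == chromosome, ]
  if (nrow(sub) == 0) stop("chromosome ", chromosome, " not on the map")
  round(approx(sub$position_cM, sub$position_bp, xout = cM, rule = 2)$y)
}

#' @rdname cMToBp
#' @param bp numeric bp positions to convert back to cM.
#' @export
bpToCM <- function(map, chromosome, bp) {
  m <- markers(map)
  sub <- m[m$chromosome == chromosome, ]
  if (nrow(sub) == 0) stop("chromosome ", chromosome, " not on the map")
  approx(sub$position_bp, sub$position_cM, xout = bp, rule = 2)$y
}

# Nearest-rank empirical quantile: k-th smallest with k = ceiling(q * n),
# clamped to [1, n] so q = 0 returns the minimum (boundary convention used
# for permutation thresholds).
nearestRankQuantile <- function(x, q) {
  x <- sort(x)
  k <- min(max(ceiling(q * length(x)), 1L), length(x))
  x[k]
}

# Derive a reproducible sub-seed from a root seed and a stage label.
# Cheap string hash kept below 2^31 so it is a valid R integer seed.
deriveSeed <- function(seed, stage) {
  h <- as.integer(seed) %% 2147483647L
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647L
  as.integer(h)
}

# Nearest marker (row index into markers(map)) to a chromosome/cM position.
nearestMarker <- function(map, chromosome, position_cM) {
  m <- markers(map)
  idx <- which(m$chromosome == chromosome)
  if (!length(idx)) stop("chromosome ", chromosome, " not on the map")
  idx[which.min(abs(m$position_cM[idx] - position_cM))]
}
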