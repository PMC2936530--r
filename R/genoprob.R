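#' Conditional genotype probabilities on a pseudomarker grid
#'
#' Computes, for every line and every evaluation position (typed markers
#' plus a regular cM grid), the probability of carrying the B parental
#' genotype given the nearest non-missing flanking markers.  With flanking
#' genotypes gL, gR at selfed-RIL transition probabilities R_L, R_R to the
#' evaluation point (Haldane distances, no interference), the line's chain
#' of genotypes along a chromosome is Markov and
#' P(B | gL, gR) = t(gL,B) t(B,gR) / sum_x t(gL,x) t(x,gR) with
#' t(same) = 1 - R, t(diff) = R.  Positions with only one informative flank
#' condition on that flank alone; a line with no typed marker on a
#' chromosome is an error.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param stepCM pseudomarker step in cM (> 0), or \code{NULL} to evaluate
#'   at typed markers only.
#' @return a \linkS4class{GenotypeProbabilities}.
#' @examples
#' map <- makeMap(1, 11, 100)
#' g <- simulateRILGenotypes(map, 20, seed = 3)
#' gp <- calcGenoprob(g, stepCM = 2)
#' @export
calcGenoprob <- function(geno, stepCM = 1) {
  if (!is.null(stepCM) && stepCM <= 0) stop("stepCM must be positive")
  map <- geno@map
  mk <- markers(map)
  a <- alleles(geno)
  nl <- nrow(a)

  posList <- lapply(unique(mk$chromosome), function(chr) {
    sub <- mk[mk$chromosome == chr, ]
    grid <- sub$position_cM
    if (!is.null(stepCM))
      grid <- sort(unique(c(grid, seq(min(grid), max(grid), by = stepCM))))
    at <- sub$marker_id[match(grid, sub$position_cM)]
    data.frame(chromosome = chr, position_cM = grid, at_marker = at,
               stringsAsFactors = FALSE)
  })
  positions <- do.call(rbind, posList)
  prob <- matrix(NA_real_, nl, nrow(positions),
                 dimnames = list(rownames(a), NULL))

  for (chr in unique(mk$chromosome)) {
    midx <- which(mk$chromosome == chr)
    mpos <- mk$position_cM[midx]
    pidx <- which(positions$chromosome == chr)
    ppos <- positions$position_cM[pidx]
    G <- a[, midx, drop = FALSE]
    allMissing <- rowSums(!is.na(G)) == 0
    if (any(allMissing))
      stop("line(s) with no typed marker on chromosome ", chr, ": ",
           paste(rownames(a)[allMissing], collapse = ", "))
    anyMissing <- anyNA(G)
    if (!anyMissing) {
      # fast path: all lines share the same flanking markers
      iL <- findInterval(ppos, mpos)
      iR <- pmin(iL + 1L, length(mpos))
      atM <- ppos %in% mpos
      ii <- match(ppos[atM], mpos)
      iL[atM] <- ii
      iR[atM] <- ii
      RL <- rilTransition(ppos - mpos[iL])
      RR <- rilTransition(mpos[iR] - ppos)
      gl <- G[, iL, drop = FALSE] == "B"
      gr <- G[, iR, drop = FALSE] == "B"
      tl <- sweep(gl, 2, RL, function(b, R) ifelse(b, 1 - R, R))
      tr <- sweep(gr, 2, RR, function(b, R) ifelse(b, 1 - R, R))
      prob[, pidx] <- tl * tr / (tl * tr + (1 - tl) * (1 - tr))
    } else {
      for (l in seq_len(nl)) {
        typed <- which(!is.na(G[l, ]))
        tpos <- mpos[typed]
        gB <- G[l, typed] == "B"
        iL <- findInterval(ppos, tpos)
        iR <- pmin(iL + 1L, length(tpos))
        atT <- ppos %in% tpos
        ii <- match(ppos[atT], tpos)
        iL[atT] <- ii
        iR[atT] <- ii
        leftOK <- iL >= 1
        iLc <- pmax(iL, 1L)
        RL <- rilTransition(abs(ppos - tpos[iLc]))
        RR <- rilTransition(abs(tpos[iR] - ppos))
        tl <- ifelse(gB[iLc], 1 - RL, RL)
        tr <- ifelse(gB[iR], 1 - RR, RR)
        tl[!leftOK] <- 0.5                      # no left flank: prior only
        p <- tl * tr / (tl * tr + (1 - tl) * (1 - tr))
        prob[l, pidx] <- p
      }
    }
  }
  new("GenotypeProbabilities", prob = prob, positions = positions, map = map)
}
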