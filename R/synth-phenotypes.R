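#' Specify planted QTL for phenotype simulation
#'
#' A QTL is an additive effect attached to the marker nearest the requested
#' genome position, with possibly different effects in the two light
#' environments.  A genotype-by-environment (G×E) QTL has
#' \code{effectSun != effectShade}; a constitutive QTL has equal effects.
#' Effects follow the usual additive-parameterization: a line carrying the B
#' allele deviates by +effect, an S line by -effect, so the additive effect
#' a (half the difference between the homozygous class means) equals the
#' planted effect.
#'
#' @param chromosome,positionCM genome position of the QTL.
#' @param effectSun,effectShade additive effects (trait units) in the sun
#'   and shade environments.
#' @return one-row data.frame; rbind several to plant multiple QTL.
#' @export
qtlSpec <- function(chromosome, positionCM, effectSun, effectShade) {
  data.frame(chromosome = chromosome, position_cM = positionCM,
             effect_sun = effectSun, effect_shade = effectShade)
}

#' Simulate a plant-level phenotype table under a G×E QTL model
#'
#' Generates \code{reps} plants per line in each of the two treatments.  A
#' plant's value is the treatment mean, plus the sum over planted QTL of
#' +effect (B allele at the nearest marker) or -effect (S allele), plus
#' additive nuisance-factor level effects (chamber, flat, ... assigned to
#' plants at random), plus N(0, noiseSD^2) measurement noise.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param qtlSpecs data.frame as built by \code{\link{qtlSpec}} (possibly
#'   zero rows for a null simulation).
#' @param nuisance named list of numeric vectors; each element is one
#'   nuisance factor, the vector holding its level effects (plants are
#'   assigned levels uniformly at random).  Empty list for none.
#' @param noiseSD plant-level noise standard deviation (>= 0).
#' @param lineSD standard deviation of a line-level random effect shared by
#'   both treatments (polygenic background; default 0).
#' @param gxeSD standard deviation of a line-by-treatment random deviation
#'   added to shade-grown plants (unmodeled plasticity variance; default 0).
#' @param reps plants per line x treatment.
#' @param treatmentMeans named numeric, baseline for \code{sun} and
#'   \code{shade}.
#' @param trait trait name recorded in the table.
#' @param seed integer seed.
#' @return long data.frame: \code{plant_id}, \code{line_id},
#'   \code{treatment}, one column per nuisance factor, \code{trait},
#'   \code{value}.
#' @examples
#' map <- makeMap(2, 10, 100)
#' g <- simulateRILGenotypes(map, 50, seed = 1)
#' ph <- simulatePhenotypes(g, qtlSpec(1, 50, 0, -1), noiseSD = 1, reps = 4,
#'                          seed = 1)
#' @export
simulatePhenotypes <- function(geno, qtlSpecs = qtlSpec(1, 0, 0, 0)[0, ],
                               nuisance = list(), noiseSD = 1, lineSD = 0,
                               gxeSD = 0, reps = 4,
                               treatmentMeans = c(sun = 0, shade = 0),
                               trait = "trait", seed = 1L) {
  if (noiseSD < 0) stop("noiseSD must be non-negative")
  if (lineSD < 0 || gxeSD < 0) stop("variance components must be non-negative")
  if (reps < 1) stop("need at least one replicate per line x treatment")
  map <- geno@map
  a <- alleles(geno)
  lines <- rownames(a)
  nl <- length(lines)

  # genetic value per line per treatment
  gsun <- gshade <- numeric(nl)
  if (nrow(qtlSpecs)) {
    for (q in seq_len(nrow(qtlSpecs))) {
      mi <- nearestMarker(map, qtlSpecs$chromosome[q], qtlSpecs$position_cM[q])
      gsc <- ifelse(a[, mi] == "B", 1, -1)
      gsc[is.na(gsc)] <- 0
      gsun <- gsun + gsc * qtlSpecs$effect_sun[q]
      gshade <- gshade + gsc * qtlSpecs$effect_shade[q]
    }
  }

  set.seed(deriveSeed(seed, paste0("phenotypes:", trait)))
  tab <- expand.grid(rep = seq_len(reps), line_id = lines,
                     treatment = c("sun", "shade"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(tab)
  li <- match(tab$line_id, lines)
  genetic <- ifelse(tab$treatment == "sun", gsun[li], gshade[li])
  lineEff <- rnorm(nl, 0, lineSD)
  gxeEff <- rnorm(nl, 0, gxeSD)
  value <- treatmentMeans[tab$treatment] + genetic + lineEff[li] +
    ifelse(tab$treatment == "shade", gxeEff[li], 0)
  for (f in names(nuisance)) {
    eff <- nuisance[[f]]
    lev <- sample(seq_along(eff), n, replace = TRUE)
    tab[[f]] <- paste0(f, lev)
    value <- value + eff[lev]
  }
  value <- value + rnorm(n, 0, noiseSD)
  out <- data.frame(plant_id = sprintf("p%05d", seq_len(n)),
                    line_id = tab$line_id, treatment = tab$treatment,
                    stringsAsFactors = FALSE)
  for (f in names(nuisance)) out[[f]] <- tab[[f]]
  out$trait <- trait
  out$value <- unname(value)
  out
}
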