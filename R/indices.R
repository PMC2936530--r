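#' Per-line condition indices with nuisance-factor adjustment
#'
#' Collapses plant-level phenotypes to one index per line and treatment
#' using a two-stage mean adjustment: (1) for each nuisance factor, in the
#' given order, a one-way F-test is run on the residuals from the current
#' line-by-treatment means; when significant (p < \code{screenAlpha}) the
#' factor's residual level means are subtracted from the data; (2) the index
#' is the mean of the adjusted values per line and treatment.  This is the
#' balanced-design analogue of fitting the nuisance terms as random effects
#' "when significant".
#'
#' @param pheno long phenotype data.frame as produced by
#'   \code{\link{simulatePhenotypes}} (columns \code{line_id},
#'   \code{treatment}, \code{value}, plus nuisance columns).
#' @param nuisanceFactors character vector of nuisance column names to
#'   screen, in adjustment order.
#' @param screenAlpha significance level of the one-way F screen.
#' @return data.frame: \code{line_id}, \code{sun}, \code{shade}.
#' @export
computeConditionIndices <- function(pheno, nuisanceFactors = character(),
                                    screenAlpha = 0.05) {
  stopifnot(all(c("line_id", "treatment", "value") %in% names(pheno)))
  tt <- table(pheno$line_id, pheno$treatment)
  if (!all(c("sun", "shade") %in% colnames(tt)))
    stop("phenotypes must contain both 'sun' and 'shade' treatments")
  bad <- rownames(tt)[tt[, "sun"] == 0 | tt[, "shade"] == 0]
  if (length(bad))
    stop("line(s) missing one treatment: ", paste(bad, collapse = ", "))

  y <- pheno$value
  cell <- interaction(pheno$line_id, pheno$treatment, drop = TRUE)
  for (f in nuisanceFactors) {
    if (!f %in% names(pheno)) stop("unknown nuisance factor: ", f)
    fac <- factor(pheno[[f]])
    # a factor whose levels partition the plants exactly like treatment
    # cannot be separated from it
    cross <- table(fac, pheno$treatment)
    if (nlevels(fac) == length(unique(pheno$treatment)) &&
        all(rowSums(cross > 0) == 1))
      stop("nuisance factor '", f, "' is confounded with treatment")
    res <- y - ave(y, cell)
    if (nlevels(fac) < 2) next
    p <- anova(lm(res ~ fac))[["Pr(>F)"]][1]
    if (!is.na(p) && p < screenAlpha)
      y <- y - ave(res, fac)
  }
  agg <- tapply(y, list(pheno$line_id, pheno$treatment), mean)
  data.frame(line_id = rownames(agg), sun = agg[, "sun"],
             shade = agg[, "shade"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Shapiro-Wilk normality gate with natural-log transform
#'
#' Tests the index distribution for normality; when rejected at
#' \code{pThreshold} the values are replaced by their natural logarithm (an
#' error is raised if any value is non-positive, no offset is silently
#' added).
#'
#' @param values numeric vector of indices (>= 3 values).
#' @param pThreshold Shapiro-Wilk rejection level (default 0.01).
#' @param trait trait name used in error messages.
#' @return list with \code{values} (possibly log-transformed) and
#'   \code{transformed} (logical flag).
#' @export
normalityGate <- function(values, pThreshold = 0.01, trait = "trait") {
  if (length(values) < 3) stop("need at least 3 values for the normality gate")
  p <- shapiro.test(values)$p.value
  if (p >= pThreshold) return(list(values = values, transformed = FALSE))
  if (any(values <= 0))
    stop("trait '", trait, "' fails normality (Shapiro-Wilk p = ",
         signif(p, 3), ") but has non-positive values; cannot log-transform")
  list(values = log(values), transformed = TRUE)
}

#' Subtraction shade-avoidance index
#'
#' sun index minus shade index, per line; for a trait accelerated by shade
#' (e.g. flowering time) larger values mean a stronger shade-avoidance
#' response.
#'
#' @param sun,shade aligned numeric vectors (same lines, same order; names
#'   are checked when present).
#' @return numeric vector sun - shade.
#' @export
subtractionIndex <- function(sun, shade) {
  if (length(sun) != length(shade))
    stop("sun and shade index vectors differ in length")
  if (!is.null(names(sun)) && !is.null(names(shade)) &&
      !identical(names(sun), names(shade)))
    stop("sun and shade indices are not aligned on the same lines")
  sun - shade
}

#' Residual shade-avoidance index
#'
#' Ordinary least-squares regression of the shade index on the sun index;
#' the index is the negated residual, so lines whose shade value is lower
#' than predicted from their sun value (stronger response) score high.  By
#' OLS orthogonality the index has mean zero and zero sample correlation
#' with the sun index.
#'
#' @inheritParams subtractionIndex
#' @return numeric vector of negated residuals.
#' @export
residualIndex <- function(sun, shade) {
  if (length(sun) != length(shade))
    stop("sun and shade index vectors differ in length")
  if (length(sun) < 3) stop("need at least 3 lines")
  if (var(sun) == 0) stop("sun index is constant; regression slope undefined")
  fit <- lm(shade ~ sun)
  unname(-resid(fit))
}

#' Full trait-index table for one trait
#'
#' Runs \code{\link{computeConditionIndices}}, optionally the
#' \code{\link{normalityGate}} on the pooled sun/shade line indices, then
#' both shade-avoidance response indices.
#'
#' @inheritParams computeConditionIndices
#' @param applyGate apply the Shapiro-Wilk/log gate to the line indices
#'   (the gate may alternatively be applied to plant-level data by gating
#'   \code{pheno$value} before calling; line-index gating is the default).
#' @param pThreshold normality-gate rejection level.
#' @return data.frame: \code{line_id}, \code{trait}, \code{sun},
#'   \code{shade}, \code{subtraction}, \code{residual}, \code{transformed}.
#' @export
computeTraitIndices <- function(pheno, nuisanceFactors = character(),
                                screenAlpha = 0.05, applyGate = TRUE,
                                pThreshold = 0.01) {
  trait <- if ("trait" %in% names(pheno)) pheno$trait[1] else "trait"
  idx <- computeConditionIndices(pheno, nuisanceFactors, screenAlpha)
  transformed <- FALSE
  if (applyGate) {
    # the distributional shape is judged after removing the condition
    # means, so a sun/shade location shift is not mistaken for
    # non-normality; the log transform itself acts on the raw indices
    centered <- c(idx$sun - mean(idx$sun), idx$shade - mean(idx$shade))
    if (shapiro.test(centered)$p.value < pThreshold) {
      if (any(c(idx$sun, idx$shade) <= 0))
        stop("trait '", trait, "' fails normality but has non-positive ",
             "index values; cannot log-transform")
      idx$sun <- log(idx$sun)
      idx$shade <- log(idx$shade)
      transformed <- TRUE
    }
  }
  data.frame(line_id = idx$line_id, trait = trait, sun = idx$sun,
             shade = idx$shade,
             subtraction = subtractionIndex(idx$sun, idx$shade),
             residual = residualIndex(idx$sun, idx$shade),
             transformed = transformed, stringsAsFactors = FALSE)
}
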