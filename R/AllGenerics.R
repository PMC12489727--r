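#' Neutral molecular formula of a structure descriptor
#'
#' Derives the [ElementalFormula-class] of an [AcylQuinate-class] or
#' [FlavonoidGlycoside-class]: core/aglycone plus sugar plus the parent acids
#' of all acyl groups, minus one H2O per ester or glycosidic bond formed.
#' Regiochemistry never changes the formula, so all regioisomers of the same
#' composition share one formula (and hence one precursor m/z).
#'
#' @param object An \code{AcylQuinate} or \code{FlavonoidGlycoside}.
#' @return An \code{ElementalFormula}.
#' @examples
#' neutralFormula(acylQuinate(c("1" = "caf", "3" = "mal", "5" = "caf")))
#' @export
setGeneric("neutralFormula", function(object) standardGeneric("neutralFormula"))

#' Count catechol (ortho-dihydroxybenzene) units in a structure
#'
#' Each caffeoyl group carries one catechol; quercetin and luteolin carry one
#' catechol on the flavonoid B ring, kaempferol none. The catechol count
#' bounds the number of in-source oxidation states (-2H per catechol) and
#' predicts DPPH radical-scavenging activity.
#'
#' @param object An \code{AcylQuinate} or \code{FlavonoidGlycoside}.
#' @return Non-negative integer.
#' @examples
#' catecholCount(acylQuinate(c("1" = "caf", "3" = "mal", "5" = "caf")))  # 2
#' @export
setGeneric("catecholCount", function(object) standardGeneric("catecholCount"))

#' @rdname peakAccessors
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))

#' @rdname peakAccessors
#' @export
setGeneric("precursorMz", function(object) standardGeneric("precursorMz"))

#' @rdname peakAccessors
#' @export
setGeneric("collisionEnergy", function(object) standardGeneric("collisionEnergy"))

#' @rdname peakAccessors
#' @export
setGeneric("polarity", function(object) standardGeneric("polarity"))

#' @rdname peakAccessors
#' @export
setGeneric("totalIonCurrent", function(object) standardGeneric("totalIonCurrent"))
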