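#' @import methods
NULL

#' ElementalFormula: integer element counts
#'
#' Container for a molecular formula as non-negative integer element counts.
#' All mass arithmetic in the package is built on this class. Supported
#' elements are C, H, N, O and S; equality is count-wise and zero counts are
#' dropped on construction.
#'
#' @slot counts Named integer vector, element symbol -> count (all >= 0).
#'
#' @seealso [parseFormula()], [monoisotopicMass()], [mzIon()]
#' @export
setClass("ElementalFormula",
    representation(counts = "integer"),
    prototype(counts = setNames(integer(0), character(0))))

setValidity("ElementalFormula", function(object) {
    cnt <- object@counts
    if (length(cnt) && is.null(names(cnt)))
        return("counts must be a named integer vector")
    bad <- setdiff(names(cnt), names(.isotopeMasses))
    if (length(bad))
        return(sprintf("unknown element symbol(s): %s",
                       paste(bad, collapse = ", ")))
    if (any(cnt < 0))
        return(sprintf("negative count for element(s): %s",
                       paste(names(cnt)[cnt < 0], collapse = ", ")))
    if (anyDuplicated(names(cnt)))
        return("duplicated element symbols")
    TRUE
})

#' AcylQuinate: an acylated quinic (or epi-quinic) acid
#'
#' Structure descriptor for a 1,3,4,5-tetrahydroxycyclohexanecarboxylic acid
#' core carrying caffeoyl and/or malonyl ester groups on a subset of the four
#' hydroxyl positions. Stereochemistry of the core is a label only
#' (\code{"quinic"} or \code{"epi-quinic"}); the mass and fragment chemistry
#' of the two cores are identical, and they are separated in practice by NMR
#' coupling constants (see [assignCore()]).
#'
#' @slot core Either \code{"quinic"} or \code{"epi-quinic"}.
#' @slot substituents Named character vector mapping position
#'   (\code{"1","3","4","5"}) to acyl label (\code{"caf"} caffeoyl,
#'   \code{"mal"} malonyl). Unlisted positions are free hydroxyls.
#'
#' @seealso [acylQuinate()], [enumerateRegioisomers()], [neutralFormula()]
#' @export
setClass("AcylQuinate",
    representation(core = "character", substituents = "character"))

setValidity("AcylQuinate", function(object) {
    if (!object@core %in% c("quinic", "epi-quinic"))
        return("core must be 'quinic' or 'epi-quinic'")
    sub <- object@substituents
    if (length(sub)) {
        if (!all(names(sub) %in% c("1", "3", "4", "5")))
            return("substituent positions must be within {1,3,4,5}")
        if (anyDuplicated(names(sub)))
            return("at most one acyl group per position")
        if (!all(sub %in% c("caf", "mal")))
            return("acyl labels must be 'caf' or 'mal'")
    }
    TRUE
})

#' FlavonoidGlycoside: flavonoid O-glucoside with malonyl esters
#'
#' Descriptor for a flavonoid aglycone bearing one beta-glucosyl unit and
#' zero to two malonyl esters on the sugar (positions 2'' and/or 6'').
#' The glycosidic bond and each malonyl ester each remove one H2O from the
#' combined formula. The anomeric configuration is metadata (always modelled
#' as beta); it does not affect the formula.
#'
#' @slot aglycone One of \code{"quercetin"}, \code{"luteolin"},
#'   \code{"kaempferol"}.
#' @slot glycosylationPosition Aglycone position of the glucosyl unit
#'   (3 or 7).
#' @slot malonylPositions Character subset of \code{c("2''", "6''")}.
#'
#' @seealso [flavonoidGlycoside()], [neutralFormula()], [catecholCount()]
#' @export
setClass("FlavonoidGlycoside",
    representation(aglycone = "character",
                   glycosylationPosition = "integer",
                   malonylPositions = "character"))

setValidity("FlavonoidGlycoside", function(object) {
    if (!object@aglycone %in% c("quercetin", "luteolin", "kaempferol"))
        return("aglycone must be quercetin, luteolin or kaempferol")
    if (!object@glycosylationPosition %in% c(3L, 7L))
        return("glycosylation position must be 3 or 7")
    mp <- object@malonylPositions
    if (length(mp) > 2 || !all(mp %in% c("2''", "6''")) || anyDuplicated(mp))
        return("malonyl positions must be a subset of {2'', 6''}")
    TRUE
})

#' MassSpectrum: a single MS or MS/MS peak list
#'
#' @slot polarity \code{"negative"} or \code{"positive"}.
#' @slot precursorMz Precursor m/z (NA for MS1 scans).
#' @slot collisionEnergy Collision energy in eV (NA for MS1 scans).
#' @slot mz Numeric vector of peak m/z values.
#' @slot intensity Numeric vector of peak intensities (>= 0), parallel to
#'   \code{mz}. Intensity units are arbitrary; the isomer key re-normalises
#'   to fractions of total ion current internally.
#' @slot title Scan title (used for pairing spectra across energies).
#'
#' @seealso [massSpectrum()], [readMGF()], [classifyIsomer()]
#' @export
setClass("MassSpectrum",
    representation(polarity = "character", precursorMz = "numeric",
                   collisionEnergy = "numeric", mz = "numeric",
                   intensity = "numeric", title = "character"))

setValidity("MassSpectrum", function(object) {
    if (!object@polarity %in% c("negative", "positive"))
        return("polarity must be 'negative' or 'positive'")
    if (length(object@mz) != length(object@intensity))
        return("mz and intensity must have equal length")
    if (length(object@intensity) && any(object@intensity < 0))
        return("intensities must be >= 0")
    if (length(object@mz) && any(object@mz <= 0))
        return("m/z values must be > 0")
    TRUE
})

#' OxidationSeries: an in-source catechol-oxidation ion series
#'
#' Result container for [detectOxidationSeries()]. Members are the intact
#' species (state 0) and its -2H / -4H satellites; each in-source oxidation
#' of a catechol removes two hydrogen atoms (2.01565 Da, exact 2 x H), so at
#' most \code{nCatechol} oxidation states beyond the base are possible.
#'
#' @slot baseMz m/z of the intact (de)protonated species.
#' @slot states Integer vector of oxidation states present (0 = intact,
#'   1 = -2H, 2 = -4H).
#' @slot memberMz Observed m/z per state.
#' @slot memberIntensity Observed intensity per state.
#' @slot nCatechol Number of catechol units in the assigned structure.
#' @slot anomaly Character vector of anomaly flags (e.g. a satellite beyond
#'   what the catechol count allows).
#' @export
setClass("OxidationSeries",
    representation(baseMz = "numeric", states = "integer",
                   memberMz = "numeric", memberIntensity = "numeric",
                   nCatechol = "integer", anomaly = "character"))

setValidity("OxidationSeries", function(object) {
    n <- length(object@states)
    if (length(object@memberMz) != n || length(object@memberIntensity) != n)
        return("states, memberMz and memberIntensity must be parallel")
    if (n && any(object@states < 0))
        return("oxidation states must be >= 0")
    TRUE
})

#' IsomerCall: output of the two-stage MDiCQA decision key
#'
#' @slot label One of \code{"cpd4"}, \code{"cpd5"}, \code{"cpd6"},
#'   \code{"cpd7"}, \code{"group_4_or_7"}, \code{"inconclusive"}.
#' @slot stage1I233,stage1I395 Fractions of total ion current of the nominal
#'   m/z 233 and 395 key ions in the 25 eV spectrum.
#' @slot stage2Ratio I173/I233 at 45 eV, or NA when stage 2 was not run.
#' @slot confidence \code{"high"} or \code{"low"}.
#' @export
setClass("IsomerCall",
    representation(label = "character", stage1I233 = "numeric",
                   stage1I395 = "numeric", stage2Ratio = "numeric",
                   confidence = "character"))

setValidity("IsomerCall", function(object) {
    ok <- c("cpd4", "cpd5", "cpd6", "cpd7", "group_4_or_7", "inconclusive")
    if (!object@label %in% ok)
        return("invalid isomer label")
    if (object@label %in% c("cpd4", "cpd7") && is.na(object@stage2Ratio))
        return("cpd4/cpd7 calls require a stage-2 ratio")
    if (!is.na(object@stage2Ratio) && object@stage2Ratio < 0)
        return("stage-2 ratio must be >= 0")
    TRUE
})

#' IC50Fit: result of a four-parameter logistic dose-response fit
#'
#' @slot ic50 Half-maximal concentration (same units as the doses, uM by
#'   convention).
#' @slot hill Hill slope.
#' @slot bottom,top Lower and upper response asymptotes (percent).
#' @slot seIC50 Standard error of the IC50 (delta method from the log-IC50
#'   parameterisation).
#' @slot seLogIC50 Standard error of log(IC50).
#' @slot status \code{"ok"}, \code{"censored_above_max"} or \code{"failed"}.
#' @slot message Diagnostic message when status is not \code{"ok"}.
#' @export
setClass("IC50Fit",
    representation(ic50 = "numeric", hill = "numeric", bottom = "numeric",
                   top = "numeric", seIC50 = "numeric", seLogIC50 = "numeric",
                   status = "character", message = "character"))

setValidity("IC50Fit", function(object) {
    if (!object@status %in% c("ok", "censored_above_max", "failed"))
        return("invalid fit status")
    if (object@status == "ok") {
        if (!is.finite(object@ic50) || object@ic50 <= 0)
            return("ic50 must be positive when status is 'ok'")
        if (is.finite(object@bottom) && is.finite(object@top) &&
            object@bottom >= object@top)
            return("bottom must be below top")
    }
    TRUE
})
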