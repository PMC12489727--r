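# Two-stage CID decision key for the four MDiCQA regioisomers. All rules
# work on fractions of total ion current (TIC), never on base-peak
# normalisation: the diagnostic percentages are "% of the total intensity".
# Key nominal ions: 233 (quinate - 2 caffeoyl - CO2), 395 (quinate -
# caffeoyl - CO2) at 25 eV; 173 (dehydrated quinic acid) vs 233 at 45 eV.

.keyThresholds <- list(
    trace = 0.05,        # "trace amounts": separates ~1-2% from >=20%
    g47_I233 = 0.5,      # compounds 4/7: m/z 233 ~70% of TIC at 25 eV
    cpd5_I395 = 0.25,    # compound 5: m/z 395 ~35% of TIC at 25 eV
    cpd6_floor = 0.2,    # compound 6: both ions ~30-35%
    cpd6_ratioLo = 0.5,  # "comparably high" encoded as ratio in [0.5, 2]
    cpd6_ratioHi = 2,
    stage2_hi = 0.7,     # I173/I233 >= 0.7 -> cpd7 (printed ratio 1.3)
    stage2_lo = 0.5)     # I173/I233 <= 0.5 -> cpd4 (printed ratio 0.3)

#' TIC fraction of a nominal key ion
#'
#' Sums the intensities of all peaks whose nominal (round-half-up) m/z
#' equals \code{nominal} and divides by the spectrum's total ion current.
#' Nominal binning suffices for the key ions; high-resolution matching is
#' unnecessary at this stage.
#'
#' @param spectrum A [MassSpectrum-class].
#' @param nominal Integer nominal m/z (173, 233 or 395 for the key).
#' @return Fraction of TIC in [0, 1]; 0 for an empty spectrum or an absent
#'   ion.
#' @export
keyIntensity <- function(spectrum, nominal) {
    stopifnot(is(spectrum, "MassSpectrum"))
    tic <- sum(spectrum@intensity)
    if (tic <= 0)
        return(0)
    sel <- nominalMz(spectrum@mz) == as.integer(nominal)
    sum(spectrum@intensity[sel]) / tic
}

.checkEnergy <- function(spectrum, expected) {
    ce <- spectrum@collisionEnergy
    if (is.na(ce) || ce != expected)
        stop("decision-key stage expects a ", expected,
             " eV spectrum, got ", ce, " eV")
}

#' Stage 1 of the MDiCQA key (25 eV)
#'
#' At 25 eV the m/z 233 ion carries ~70% of the TIC for compounds 4 and 7
#' (indistinguishable at this stage), m/z 395 ~35% with 233 in traces for
#' compound 5, and both ions are comparably high (~30%/~35%) for compound
#' 6.
#'
#' @param spec25 Negative-mode 25 eV [MassSpectrum-class].
#' @return Label: \code{"group_4_or_7"}, \code{"cpd5"}, \code{"cpd6"} or
#'   \code{"inconclusive"}, with attributes \code{I233}, \code{I395} and
#'   \code{margin} (smallest relative margin over the fired rule's
#'   thresholds).
#' @export
classifyStage1 <- function(spec25) {
    .checkEnergy(spec25, 25)
    th <- .keyThresholds
    i233 <- keyIntensity(spec25, 233)
    i395 <- keyIntensity(spec25, 395)
    label <- "inconclusive"
    margin <- 0
    if (i233 >= th$g47_I233 && i395 < th$trace) {
        label <- "group_4_or_7"
        margin <- min(i233 / th$g47_I233 - 1, 1 - i395 / th$trace)
    } else if (i395 >= th$cpd5_I395 && i233 < th$trace) {
        label <- "cpd5"
        margin <- min(i395 / th$cpd5_I395 - 1, 1 - i233 / th$trace)
    } else if (i233 >= th$cpd6_floor && i395 >= th$cpd6_floor &&
               i233 / i395 >= th$cpd6_ratioLo &&
               i233 / i395 <= th$cpd6_ratioHi) {
        label <- "cpd6"
        r <- i233 / i395
        margin <- min(i233 / th$cpd6_floor - 1, i395 / th$cpd6_floor - 1,
                      r / th$cpd6_ratioLo - 1, 1 - r / th$cpd6_ratioHi)
    }
    structure(label, I233 = i233, I395 = i395, margin = margin)
}

#' Stage 2 of the MDiCQA key (45 eV)
#'
#' Separates compounds 4 and 7 by the I173/I233 abundance ratio at 45 eV:
#' ~1.3 (40%/30%) for compound 7, ~0.3 (8%/30%) for compound 4. The dead
#' band (0.5, 0.7) between the decision thresholds straddles the geometric
#' midpoint of the printed ratios and avoids overclaiming near the
#' boundary.
#'
#' @param spec45 Negative-mode 45 eV [MassSpectrum-class]; the m/z 233 ion
#'   must be present (it is the diagnostic denominator).
#' @return Label \code{"cpd7"}, \code{"cpd4"} or \code{"inconclusive"} with
#'   attributes \code{ratio} and \code{margin}. Invariant to intensity
#'   units (raw counts or fractions) since only a ratio is used.
#' @export
classifyStage2 <- function(spec45) {
    .checkEnergy(spec45, 45)
    th <- .keyThresholds
    i173 <- keyIntensity(spec45, 173)
    i233 <- keyIntensity(spec45, 233)
    if (i233 <= 0)
        stop("diagnostic denominator absent: no m/z 233 ion at 45 eV")
    r <- i173 / i233
    if (r >= th$stage2_hi) {
        structure("cpd7", ratio = r, margin = r / th$stage2_hi - 1)
    } else if (r <= th$stage2_lo) {
        structure("cpd4", ratio = r, margin = 1 - r / th$stage2_lo)
    } else {
        structure("inconclusive", ratio = r, margin = 0)
    }
}

#' Full two-stage MDiCQA isomer key
#'
#' Runs stage 1 on the 25 eV spectrum; when the result is the unresolved
#' 4/7 group and a 45 eV spectrum is supplied, refines it with the stage-2
#' intensity ratio. Confidence is \code{"high"} only when every rule that
#' fired did so with a margin of at least 20% of its threshold.
#'
#' @param spec25 Negative-mode 25 eV [MassSpectrum-class] (required).
#' @param spec45 Optional negative-mode 45 eV [MassSpectrum-class].
#' @return An [IsomerCall-class].
#' @examples
#' tpl <- spectrumTemplates()
#' s25 <- genMSMS(tpl[["cpd7_25"]], noiseModel(0, 0, 0, seed = 1))
#' s45 <- genMSMS(tpl[["cpd7_45"]], noiseModel(0, 0, 0, seed = 1))
#' classifyIsomer(s25, s45)
#' @export
classifyIsomer <- function(spec25, spec45 = NULL) {
    s1 <- classifyStage1(spec25)
    margins <- attr(s1, "margin")
    label <- as.character(s1)
    ratio <- NA_real_
    if (label == "group_4_or_7" && !is.null(spec45)) {
        s2 <- classifyStage2(spec45)
        ratio <- attr(s2, "ratio")
        if (as.character(s2) != "inconclusive") {
            label <- as.character(s2)
            margins <- c(margins, attr(s2, "margin"))
        }
    }
    conf <- if (label %in% c("inconclusive", "group_4_or_7")) "low"
            else if (all(margins >= 0.2)) "high" else "low"
    new("IsomerCall", label = label,
        stage1I233 = attr(s1, "I233"), stage1I395 = attr(s1, "I395"),
        stage2Ratio = ratio, confidence = conf)
}

#' @export
setMethod("show", "IsomerCall", function(object) {
    cat("IsomerCall:", object@label,
        sprintf("(confidence %s)\n", object@confidence))
    cat(sprintf("  stage 1 (25 eV): I233 = %.3f, I395 = %.3f of TIC\n",
                object@stage1I233, object@stage1I395))
    if (!is.na(object@stage2Ratio))
        cat(sprintf("  stage 2 (45 eV): I173/I233 = %.2f\n",
                    object@stage2Ratio))
})
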