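# In-source oxidation of a catechol strips two hydrogen atoms; the exact
# offset is 2 x 1.0078250 = 2.0156500 Da ("2 Da" only nominally).
.oxidationStep <- 2 * 1.0078250319

#' Detect an in-source catechol-oxidation ion series
#'
#' Searches an MS1 peak list for the intact species at \code{baseMz} and its
#' oxidation satellites at \code{baseMz - k * 2.01565} for
#' \code{k = 1..nCatechol}. Satellites beyond the catechol count are never
#' claimed as oxidation; a peak at the -2H offset of a catechol-free
#' structure raises an anomaly flag instead (it could be an isotope
#' misassignment or an unrelated ion).
#'
#' @param peaks Two-column matrix or data.frame (mz, intensity), or a
#'   [MassSpectrum-class].
#' @param baseMz Expected m/z of the intact (de)protonated species.
#' @param nCatechol Number of catechol units in the assigned structure.
#' @param tolPpm Match tolerance in ppm (default 10).
#' @return An [OxidationSeries-class].
#' @examples
#' pk <- cbind(mz = c(601.1199, 599.1043, 597.0886),
#'             intensity = c(100, 40, 8))
#' detectOxidationSeries(pk, baseMz = 601.1199, nCatechol = 2)
#' @export
detectOxidationSeries <- function(peaks, baseMz, nCatechol, tolPpm = 10) {
    if (is(peaks, "MassSpectrum"))
        peaks <- peaks(peaks)
    peaks <- as.matrix(peaks)
    mz <- peaks[, 1]
    int <- peaks[, 2]
    nCatechol <- as.integer(nCatechol)

    findPeak <- function(target) {
        if (!length(mz))
            return(NULL)
        err <- ppmError(mz, target)
        j <- which.min(abs(err))
        if (abs(err[j]) <= tolPpm) j else NULL
    }

    j0 <- findPeak(baseMz)
    if (is.null(j0))
        stop("no base peak within ", tolPpm, " ppm of m/z ",
             sprintf("%.4f", baseMz),
             " (cannot distinguish 'no series' without the intact species)")

    states <- 0L
    memberMz <- mz[j0]
    memberInt <- int[j0]
    anomaly <- character(0)
    for (k in seq_len(max(nCatechol, 0L))) {
        j <- findPeak(baseMz - k * .oxidationStep)
        if (!is.null(j)) {
            states <- c(states, k)
            memberMz <- c(memberMz, mz[j])
            memberInt <- c(memberInt, int[j])
        }
    }
    # satellites past the catechol budget: flag, never claim
    j <- findPeak(baseMz - (nCatechol + 1L) * .oxidationStep)
    if (!is.null(j))
        anomaly <- sprintf(
            "peak at m/z %.4f sits at oxidation state %d but only %d catechol(s) available",
            mz[j], nCatechol + 1L, nCatechol)

    new("OxidationSeries", baseMz = baseMz, states = states,
        memberMz = memberMz, memberIntensity = memberInt,
        nCatechol = nCatechol, anomaly = anomaly)
}

#' Most intense oxidation state of a series
#'
#' Under acidified eluents the intact deprotonated species dominates; with
#' water-only eluents the equilibrium flips and the doubly oxidized (-4H)
#' ion becomes the base peak. Ties resolve to the lower oxidation state with
#' a tie attribute.
#'
#' @param series An [OxidationSeries-class] with >= 1 member.
#' @return State label: \code{"0"}, \code{"-2H"} or \code{"-4H"}, with
#'   attribute \code{tie = TRUE} when the maximum was tied.
#' @export
dominantState <- function(series) {
    stopifnot(is(series, "OxidationSeries"))
    if (!length(series@states))
        stop("empty oxidation series")
    mx <- max(series@memberIntensity)
    hits <- series@states[series@memberIntensity == mx]
    state <- min(hits)
    lab <- c("0", "-2H", "-4H", "-6H", "-8H")[state + 1L]
    if (length(hits) > 1L)
        attr(lab, "tie") <- TRUE
    lab
}

#' Total intensity of a series attributed to the intact species
#'
#' Sums member intensities so that quantitation is robust to in-source
#' oxidation (the satellites are the same molecule).
#'
#' @param series An [OxidationSeries-class] with >= 1 member.
#' @return Named list with \code{baseMz} and \code{intensity}.
#' @export
mergeSeriesIntensity <- function(series) {
    stopifnot(is(series, "OxidationSeries"))
    if (!length(series@states))
        stop("empty oxidation series")
    list(baseMz = series@baseMz, intensity = sum(series@memberIntensity))
}

#' @export
setMethod("show", "OxidationSeries", function(object) {
    lab <- c("0", "-2H", "-4H", "-6H", "-8H")[object@states + 1L]
    cat(sprintf("OxidationSeries at base m/z %.4f (%d catechols)\n",
                object@baseMz, object@nCatechol))
    for (i in seq_along(object@states))
        cat(sprintf("  %4s  m/z %.4f  intensity %g\n", lab[i],
                    object@memberMz[i], object@memberIntensity[i]))
    if (length(object@anomaly))
        cat("  anomaly:", object@anomaly, "\n")
})
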