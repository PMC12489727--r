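#' Construct a MassSpectrum
#'
#' @param mz,intensity Parallel numeric peak vectors.
#' @param precursorMz Precursor m/z (NA for MS1).
#' @param collisionEnergy Collision energy in eV (NA for MS1).
#' @param polarity \code{"negative"} or \code{"positive"}.
#' @param title Scan title.
#' @return A [MassSpectrum-class]; peaks are sorted by m/z.
#' @export
massSpectrum <- function(mz, intensity, precursorMz = NA_real_,
                         collisionEnergy = NA_real_,
                         polarity = "negative", title = "") {
    o <- order(mz)
    new("MassSpectrum", polarity = polarity,
        precursorMz = as.numeric(precursorMz),
        collisionEnergy = as.numeric(collisionEnergy),
        mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o],
        title = title)
}

#' Peak-level accessors for MassSpectrum
#'
#' @param object A [MassSpectrum-class].
#' @return \code{peaks}: two-column matrix (mz, intensity);
#'   \code{precursorMz}, \code{collisionEnergy}, \code{totalIonCurrent}:
#'   numeric scalars; \code{polarity}: character.
#' @name peakAccessors
NULL

#' @rdname peakAccessors
#' @export
setMethod("peaks", "MassSpectrum", function(object)
    cbind(mz = object@mz, intensity = object@intensity))

#' @rdname peakAccessors
#' @export
setMethod("precursorMz", "MassSpectrum", function(object) object@precursorMz)

#' @rdname peakAccessors
#' @export
setMethod("collisionEnergy", "MassSpectrum",
          function(object) object@collisionEnergy)

#' @rdname peakAccessors
#' @export
setMethod("polarity", "MassSpectrum", function(object) object@polarity)

#' @rdname peakAccessors
#' @export
setMethod("totalIonCurrent", "MassSpectrum",
          function(object) sum(object@intensity))

#' @export
setMethod("show", "MassSpectrum", function(object) {
    cat(sprintf("MassSpectrum (%s): %d peaks", object@polarity,
                length(object@mz)))
    if (!is.na(object@precursorMz))
        cat(sprintf(", precursor %.4f", object@precursorMz))
    if (!is.na(object@collisionEnergy))
        cat(sprintf(", CE %g eV", object@collisionEnergy))
    cat("\n")
    if (nzchar(object@title))
        cat("  title:", object@title, "\n")
})
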