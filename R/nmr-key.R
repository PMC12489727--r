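# Coupling-constant diagnostics. In DMSO-d6 the acyl-quinates sit in a
# chair-dominated conformational equilibrium; a large trans-diaxial 3J(4,5)
# of the H-4 proton (~9 Hz) marks the quinic configuration, while the
# epi-quinic core equilibrates between two chairs and shows J < 8 Hz. The
# 8.0-8.5 Hz gap is deliberately left indeterminate: it was not observed
# and a single hard threshold there would overclaim.

#' Assign quinic vs epi-quinic core from the H-4 coupling constant
#'
#' @param J45Dmso Largest H-4 coupling (the trans-diaxial 3J(4,5)
#'   candidate) in Hz, measured in DMSO-d6; must be >= 0.
#' @return Named list: \code{core} (\code{"quinic"}, \code{"epi-quinic"} or
#'   \code{"indeterminate"}), \code{J} and \code{solvent}. Monotone step
#'   function of J: quinic for J >= 8.5, epi-quinic for J < 8.0,
#'   indeterminate in between.
#' @examples
#' assignCore(8.8)$core  # quinic
#' assignCore(7.3)$core  # epi-quinic
#' @export
assignCore <- function(J45Dmso) {
    if (J45Dmso < 0)
        stop("coupling constants must be >= 0 Hz")
    core <- if (J45Dmso >= 8.5) "quinic"
            else if (J45Dmso < 8.0) "epi-quinic"
            else "indeterminate"
    list(core = core, J = J45Dmso, solvent = "DMSO")
}

#' Solvent-shift consistency check for a core assignment
#'
#' In D2O the conformational equilibrium of a quinic core shifts further
#' toward the double-diaxial chair, so its trans-diaxial coupling must
#' increase relative to DMSO-d6 (e.g. 8.8 -> 10.1 Hz). For an epi-quinic
#' core the diagnostic is the increase of the 3J(3,4) coupling (e.g.
#' -> 8.9 Hz). Supply the relevant coupling pair for the claimed core.
#'
#' @param JDmso,JD2o The diagnostic coupling in Hz in each solvent (>= 0).
#' @param core \code{"quinic"} or \code{"epi-quinic"}.
#' @return \code{"consistent"} or \code{"inconsistent"}.
#' @export
solventShiftCheck <- function(JDmso, JD2o, core) {
    if (JDmso < 0 || JD2o < 0)
        stop("coupling constants must be >= 0 Hz")
    if (!core %in% c("quinic", "epi-quinic"))
        stop("unknown core label: ", core)
    # both cores: the conformational shift in D2O must increase the
    # diagnostic vicinal coupling (3J(4,5) for quinic, 3J(3,4) for epi)
    if (JD2o > JDmso) "consistent" else "inconsistent"
}

#' Beta-anomeric configuration from the anomeric coupling
#'
#' A large anomeric doublet (axial-axial H-1''/H-2'', >= 7 Hz) indicates a
#' beta-glucosidic configuration; small couplings (~3-4 Hz) indicate alpha.
#' The 7.0 Hz floor covers the observed anomeric range (7.3-8.1 Hz).
#'
#' @param J Anomeric coupling in Hz (>= 0).
#' @return \code{"beta"} or \code{"not_beta"}.
#' @export
checkAnomeric <- function(J) {
    if (J < 0)
        stop("coupling constants must be >= 0 Hz")
    if (J >= 7.0) "beta" else "not_beta"
}

#' Apply the core-assignment key to a coupling table
#'
#' Convenience wrapper over [assignCore()] for CSV-style input with one row
#' per compound: columns \code{compound}, \code{J} (largest H-4 coupling in
#' DMSO-d6, Hz).
#'
#' @param couplings data.frame with columns \code{compound} and \code{J},
#'   or a path to a CSV file with those columns.
#' @return data.frame with columns \code{compound}, \code{J}, \code{core}.
#' @export
assignCoreTable <- function(couplings) {
    if (is.character(couplings))
        couplings <- utils::read.csv(couplings, stringsAsFactors = FALSE)
    stopifnot(all(c("compound", "J") %in% names(couplings)))
    couplings$core <- vapply(couplings$J,
                             function(j) assignCore(j)$core, character(1))
    couplings[, c("compound", "J", "core")]
}
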