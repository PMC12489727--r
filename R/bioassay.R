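#' Four-parameter logistic IC50 fit
#'
#' Least-squares fit of the 4PL model
#' \deqn{y = bottom + (top - bottom) / (1 + exp(-hill (log d - log IC50)))}
#' via Levenberg-Marquardt (\pkg{minpack.lm}). The model is parameterised
#' in log(IC50), so the reported standard error of the IC50 comes from the
#' delta method on a scale where the sampling distribution is closer to
#' normal. For viability data (response decreasing with dose) set
#' \code{direction = "viability"}; the effect is then \code{100 - response}
#' and IC50 keeps its half-maximal-effect meaning.
#'
#' @param dose Concentrations (> 0, uM by convention); >= 5 distinct levels
#'   required.
#' @param response Percent inhibition (or percent viability), parallel to
#'   \code{dose}.
#' @param direction \code{"inhibition"} (response rises with dose, the
#'   default) or \code{"viability"} (response falls).
#' @return An [IC50Fit-class]. Status is \code{"censored_above_max"} when
#'   the maximal observed effect stays below 50% (the IC50 is then beyond
#'   the tested range), \code{"failed"} on non-convergence.
#' @examples
#' d <- 10 * 2^seq(-3, 4)
#' y <- 100 / (1 + 10 / d)          # exact 4PL, hill 1, IC50 10
#' fitIC50(d, y)
#' @export
fitIC50 <- function(dose, response, direction = c("inhibition",
                                                  "viability")) {
    direction <- match.arg(direction)
    stopifnot(length(dose) == length(response), all(is.finite(response)))
    if (any(dose <= 0))
        stop("doses must be positive")
    if (length(unique(dose)) < 5L)
        stop("at least 5 dose levels are required for a 4PL fit")
    effect <- if (direction == "viability") 100 - response else response

    if (max(effect) < 50)
        return(new("IC50Fit", ic50 = NA_real_, hill = NA_real_,
                   bottom = NA_real_, top = NA_real_, seIC50 = NA_real_,
                   seLogIC50 = NA_real_, status = "censored_above_max",
                   message = sprintf(
                       "max effect %.1f%% < 50%%; IC50 beyond tested range",
                       max(effect))))

    x <- log(dose)
    start <- list(bottom = max(min(effect), -20), top = min(max(effect), 110),
                  hill = 1, lambda = x[which.min(abs(effect - 50))])
    # box constraints keep the asymptotes on a percent scale and the
    # midpoint near the tested range; without them sparse noisy curves can
    # drift into degenerate bottom/top solutions
    lower <- c(bottom = -10, top = 55, hill = 0.1,
               lambda = min(x) - log(100))
    upper <- c(bottom = 45, top = 120, hill = 20,
               lambda = max(x) + log(100))
    fit <- tryCatch(
        minpack.lm::nlsLM(
            effect ~ bottom + (top - bottom) /
                (1 + exp(-hill * (x - lambda))),
            start = start, lower = lower, upper = upper,
            control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) e)
    if (inherits(fit, "error"))
        return(new("IC50Fit", ic50 = NA_real_, hill = NA_real_,
                   bottom = NA_real_, top = NA_real_, seIC50 = NA_real_,
                   seLogIC50 = NA_real_, status = "failed",
                   message = conditionMessage(fit)))
    cf <- stats::coef(fit)
    seLambda <- tryCatch(sqrt(diag(stats::vcov(fit)))[["lambda"]],
                         error = function(e) NA_real_)
    ic50 <- exp(cf[["lambda"]])
    new("IC50Fit", ic50 = ic50, hill = cf[["hill"]],
        bottom = cf[["bottom"]], top = cf[["top"]],
        seIC50 = ic50 * seLambda, seLogIC50 = seLambda,
        status = "ok", message = "")
}

#' Linear-interpolation IC50 (cross-check estimator)
#'
#' Dose at the first 50%-effect crossing, interpolated linearly in
#' log-dose. A model-free sanity check on [fitIC50()]; not recommended as
#' the primary estimator.
#'
#' @inheritParams fitIC50
#' @return IC50 (same units as dose) or NA when the response never crosses
#'   50%.
#' @export
interpolateIC50 <- function(dose, response,
                            direction = c("inhibition", "viability")) {
    direction <- match.arg(direction)
    effect <- if (direction == "viability") 100 - response else response
    o <- order(dose)
    d <- log(dose[o]); y <- effect[o]
    above <- which(y >= 50)
    if (!length(above) || above[1] == 1L)
        return(if (length(above)) exp(d[1]) else NA_real_)
    i <- above[1]
    exp(d[i - 1] + (50 - y[i - 1]) / (y[i] - y[i - 1]) * (d[i] - d[i - 1]))
}

#' @export
setMethod("show", "IC50Fit", function(object) {
    cat("IC50Fit:", object@status, "\n")
    if (object@status == "ok")
        cat(sprintf(
            "  IC50 = %.3g +/- %.2g, hill = %.2f, range [%.1f, %.1f]%%\n",
            object@ic50, object@seIC50, object@hill, object@bottom,
            object@top))
    else if (nzchar(object@message))
        cat(" ", object@message, "\n")
})

#' Catechol-based activity flag
#'
#' Structures carrying at least one catechol unit (ortho-dihydroxybenzene,
#' an effective hydrogen donor) are flagged as expected strong DPPH
#' radical scavengers; catechol-free structures (e.g. kaempferol
#' glycosides, whose B ring has a single hydroxyl) as weak.
#'
#' @param s Structure descriptor (object or descriptor string).
#' @return \code{"catechol_bearing"} or \code{"catechol_free"}.
#' @export
activityFlag <- function(s) {
    s <- parseDescriptor(s)
    if (catecholCount(s) >= 1L) "catechol_bearing" else "catechol_free"
}

#' Summarise tissue-abundance records for one compound
#'
#' @param records data.frame with columns \code{species}, \code{organ}
#'   (inflorescence/leaf/root), \code{phase} (BVC = beginning of the
#'   vegetation cycle, or flowering), \code{compound} and \code{mg_per_g}
#'   (mg per g dry tissue, >= 0).
#' @param compound Compound id to summarise.
#' @return Named list: \code{cellMeans} (mean per organ x phase),
#'   \code{organMeans}, \code{argmax} (the single record with the highest
#'   concentration), \code{foldDifference} (max organ mean / min positive
#'   organ mean; 1 when only one organ is present). Deterministic and
#'   invariant to record order.
#' @export
summarizeTissues <- function(records, compound) {
    stopifnot(all(c("species", "organ", "phase", "compound",
                    "mg_per_g") %in% names(records)))
    rec <- records[records$compound == compound, , drop = FALSE]
    if (!nrow(rec))
        stop("no records for compound ", compound)
    if (any(rec$mg_per_g < 0))
        stop("concentrations must be >= 0")
    rec <- rec[order(rec$species, rec$organ, rec$phase, rec$mg_per_g), ]
    cellMeans <- stats::aggregate(mg_per_g ~ organ + phase, data = rec,
                                  FUN = mean)
    organMeans <- stats::aggregate(mg_per_g ~ organ, data = rec, FUN = mean)
    pos <- organMeans$mg_per_g[organMeans$mg_per_g > 0]
    fold <- if (length(pos) >= 2L) max(pos) / min(pos) else 1
    argmax <- rec[which.max(rec$mg_per_g), , drop = FALSE]
    rownames(argmax) <- NULL
    list(cellMeans = cellMeans[order(cellMeans$organ, cellMeans$phase), ],
         organMeans = organMeans[order(organMeans$organ), ],
         argmax = argmax, foldDifference = fold)
}
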