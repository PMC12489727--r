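#' Read an MGF peak-list file
#'
#' Parses \code{BEGIN IONS}/\code{END IONS} blocks with \code{TITLE},
#' \code{PEPMASS}, \code{CHARGE} (\code{1-} = negative, \code{1+} =
#' positive) and \code{COLLISION_ENERGY} headers; a \code{CE=<x>} tag in
#' the title is honoured when no explicit header is present. Malformed
#' blocks are skipped with a warning naming the offending line.
#'
#' @param path MGF file path.
#' @return List of [MassSpectrum-class] objects.
#' @export
readMGF <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    starts <- grep("^BEGIN IONS\\s*$", lines)
    ends <- grep("^END IONS\\s*$", lines)
    if (!length(starts) || length(starts) != length(ends))
        stop("no valid BEGIN IONS/END IONS blocks in ", path)
    spectra <- list()
    for (b in seq_along(starts)) {
        block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
        hdr <- grep("=", block, fixed = TRUE, value = TRUE)
        pk <- grep("^\\s*[0-9]", block, value = TRUE)
        getHdr <- function(key) {
            v <- sub(paste0("^", key, "="), "",
                     grep(paste0("^", key, "="), hdr, value = TRUE))
            if (length(v)) v[1] else NA_character_
        }
        title <- getHdr("TITLE")
        if (is.na(title)) title <- ""
        pep <- suppressWarnings(
            as.numeric(strsplit(getHdr("PEPMASS"), "\\s+")[[1]][1]))
        charge <- getHdr("CHARGE")
        pol <- if (!is.na(charge) && grepl("-", charge, fixed = TRUE))
            "negative" else "positive"
        ce <- suppressWarnings(as.numeric(getHdr("COLLISION_ENERGY")))
        if (is.na(ce) && grepl("CE=", title)) {
            ce <- suppressWarnings(
                as.numeric(sub(".*CE=([0-9.]+).*", "\\1", title)))
        }
        fields <- strsplit(trimws(pk), "\\s+")
        ok <- lengths(fields) >= 2L
        if (!length(pk) || !all(ok)) {
            warning("skipping malformed block starting at line ", starts[b])
            next
        }
        mz <- as.numeric(vapply(fields, `[`, character(1), 1L))
        int <- as.numeric(vapply(fields, `[`, character(1), 2L))
        if (anyNA(mz) || anyNA(int)) {
            warning("skipping malformed block starting at line ", starts[b])
            next
        }
        spectra[[length(spectra) + 1L]] <-
            massSpectrum(mz, int, precursorMz = pep, collisionEnergy = ce,
                         polarity = pol, title = title)
    }
    if (!length(spectra))
        stop("no valid blocks in ", path)
    spectra
}

#' Write spectra to an MGF file
#'
#' Round-trips with [readMGF()]; peak m/z are written at 6 decimals.
#'
#' @param spectra A [MassSpectrum-class] or list of them.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeMGF <- function(spectra, path) {
    if (is(spectra, "MassSpectrum"))
        spectra <- list(spectra)
    out <- character(0)
    for (sp in spectra) {
        blk <- c("BEGIN IONS",
                 paste0("TITLE=", sp@title))
        if (!is.na(sp@precursorMz))
            blk <- c(blk, sprintf("PEPMASS=%.6f", sp@precursorMz))
        blk <- c(blk, paste0("CHARGE=1",
                             if (sp@polarity == "negative") "-" else "+"))
        if (!is.na(sp@collisionEnergy))
            blk <- c(blk, sprintf("COLLISION_ENERGY=%g",
                                  sp@collisionEnergy))
        blk <- c(blk, sprintf("%.6f %.6g", sp@mz, sp@intensity),
                 "END IONS", "")
        out <- c(out, blk)
    }
    writeLines(out, path)
    invisible(path)
}

#' Read a two-column CSV peak list
#'
#' @param path CSV with columns \code{mz} and \code{intensity}.
#' @return Two-column matrix (mz, intensity).
#' @export
readPeakCSV <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("mz", "intensity") %in% names(d)))
    cbind(mz = d$mz, intensity = d$intensity)
}

#' Pipeline configuration
#'
#' Defaults equal the documented design choices: 5 ppm MS2 annotation
#' tolerance, 10 mDa loss-explanation tolerance, 10 ppm precursor/oxidation
#' matching, TIC-fraction key thresholds.
#'
#' @param tolPpmMs2 MS/MS annotation tolerance (ppm).
#' @param tolPpmPrecursor Precursor formula-match tolerance (ppm).
#' @param tolMDaLoss Neutral-loss explanation tolerance (mDa).
#' @param eluentPreset Eluent preset label carried into reports.
#' @param seed Integer seed for any stochastic stage.
#' @return Named list of class \code{"RunConfig"}.
#' @export
pipelineConfig <- function(tolPpmMs2 = 5, tolPpmPrecursor = 10,
                           tolMDaLoss = 10, eluentPreset = "formic_0.1",
                           seed = 1L) {
    structure(list(tolPpmMs2 = tolPpmMs2,
                   tolPpmPrecursor = tolPpmPrecursor,
                   tolMDaLoss = tolMDaLoss, eluentPreset = eluentPreset,
                   seed = as.integer(seed)),
              class = "RunConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
readConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    do.call(pipelineConfig, cfg)
}

#' @rdname pipelineConfig
#' @param config A \code{RunConfig}.
#' @export
writeConfig <- function(config, path) {
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

# Pair 25 eV and 45 eV spectra by precursor m/z (within tolPpm) and shared
# title stem (title up to the first "CE=" tag).
.pairSpectra <- function(spectra, tolPpm = 10) {
    stem <- vapply(spectra, function(s)
        trimws(sub("CE=.*$", "", s@title)), character(1))
    ce <- vapply(spectra, function(s) s@collisionEnergy, numeric(1))
    prec <- vapply(spectra, function(s) s@precursorMz, numeric(1))
    i25 <- which(ce == 25)
    i45 <- which(ce == 45)
    used45 <- logical(length(i45))
    pairs <- list()
    for (i in i25) {
        match45 <- NULL
        for (k in seq_along(i45)) {
            j <- i45[k]
            if (used45[k] || stem[j] != stem[i])
                next
            if (is.na(prec[i]) || is.na(prec[j]) ||
                abs(ppmError(prec[j], prec[i])) > tolPpm)
                next
            match45 <- j
            used45[k] <- TRUE
            break
        }
        pairs[[length(pairs) + 1L]] <- list(spec25 = spectra[[i]],
                                            spec45 = if (is.null(match45))
                                                NULL else spectra[[match45]])
    }
    if (any(!used45))
        warning(sum(!used45), " unpaired 45 eV spectrum/spectra ignored")
    pairs
}

#' Run the full interpretation pipeline over an MGF file
#'
#' Per precursor: (1) formula check of the precursor m/z against the known
#' compound panel ([knownCompounds()]) within the precursor ppm tolerance;
#' (2) fragment annotation against the matched structure's theoretical
#' tree; (3) the two-stage isomer key for MDiCQA precursors (25 eV
#' spectrum required, 45 eV used when present). Stage failures are
#' recorded per spectrum and the pipeline continues.
#'
#' @param mgfPath Input MGF with one 25 eV and optionally one 45 eV
#'   spectrum per precursor.
#' @param config A [pipelineConfig()].
#' @param jsonPath Optional path; when given, the report is also written as
#'   deterministically formatted JSON (identical inputs and config give
#'   byte-identical files).
#' @return List of per-precursor reports: \code{title}, \code{precursorMz},
#'   \code{formulaMatch} (compound id, formula, ppm or NA), \code{nAnnotated},
#'   \code{call} (isomer label), \code{confidence}, \code{error}.
#' @export
runPipeline <- function(mgfPath, config = pipelineConfig(),
                        jsonPath = NULL) {
    spectra <- readMGF(mgfPath)
    panel <- knownCompounds()
    reports <- lapply(.pairSpectra(spectra, config$tolPpmPrecursor),
                      function(pair) {
        sp <- pair$spec25
        rep <- list(title = sp@title,
                    precursorMz = round(sp@precursorMz, 4),
                    formulaMatch = NA_character_, formula = NA_character_,
                    precursorPpm = NA_real_, nAnnotated = 0L,
                    call = NA_character_, confidence = NA_character_,
                    error = NA_character_)
        err <- ppmError(sp@precursorMz, panel$mzNeg)
        j <- which.min(abs(err))
        if (abs(err[j]) > config$tolPpmPrecursor) {
            rep$error <- "precursor matches no known compound formula"
            return(rep)
        }
        hits <- panel$id[panel$formula == panel$formula[j]]
        rep$formulaMatch <- paste(hits, collapse = "|")
        rep$formula <- panel$formula[j]
        rep$precursorPpm <- round(err[j], 2)
        ann <- tryCatch({
            nodes <- generateFragments(panel$descriptor[j], maxDepth = 4L)
            annotatePeaks(sp, nodes, config$tolPpmMs2)
        }, error = function(e) NULL)
        if (!is.null(ann))
            rep$nAnnotated <- sum(!is.na(ann$matchedFormula))
        if (identical(panel$formula[j], "C28H26O15")) {
            call <- tryCatch(classifyIsomer(sp, pair$spec45),
                             error = function(e) e)
            if (inherits(call, "error")) {
                rep$error <- conditionMessage(call)
            } else {
                rep$call <- call@label
                rep$confidence <- call@confidence
            }
        }
        rep
    })
    if (!is.null(jsonPath)) {
        json <- jsonlite::toJSON(reports, auto_unbox = TRUE, digits = 6,
                                 na = "null", pretty = TRUE)
        writeLines(json, jsonPath)
    }
    reports
}
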