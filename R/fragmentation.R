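# Neutral-loss vocabulary of the ester fragmentation grammar. The malonyl
# residue leaves as C3H2O3 (ketene-type ester cleavage, 86.0004 Da), not as
# malonic acid: only that loss reproduces the observed 601->515 and 549->463
# deltas. Caffeoyl and glucosyl residues are isomass at nominal 162 but
# differ by 21 mDa, which exact-mass matching separates.
.neutralLosses <- data.frame(
    label = c("malonyl_residue", "caffeoyl_residue", "glucosyl_residue",
              "CO2", "H2O"),
    formula = c("C3H2O3", "C9H6O3", "C6H10O5", "CO2", "H2O"),
    stringsAsFactors = FALSE)

#' Neutral-loss vocabulary
#'
#' @return data.frame with columns \code{label}, \code{formula} and
#'   \code{mass} (Da) of the five losses the grammar can apply: malonyl
#'   residue (86.0004), caffeoyl residue (162.0317), glucosyl residue
#'   (162.0528), CO2 (43.9898) and H2O (18.0106).
#' @export
neutralLosses <- function() {
    d <- .neutralLosses
    d$mass <- vapply(d$formula, monoisotopicMass, numeric(1))
    d
}

# Loss budget available to a structure: how many times each loss may fire.
.lossBudget <- function(s) {
    if (is(s, "AcylQuinate")) {
        list(malonyl_residue = sum(s@substituents == "mal"),
             caffeoyl_residue = sum(s@substituents == "caf"),
             glucosyl_residue = 0L,
             CO2 = 1L,      # the free carboxyl at C-1
             H2O = 1L)
    } else if (is(s, "FlavonoidGlycoside")) {
        nmal <- length(s@malonylPositions)
        list(malonyl_residue = nmal,
             caffeoyl_residue = 0L,
             glucosyl_residue = 1L,
             CO2 = if (nmal > 0L) 1L else 0L,  # malonyl free carboxyl
             H2O = 1L)
    } else stop("unsupported structure descriptor")
}

#' Generate the theoretical fragment tree of a structure
#'
#' Breadth-first expansion of the neutral-loss grammar from the deprotonated
#' molecule: each available loss fires at most its multiplicity (one malonyl
#' residue per malonyl ester, one caffeoyl residue per caffeoyl ester, one
#' glucosyl residue per glycosidic bond — and only after every malonyl on
#' the sugar has left, matching the demalonylation-first series 619 -> 533
#' -> 447; one CO2 while a free carboxyl is present; one H2O). Nodes are
#' deduplicated by remaining formula. For acyl-quinates, terminal marker
#' ions are appended: deprotonated quinic acid (nominal 191), caffeic acid
#' (179, when a caffeoyl is present) and dehydrated quinic acid (173).
#'
#' @param s Structure descriptor ([AcylQuinate-class],
#'   [FlavonoidGlycoside-class], or a descriptor string).
#' @param maxDepth Maximum number of sequential losses (>= 0).
#' @return data.frame with columns \code{formula}, \code{mz} (exact
#'   negative-mode m/z), \code{nominal}, \code{depth}, \code{path}
#'   (loss labels joined by \code{">"}; \code{""} for the precursor) and
#'   \code{marker} (logical).
#' @examples
#' fr <- generateFragments("QA[1:caf,3:mal,5:caf]", maxDepth = 4)
#' sort(unique(fr$nominal))
#' @export
generateFragments <- function(s, maxDepth = 4L) {
    s <- parseDescriptor(s)
    maxDepth <- as.integer(maxDepth)
    if (maxDepth < 0L)
        stop("maxDepth must be >= 0")
    losses <- neutralLosses()
    budget0 <- .lossBudget(s)
    root <- neutralFormula(s)
    isQuinate <- is(s, "AcylQuinate")

    nodes <- list(list(formula = root, depth = 0L, path = character(0),
                       budget = budget0))
    seen <- formulaString(root)
    frontier <- nodes
    depth <- 0L
    while (depth < maxDepth && length(frontier)) {
        nxt <- list()
        for (node in frontier) {
            for (i in seq_len(nrow(losses))) {
                lab <- losses$label[i]
                if (node$budget[[lab]] < 1L)
                    next
                # glucosyl leaves only after all sugar malonyls are gone
                if (lab == "glucosyl_residue" &&
                    node$budget$malonyl_residue > 0L)
                    next
                rem <- tryCatch(
                    formulaSubtract(node$formula, losses$formula[i]),
                    error = function(e) NULL)
                if (is.null(rem))
                    next
                key <- formulaString(rem)
                if (key %in% seen)
                    next
                seen <- c(seen, key)
                b <- node$budget
                b[[lab]] <- b[[lab]] - 1L
                child <- list(formula = rem, depth = depth + 1L,
                              path = c(node$path, lab), budget = b)
                nodes[[length(nodes) + 1L]] <- child
                nxt[[length(nxt) + 1L]] <- child
            }
        }
        frontier <- nxt
        depth <- depth + 1L
    }

    out <- data.frame(
        formula = vapply(nodes, function(n) formulaString(n$formula),
                         character(1)),
        mz = vapply(nodes, function(n) mzIon(n$formula, "negative"),
                    numeric(1)),
        depth = vapply(nodes, function(n) n$depth, integer(1)),
        path = vapply(nodes, function(n) paste(n$path, collapse = ">"),
                      character(1)),
        marker = FALSE,
        stringsAsFactors = FALSE)

    if (isQuinate && maxDepth >= 1L) {
        markers <- list(list(f = "C7H12O6", lab = "marker:quinic"),
                        list(f = "C7H10O5", lab = "marker:quinic-H2O"))
        if (budget0$caffeoyl_residue > 0L)
            markers <- c(markers,
                         list(list(f = "C9H8O4", lab = "marker:caffeic")))
        for (m in markers) {
            if (formulaString(parseFormula(m$f)) %in% out$formula)
                next
            out <- rbind(out, data.frame(
                formula = formulaString(parseFormula(m$f)),
                mz = mzIon(m$f, "negative"),
                depth = NA_integer_, path = m$lab, marker = TRUE,
                stringsAsFactors = FALSE))
        }
    }
    out$nominal <- nominalMz(out$mz)
    out[order(-out$mz), c("formula", "mz", "nominal", "depth", "path",
                          "marker")]
}

#' Annotate observed peaks against a fragment tree
#'
#' Each peak is matched to the nearest theoretical node within a ppm
#' tolerance; one node may annotate several peaks; unmatched peaks keep NA
#' annotations. The default 5 ppm reflects Orbitrap-class accuracy.
#'
#' @param spectrum A negative-mode [MassSpectrum-class].
#' @param nodes Fragment table from [generateFragments()].
#' @param tolPpm Match tolerance in ppm (> 0).
#' @return data.frame with columns \code{mz}, \code{intensity},
#'   \code{matchedFormula}, \code{matchedMz}, \code{path}, \code{ppm}.
#' @export
annotatePeaks <- function(spectrum, nodes, tolPpm = 5) {
    stopifnot(is(spectrum, "MassSpectrum"))
    if (spectrum@polarity != "negative")
        stop("peak annotation supports negative-mode spectra only")
    if (tolPpm <= 0)
        stop("tolPpm must be > 0")
    n <- length(spectrum@mz)
    out <- data.frame(mz = spectrum@mz, intensity = spectrum@intensity,
                      matchedFormula = rep(NA_character_, n),
                      matchedMz = rep(NA_real_, n),
                      path = rep(NA_character_, n),
                      ppm = rep(NA_real_, n), stringsAsFactors = FALSE)
    if (!n || !NROW(nodes))
        return(out)
    for (i in seq_len(n)) {
        err <- ppmError(out$mz[i], nodes$mz)
        j <- which.min(abs(err))
        if (abs(err[j]) <= tolPpm) {
            out$matchedFormula[i] <- nodes$formula[j]
            out$matchedMz[i] <- nodes$mz[j]
            out$path[i] <- nodes$path[j]
            out$ppm[i] <- err[j]
        }
    }
    out
}

#' Explain a precursor-to-fragment mass difference as neutral losses
#'
#' Enumerates every multiset of at most three losses from the grammar
#' vocabulary (including the empty combination) whose summed mass matches
#' \code{parentMz - fragmentMz} within a mDa tolerance, sorted by absolute
#' error.
#'
#' @param parentMz,fragmentMz Observed m/z, \code{parentMz >= fragmentMz}.
#' @param tolMDa Tolerance in milli-Da (default 10).
#' @return data.frame with columns \code{losses} (labels joined by
#'   \code{"+"}, \code{""} for the empty combination), \code{mass},
#'   \code{errorMDa}; zero rows if nothing matches.
#' @examples
#' explainLoss(601.12, 515.12)  # the malonyl-residue loss
#' @export
explainLoss <- function(parentMz, fragmentMz, tolMDa = 10) {
    if (parentMz < fragmentMz)
        stop("parent m/z must be >= fragment m/z")
    delta <- parentMz - fragmentMz
    losses <- neutralLosses()
    k <- nrow(losses)
    combos <- list(integer(0))
    for (size in 1:3) {
        g <- expand.grid(rep(list(seq_len(k)), size))
        nondec <- apply(as.matrix(g), 1L,
                        function(r) all(diff(r) >= 0))
        rows <- as.matrix(g)[nondec, , drop = FALSE]
        combos <- c(combos,
                    lapply(seq_len(nrow(rows)),
                           function(i) as.integer(rows[i, ])))
    }
    mass <- vapply(combos, function(ix) sum(losses$mass[ix]), numeric(1))
    err <- (mass - delta) * 1000
    keep <- abs(err) <= tolMDa
    out <- data.frame(
        losses = vapply(combos, function(ix)
            paste(losses$label[ix], collapse = "+"), character(1)),
        mass = mass, errorMDa = err, stringsAsFactors = FALSE)[keep, ]
    out[order(abs(out$errorMDa)), , drop = FALSE]
}
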