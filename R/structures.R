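# Building-block formulas. Esterification/glycosylation removes one H2O per
# bond formed, so e.g. MDiCQA = quinic + 2 caffeic + malonic - 3 H2O.
.coreFormulas <- list(
    quinic     = "C7H12O6",
    caffeic    = "C9H8O4",
    malonic    = "C3H4O4",
    glucose    = "C6H12O6",
    water      = "H2O",
    quercetin  = "C15H10O7",
    luteolin   = "C15H10O6",
    kaempferol = "C15H10O6")

.acylParent <- c(caf = "caffeic", mal = "malonic")

#' Construct an acyl-quinate structure descriptor
#'
#' @param substituents Named character vector mapping hydroxyl position
#'   (\code{"1","3","4","5"}) to acyl label (\code{"caf"} or \code{"mal"});
#'   empty for unsubstituted quinic acid.
#' @param core \code{"quinic"} (default) or \code{"epi-quinic"}. A label
#'   only: regiochemistry and mass are core-independent.
#' @return An [AcylQuinate-class].
#' @examples
#' # compound 4, 1,5-dicaffeoyl-3-malonylquinic acid:
#' acylQuinate(c("1" = "caf", "3" = "mal", "5" = "caf"))
#' @export
acylQuinate <- function(substituents = character(0), core = "quinic") {
    sub <- setNames(as.character(substituents), names(substituents))
    if (length(sub))
        sub <- sub[order(names(sub))]
    new("AcylQuinate", core = core, substituents = sub)
}

#' Construct a flavonoid malonyl-glucoside descriptor
#'
#' @param aglycone \code{"quercetin"}, \code{"luteolin"} or
#'   \code{"kaempferol"}.
#' @param glycosylationPosition 3 or 7.
#' @param malonylPositions Character subset of \code{c("2''", "6''")}.
#' @return A [FlavonoidGlycoside-class].
#' @examples
#' flavonoidGlycoside("quercetin", 3, "6''")  # compound 1
#' @export
flavonoidGlycoside <- function(aglycone, glycosylationPosition = 3,
                               malonylPositions = character(0)) {
    new("FlavonoidGlycoside", aglycone = aglycone,
        glycosylationPosition = as.integer(glycosylationPosition),
        malonylPositions = sort(as.character(malonylPositions)))
}

#' @rdname neutralFormula
#' @export
setMethod("neutralFormula", "AcylQuinate", function(object) {
    f <- parseFormula(.coreFormulas$quinic)
    for (acyl in object@substituents) {
        f <- formulaAdd(f, .coreFormulas[[.acylParent[[acyl]]]])
        f <- formulaSubtract(f, .coreFormulas$water)
    }
    f
})

#' @rdname neutralFormula
#' @export
setMethod("neutralFormula", "FlavonoidGlycoside", function(object) {
    f <- formulaAdd(.coreFormulas[[object@aglycone]], .coreFormulas$glucose)
    f <- formulaSubtract(f, .coreFormulas$water)   # glycosidic bond
    for (p in object@malonylPositions) {
        f <- formulaAdd(f, .coreFormulas$malonic)
        f <- formulaSubtract(f, .coreFormulas$water)
    }
    f
})

#' @rdname catecholCount
#' @export
setMethod("catecholCount", "AcylQuinate", function(object) {
    sum(object@substituents == "caf")
})

#' @rdname catecholCount
#' @export
setMethod("catecholCount", "FlavonoidGlycoside", function(object) {
    base <- if (object@aglycone %in% c("quercetin", "luteolin")) 1L else 0L
    base
})

#' Enumerate acyl-quinate regioisomers
#'
#' All distinct assignments of \code{nCaffeoyl} caffeoyl and \code{nMalonyl}
#' malonyl ester groups over the four acylatable hydroxyl positions
#' \{1,3,4,5\} of the quinic acid core. The count is the multinomial
#' 4!/(a! b! (4-a-b)!): two caffeoyl plus one malonyl gives the 12
#' regioisomeric MDiCQAs. The carboxyl at C-1 is never esterified by an
#' acid; the C-1 hydroxyl is acylatable. Core stereochemistry is not an
#' enumerated dimension (every structure carries the \code{"quinic"} label).
#'
#' @param nCaffeoyl,nMalonyl Non-negative integers, sum <= 4.
#' @return List of [AcylQuinate-class] objects in deterministic
#'   lexicographic order (by position, caffeoyl before malonyl).
#' @examples
#' length(enumerateRegioisomers(2, 1))  # 12
#' @export
enumerateRegioisomers <- function(nCaffeoyl, nMalonyl) {
    nCaffeoyl <- as.integer(nCaffeoyl)
    nMalonyl <- as.integer(nMalonyl)
    if (nCaffeoyl < 0 || nMalonyl < 0)
        stop("acyl counts must be non-negative")
    if (nCaffeoyl + nMalonyl > 4L)
        stop("cannot place ", nCaffeoyl + nMalonyl,
             " acyl groups on 4 positions")
    positions <- c("1", "3", "4", "5")
    labels <- c(rep("caf", nCaffeoyl), rep("mal", nMalonyl))
    if (!length(labels))
        return(list(acylQuinate()))
    # all ordered choices of positions for the distinct label slots,
    # deduplicated over permutations of identical labels
    out <- list()
    seen <- character(0)
    idx <- utils::combn(4L, length(labels), simplify = FALSE)
    perms <- .permutations(length(labels))
    for (cmb in idx) {
        for (p in perms) {
            sub <- setNames(labels[p], positions[cmb])
            key <- paste(names(sub), sub, sep = ":", collapse = ",")
            if (key %in% seen)
                next
            seen <- c(seen, key)
            out[[length(out) + 1L]] <- acylQuinate(sub)
        }
    }
    out[order(vapply(out, quinateDescriptor, character(1)))]
}

.permutations <- function(n) {
    if (n <= 1L)
        return(list(seq_len(n)))
    out <- list()
    for (i in seq_len(n)) {
        rest <- setdiff(seq_len(n), i)
        for (p in .permutations(n - 1L))
            out[[length(out) + 1L]] <- c(i, rest[p])
    }
    out
}

#' Compact structure descriptor strings
#'
#' Acyl-quinates serialise as \code{"QA[1:caf,3:mal,5:caf]"}
#' (\code{"epiQA[...]"} for the epi-quinic core); flavonoid glycosides as
#' \code{"QCT-3-Glc[6'':mal]"} / \code{"LUT-7-Glc[2'':mal,6'':mal]"} /
#' \code{"KMP-3-Glc[...]"}. \code{parseDescriptor} and the two writers
#' round-trip.
#'
#' @param object An \code{AcylQuinate} or \code{FlavonoidGlycoside}.
#' @return Character scalar.
#' @export
quinateDescriptor <- function(object) {
    stopifnot(is(object, "AcylQuinate"))
    head <- if (object@core == "quinic") "QA" else "epiQA"
    sub <- object@substituents
    inner <- if (length(sub))
        paste(names(sub), sub, sep = ":", collapse = ",") else ""
    paste0(head, "[", inner, "]")
}

#' @rdname quinateDescriptor
#' @export
glycosideDescriptor <- function(object) {
    stopifnot(is(object, "FlavonoidGlycoside"))
    head <- c(quercetin = "QCT", luteolin = "LUT", kaempferol = "KMP")
    inner <- if (length(object@malonylPositions))
        paste(object@malonylPositions, "mal", sep = ":", collapse = ",")
    else ""
    paste0(head[[object@aglycone]], "-", object@glycosylationPosition,
           "-Glc[", inner, "]")
}

#' @rdname quinateDescriptor
#' @param x Descriptor string.
#' @export
parseDescriptor <- function(x) {
    if (is(x, "AcylQuinate") || is(x, "FlavonoidGlycoside"))
        return(x)
    stopifnot(is.character(x), length(x) == 1L)
    m <- regmatches(x, regexec("^(epiQA|QA)\\[([^]]*)\\]$", x))[[1]]
    if (length(m)) {
        core <- if (m[2] == "epiQA") "epi-quinic" else "quinic"
        return(acylQuinate(.parseSubs(m[3]), core = core))
    }
    m <- regmatches(x,
        regexec("^(QCT|LUT|KMP)-([37])-Glc\\[([^]]*)\\]$", x))[[1]]
    if (length(m)) {
        agly <- c(QCT = "quercetin", LUT = "luteolin",
                  KMP = "kaempferol")[[m[2]]]
        sub <- .parseSubs(m[4])
        if (length(sub) && !all(sub == "mal"))
            stop("only malonyl esters are supported on the sugar")
        return(flavonoidGlycoside(agly, as.integer(m[3]), names(sub)))
    }
    stop("cannot parse structure descriptor: ", x)
}

.parseSubs <- function(inner) {
    if (inner == "")
        return(character(0))
    parts <- strsplit(strsplit(inner, ",", fixed = TRUE)[[1]], ":",
                      fixed = TRUE)
    setNames(vapply(parts, `[`, character(1), 2L),
             vapply(parts, `[`, character(1), 1L))
}

#' @export
setMethod("show", "AcylQuinate", function(object) {
    cat("AcylQuinate", quinateDescriptor(object), "\n")
    cat("  neutral formula:", formulaString(neutralFormula(object)),
        sprintf(" [M-H]- %.4f\n", mzIon(neutralFormula(object), "negative")))
})

#' @export
setMethod("show", "FlavonoidGlycoside", function(object) {
    cat("FlavonoidGlycoside", glycosideDescriptor(object), "\n")
    cat("  neutral formula:", formulaString(neutralFormula(object)),
        sprintf(" [M-H]- %.4f\n", mzIon(neutralFormula(object), "negative")))
})

#' The nine study compounds
#'
#' Registry of structure descriptors for the compound panel: four flavonoid
#' malonyl-glucosides (1-3, 8), four malonyl-dicaffeoylquinic acid isomers
#' (4-7) and one dimalonyl-dicaffeoylquinic acid (9).
#'
#' @return A data.frame with columns \code{id}, \code{name},
#'   \code{descriptor}, \code{formula}, \code{mzNeg} ([M-H]- m/z) and
#'   \code{catechols}.
#' @examples
#' knownCompounds()
#' @export
knownCompounds <- function() {
    d <- data.frame(
        id = paste0("cpd", 1:9),
        name = c(
            "quercetin-3-O-(6''-O-malonyl)-glucoside",
            "luteolin-7-O-(6''-O-malonyl)-glucoside",
            "kaempferol-3-O-(6''-O-malonyl)-glucoside",
            "1,5-dicaffeoyl-3-malonylquinic acid",
            "3,5-dicaffeoyl-1-malonylquinic acid",
            "3,5-dicaffeoyl-4-malonyl-epi-quinic acid",
            "1,5-dicaffeoyl-4-malonylquinic acid",
            "luteolin-7-O-(2'',6''-di-O-malonyl)-glucoside",
            "1,5-dicaffeoyl-3,4-dimalonylquinic acid"),
        descriptor = c(
            "QCT-3-Glc[6'':mal]",
            "LUT-7-Glc[6'':mal]",
            "KMP-3-Glc[6'':mal]",
            "QA[1:caf,3:mal,5:caf]",
            "QA[1:mal,3:caf,5:caf]",
            "epiQA[3:caf,4:mal,5:caf]",
            "QA[1:caf,4:mal,5:caf]",
            "LUT-7-Glc[2'':mal,6'':mal]",
            "QA[1:caf,3:mal,4:mal,5:caf]"),
        stringsAsFactors = FALSE)
    structs <- lapply(d$descriptor, parseDescriptor)
    d$formula <- vapply(structs,
        function(s) formulaString(neutralFormula(s)), character(1))
    d$mzNeg <- vapply(structs,
        function(s) mzIon(neutralFormula(s), "negative"), numeric(1))
    d$catechols <- vapply(structs, catecholCount, integer(1))
    d
}
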