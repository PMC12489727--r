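# Monoisotopic (most-abundant-isotope) masses, IUPAC values, pinned as
# constants so computed m/z values are bit-stable across platforms.
.isotopeMasses <- c(
    C = 12.000000000,
    H = 1.0078250319,
    N = 14.0030740052,
    O = 15.9949146221,
    S = 31.9720707300)

.electronMass <- 0.00054857990907

#' Parse a Hill-notation formula string
#'
#' Accepts strings such as \code{"C28H26O15"} (Hill order, no parentheses;
#' an omitted count means 1). The inverse of [formulaString()].
#'
#' @param x Character scalar formula, or an \code{ElementalFormula} (returned
#'   unchanged).
#' @return An [ElementalFormula-class].
#' @examples
#' parseFormula("C28H26O15")
#' formulaString(parseFormula("H2O"))
#' @export
parseFormula <- function(x) {
    if (is(x, "ElementalFormula"))
        return(x)
    stopifnot(is.character(x), length(x) == 1L)
    if (x == "" || is.na(x))
        return(new("ElementalFormula"))
    tokens <- regmatches(x, gregexpr("[A-Z][a-z]?[0-9]*", x))[[1]]
    if (nchar(paste(tokens, collapse = "")) != nchar(x))
        stop("cannot parse formula string: ", x)
    sym <- sub("[0-9]*$", "", tokens)
    n <- sub("^[A-Za-z]+", "", tokens)
    n <- ifelse(n == "", 1L, as.integer(n))
    counts <- tapply(n, sym, sum)
    elementalFormula(setNames(as.integer(counts), names(counts)))
}

#' Construct an ElementalFormula from named counts
#'
#' @param counts Named numeric/integer vector of element counts; zero counts
#'   are dropped.
#' @return An [ElementalFormula-class].
#' @export
elementalFormula <- function(counts = integer(0)) {
    counts <- counts[counts != 0]
    cnt <- setNames(as.integer(counts), names(counts))
    # Hill order: C, H, then alphabetical
    ord <- c("C", "H", setdiff(sort(names(cnt)), c("C", "H")))
    new("ElementalFormula", counts = cnt[ord[ord %in% names(cnt)]])
}

#' Serialize a formula to Hill notation
#'
#' @param f An \code{ElementalFormula}.
#' @return Character scalar, e.g. \code{"C28H26O15"}; \code{""} for the
#'   empty formula.
#' @export
formulaString <- function(f) {
    f <- parseFormula(f)
    cnt <- f@counts
    if (!length(cnt))
        return("")
    paste0(names(cnt), ifelse(cnt == 1L, "", cnt), collapse = "")
}

#' @describeIn parseFormula Show method prints the Hill string.
#' @param object An \code{ElementalFormula}.
#' @export
setMethod("show", "ElementalFormula", function(object) {
    cat("ElementalFormula:", if (length(object@counts))
        formulaString(object) else "(empty)", "\n")
})

#' Count-wise formula arithmetic
#'
#' \code{formulaAdd} sums counts; \code{formulaSubtract} differences them and
#' fails if any element would go negative (a neutral loss must be contained
#' in the species it leaves).
#'
#' @param a,b Formulas (objects or Hill strings).
#' @return An [ElementalFormula-class].
#' @examples
#' formulaSubtract("C28H26O15", "C3H2O3")  # C25H24O12
#' @export
formulaAdd <- function(a, b) {
    a <- parseFormula(a)@counts
    b <- parseFormula(b)@counts
    all <- union(names(a), names(b))
    elementalFormula(setNames(
        ifelse(all %in% names(a), a[all], 0L) +
        ifelse(all %in% names(b), b[all], 0L), all))
}

#' @rdname formulaAdd
#' @export
formulaSubtract <- function(a, b) {
    a <- parseFormula(a)@counts
    b <- parseFormula(b)@counts
    all <- union(names(a), names(b))
    av <- setNames(ifelse(all %in% names(a), a[all], 0L), all)
    bv <- setNames(ifelse(all %in% names(b), b[all], 0L), all)
    d <- av - bv
    if (any(d < 0))
        stop("loss not contained in formula: element ",
             paste(all[d < 0], collapse = ", "), " would go negative")
    elementalFormula(d)
}

#' Monoisotopic mass of a neutral formula
#'
#' Sum of per-element most-abundant-isotope masses (IUPAC values pinned in
#' the package source). Additive: \code{mass(a) + mass(b) == mass(a + b)}.
#'
#' @param f Formula (object or Hill string).
#' @return Mass in Da.
#' @examples
#' monoisotopicMass("H2O")        # 18.010565
#' monoisotopicMass("C28H26O15")  # 602.1272
#' @export
monoisotopicMass <- function(f) {
    cnt <- parseFormula(f)@counts
    if (!length(cnt))
        return(0)
    unknown <- setdiff(names(cnt), names(.isotopeMasses))
    if (length(unknown))
        stop("unknown element symbol: ", paste(unknown, collapse = ", "))
    sum(.isotopeMasses[names(cnt)] * cnt)
}

#' Exact m/z of a singly charged (de)protonated ion
#'
#' Negative mode gives the deprotonated ion [M-H]-: monoisotopic mass minus
#' one hydrogen atom plus one electron. Positive mode gives [M+H]+: plus one
#' hydrogen atom minus one electron. The electron mass (0.00054858 Da) is
#' included; at 4-decimal Orbitrap precision it is not negligible. Only
#' singly charged species are supported.
#'
#' @param f Neutral formula (object or Hill string).
#' @param polarity \code{"negative"} (default) or \code{"positive"}.
#' @return m/z in Th.
#' @examples
#' mzIon("C28H26O15", "negative")  # 601.1199, the MDiCQA [M-H]- ion
#' @export
mzIon <- function(f, polarity = c("negative", "positive")) {
    polarity <- match.arg(polarity)
    f <- parseFormula(f)
    m <- monoisotopicMass(f)
    h <- .isotopeMasses[["H"]]
    if (polarity == "negative") {
        nH <- if ("H" %in% names(f@counts)) f@counts[["H"]] else 0L
        if (nH < 1L)
            stop("deprotonation requires at least one H in the neutral formula")
        m - h + .electronMass
    } else {
        m + h - .electronMass
    }
}

#' Signed parts-per-million mass error
#'
#' @param observed,theoretical m/z values; \code{theoretical} must be > 0.
#' @return Signed ppm: \code{(observed - theoretical)/theoretical * 1e6}.
#' @export
ppmError <- function(observed, theoretical) {
    if (any(theoretical <= 0))
        stop("theoretical m/z must be positive")
    (observed - theoretical) / theoretical * 1e6
}

# round-half-up nominal m/z; base round() is round-half-even, which would
# give the wrong nominal value for x.5 exact masses
.roundHalfUp <- function(x) floor(x + 0.5)

#' Nominal (integer) m/z of an exact m/z
#'
#' Round-half-up, the convention under which all printed nominal fragment
#' values (515, 557, 233, ...) reproduce from the exact masses.
#'
#' @param mz Numeric m/z.
#' @return Integer nominal m/z.
#' @export
nominalMz <- function(mz) as.integer(.roundHalfUp(mz))
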