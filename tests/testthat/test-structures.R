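# Brute-force oracle: label each of the four positions {1,3,4,5} with
# none/caf/mal and count labelings with the requested composition.
.bruteCount <- function(nCaf, nMal) {
    g <- expand.grid(rep(list(c("none", "caf", "mal")), 4))
    sum(apply(g, 1, function(r)
        sum(r == "caf") == nCaf && sum(r == "mal") == nMal))
}

test_that("neutral formulas of the compound panel are correct", {
    cpd4 <- acylQuinate(c("1" = "caf", "3" = "mal", "5" = "caf"))
    expect_identical(formulaString(neutralFormula(cpd4)), "C28H26O15")
    cpd9 <- acylQuinate(c("1" = "caf", "3" = "mal", "4" = "mal",
                          "5" = "caf"))
    expect_identical(formulaString(neutralFormula(cpd9)), "C31H28O18")
    cpd2 <- flavonoidGlycoside("luteolin", 7, "6''")
    expect_identical(formulaString(neutralFormula(cpd2)), "C24H22O14")
    cpd8 <- flavonoidGlycoside("luteolin", 7, c("2''", "6''"))
    expect_identical(formulaString(neutralFormula(cpd8)), "C27H24O17")
    # unsubstituted core is quinic acid itself
    expect_identical(formulaString(neutralFormula(acylQuinate())),
                     "C7H12O6")
})

test_that("neutral formula is invariant under substituent permutation", {
    isomers <- enumerateRegioisomers(2, 1)
    fs <- vapply(isomers, function(s) formulaString(neutralFormula(s)),
                 character(1))
    expect_true(all(fs == "C28H26O15"))
    mz <- vapply(isomers, function(s)
        mzIon(neutralFormula(s), "negative"), numeric(1))
    expect_equal(max(mz) - min(mz), 0, tolerance = 1e-12)
})

test_that("regioisomer enumeration matches the brute-force oracle", {
    expect_length(enumerateRegioisomers(2, 1), 12L)
    expect_length(enumerateRegioisomers(1, 0), 4L)
    expect_length(enumerateRegioisomers(2, 2), 6L)
    for (a in 0:4) for (b in 0:(4 - a)) {
        expect_length(enumerateRegioisomers(a, b), .bruteCount(a, b))
    }
    expect_error(enumerateRegioisomers(3, 2), "4 positions")
})

test_that("enumeration order is deterministic and structures distinct", {
    r1 <- vapply(enumerateRegioisomers(2, 1), quinateDescriptor,
                 character(1))
    r2 <- vapply(enumerateRegioisomers(2, 1), quinateDescriptor,
                 character(1))
    expect_identical(r1, r2)
    expect_identical(anyDuplicated(r1), 0L)
    expect_identical(r1, sort(r1))
})

test_that("catechol counting follows caffeoyl and B-ring rules", {
    mdicqas <- enumerateRegioisomers(2, 1)
    expect_true(all(vapply(mdicqas, catecholCount, integer(1)) == 2L))
    expect_identical(catecholCount(flavonoidGlycoside("kaempferol", 3,
                                                      "6''")), 0L)
    expect_identical(catecholCount(flavonoidGlycoside("quercetin", 3,
                                                      "6''")), 1L)
    expect_identical(catecholCount(acylQuinate()), 0L)
})

test_that("descriptor strings round-trip through the parser", {
    descs <- c("QA[1:caf,3:mal,5:caf]", "epiQA[3:caf,4:mal,5:caf]",
               "QA[]", "QA[1:caf,3:mal,4:mal,5:caf]")
    for (d in descs)
        expect_identical(quinateDescriptor(parseDescriptor(d)), d)
    gd <- c("QCT-3-Glc[6'':mal]", "LUT-7-Glc[2'':mal,6'':mal]",
            "KMP-3-Glc[6'':mal]")
    for (d in gd)
        expect_identical(glycosideDescriptor(parseDescriptor(d)), d)
    expect_error(parseDescriptor("XX[1:caf]"), "parse")
})

test_that("the compound registry reproduces the printed panel properties", {
    k <- knownCompounds()
    expect_identical(nrow(k), 9L)
    expect_equal(round(k$mzNeg[k$id == "cpd4"], 4), 601.1199)
    expect_equal(round(k$mzNeg[k$id == "cpd9"], 4), 687.1203)
    expect_equal(round(k$mzNeg[k$id == "cpd8"], 4), 619.0941)
    # only the kaempferol glycoside is catechol-free
    expect_identical(k$id[k$catechols == 0L], "cpd3")
})
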