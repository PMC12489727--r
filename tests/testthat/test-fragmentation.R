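# Exhaustive oracle for the acyl-quinate grammar: enumerate every multiset
# of losses within the budget (order-free), apply the subtraction when
# contained, deduplicate by formula.
.bruteQuinateFragments <- function(desc, maxDepth) {
    s <- parseDescriptor(desc)
    nMal <- sum(s@substituents == "mal")
    nCaf <- sum(s@substituents == "caf")
    counts <- expand.grid(mal = 0:nMal, caf = 0:nCaf, co2 = 0:1, h2o = 0:1)
    counts <- counts[rowSums(counts) <= maxDepth, , drop = FALSE]
    root <- neutralFormula(s)
    keys <- character(0)
    for (i in seq_len(nrow(counts))) {
        loss <- parseFormula("")
        for (nm in c(rep("C3H2O3", counts$mal[i]),
                     rep("C9H6O3", counts$caf[i]),
                     rep("CO2", counts$co2[i]),
                     rep("H2O", counts$h2o[i])))
            loss <- formulaAdd(loss, nm)
        rem <- tryCatch(formulaSubtract(root, loss),
                        error = function(e) NULL)
        if (!is.null(rem))
            keys <- c(keys, formulaString(rem))
    }
    sort(unique(keys))
}

test_that("the MDiCQA fragment tree contains all printed nominal ions", {
    fr <- generateFragments("QA[1:caf,3:mal,5:caf]", maxDepth = 3)
    expect_true(all(c(515, 439, 353, 557, 395, 377, 233, 191, 179, 173)
                    %in% fr$nominal))
})

test_that("the dimalonyl tree and the glycoside trees cover printed ions", {
    fr9 <- generateFragments("QA[1:caf,3:mal,4:mal,5:caf]", maxDepth = 1)
    expect_true(all(c(601, 525) %in% fr9$nominal))
    fr1 <- generateFragments("QCT-3-Glc[6'':mal]", maxDepth = 2)
    expect_true(all(c(463, 301) %in% fr1$nominal))
    # demalonylation-first series of the dimalonyl glucoside: 619->533->447
    fr8 <- generateFragments("LUT-7-Glc[2'':mal,6'':mal]", maxDepth = 3)
    expect_true(all(c(619, 533, 447, 285) %in% fr8$nominal))
})

test_that("depth 0 yields the precursor only; deeper sets are supersets", {
    fr0 <- generateFragments("QA[1:caf,3:mal,5:caf]", maxDepth = 0)
    expect_identical(nrow(fr0), 1L)
    expect_identical(fr0$path, "")
    prev <- fr0$formula
    for (d in 1:4) {
        cur <- generateFragments("QA[1:caf,3:mal,5:caf]", d)$formula
        expect_true(all(prev %in% cur))
        prev <- cur
    }
    expect_error(generateFragments("QA[1:caf,3:mal,5:caf]", -1), ">= 0")
})

test_that("every node conserves mass along its loss path", {
    losses <- neutralLosses()
    lm <- setNames(losses$mass, losses$label)
    fr <- generateFragments("QA[1:caf,3:mal,4:mal,5:caf]", maxDepth = 4)
    prec <- mzIon("C31H28O18", "negative")
    real <- fr[!fr$marker, ]
    for (i in seq_len(nrow(real))) {
        labs <- strsplit(real$path[i], ">", fixed = TRUE)[[1]]
        expect_equal(real$mz[i], prec - sum(lm[labs]), tolerance = 1e-6)
    }
})

test_that("grammar output equals the exhaustive loss-multiset oracle", {
    fr <- generateFragments("QA[1:caf,3:mal,5:caf]", maxDepth = 5)
    expect_identical(sort(unique(fr$formula[!fr$marker])),
                     .bruteQuinateFragments("QA[1:caf,3:mal,5:caf]", 5))
})

test_that("the nominal fragment set is identical across all 12 regioisomers", {
    sets <- lapply(enumerateRegioisomers(2, 1), function(s)
        sort(unique(generateFragments(s, maxDepth = 4)$nominal)))
    for (i in 2:12)
        expect_identical(sets[[i]], sets[[1]])
})

test_that("glucosyl loss fires only after sugar demalonylation", {
    fr <- generateFragments("LUT-7-Glc[2'':mal,6'':mal]", maxDepth = 3)
    paths <- strsplit(fr$path[!fr$marker], ">", fixed = TRUE)
    for (p in paths) {
        g <- which(p == "glucosyl_residue")
        if (length(g))
            expect_identical(sum(p[seq_len(g - 1)] == "malonyl_residue"), 2L)
    }
    # aglycone (luteolin - H, nominal 285) is reachable
    expect_true(285 %in% fr$nominal)
})

test_that("peak annotation matches within tolerance and leaves the rest NA", {
    nodes <- generateFragments("QA[1:caf,3:mal,5:caf]", maxDepth = 3)
    node515 <- nodes$mz[nodes$nominal == 515][1]
    sp <- massSpectrum(c(node515 * (1 + 0.2e-6), 500.0),
                       c(100, 10), precursorMz = 601.12,
                       collisionEnergy = 25)
    ann <- annotatePeaks(sp, nodes, tolPpm = 5)
    matched <- ann[!is.na(ann$matchedFormula), ]
    expect_identical(nrow(matched), 1L)
    expect_equal(matched$ppm, 0.2, tolerance = 0.05)
    expect_true(is.na(ann$matchedFormula[ann$mz == 500.0]))
    # empty spectrum -> empty annotation list
    empty <- massSpectrum(numeric(0), numeric(0))
    expect_identical(nrow(annotatePeaks(empty, nodes)), 0L)
    # empty node set -> all peaks unannotated, no error
    ann0 <- annotatePeaks(sp, nodes[0, ], tolPpm = 5)
    expect_true(all(is.na(ann0$matchedFormula)))
    expect_error(annotatePeaks(sp, nodes, tolPpm = 0), "tolPpm")
})

test_that("explainLoss recovers the printed loss assignments", {
    e <- explainLoss(601.12, 515.12)
    expect_identical(e$losses[1], "malonyl_residue")
    e <- explainLoss(601.12, 557.13)
    expect_identical(e$losses[1], "CO2")
    e <- explainLoss(601.12, 601.12)
    expect_identical(e$losses[1], "")
    # caffeoyl (162.0317) vs glucosyl (162.0528) separate at 10 mDa
    e <- explainLoss(601.1199, 601.1199 - 162.0317)
    expect_identical(e$losses[1], "caffeoyl_residue")
    expect_false("glucosyl_residue" %in% e$losses)
    expect_error(explainLoss(100, 200), ">=")
})
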