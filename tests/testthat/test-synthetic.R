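test_that("zero-noise spectra reproduce template fractions exactly", {
    tpl <- spectrumTemplates()
    sp <- genMSMS(tpl[["cpd7_45"]])
    expect_equal(keyIntensity(sp, 173), 0.40, tolerance = 1e-12)
    expect_equal(keyIntensity(sp, 233), 0.30, tolerance = 1e-12)
    for (nm in names(tpl)) {
        sp <- genMSMS(tpl[[nm]])
        fr <- tpl[[nm]]$fractions
        expect_equal(sum(sp@intensity), 1, tolerance = 1e-12)
        for (ion in names(fr))
            expect_equal(keyIntensity(sp, as.integer(ion)),
                         unname(fr[[ion]]), tolerance = 1e-12)
    }
})

test_that("all generators are deterministic in the seed", {
    tpl <- spectrumTemplates()[["cpd4_25"]]
    nm <- noiseModel(3, 0.05, 5, seed = 42)
    a <- genMSMS(tpl, nm)
    b <- genMSMS(tpl, nm)
    expect_identical(a@mz, b@mz)
    expect_identical(a@intensity, b@intensity)
    c <- genMSMS(tpl, noiseModel(3, 0.05, 5, seed = 43))
    expect_false(identical(a@mz, c@mz))
    o1 <- genMS1Oxidation("QA[1:caf,3:mal,5:caf]", "water",
                          noiseModel(2, 0.1, seed = 7))
    o2 <- genMS1Oxidation("QA[1:caf,3:mal,5:caf]", "water",
                          noiseModel(2, 0.1, seed = 7))
    expect_identical(o1, o2)
    d1 <- genDoseResponse(10, sigma = 3, seed = 5)
    d2 <- genDoseResponse(10, sigma = 3, seed = 5)
    expect_identical(d1, d2)
    t1 <- genTissueTable(data.frame(organ = "leaf", phase = "BVC",
                                    mean = 5), 3, 0.2, seed = 9)
    t2 <- genTissueTable(data.frame(organ = "leaf", phase = "BVC",
                                    mean = 5), 3, 0.2, seed = 9)
    expect_identical(t1, t2)
})

test_that("generators leave the global RNG stream untouched", {
    set.seed(123)
    before <- .Random.seed
    invisible(genMSMS(spectrumTemplates()[["cpd4_25"]],
                      noiseModel(3, 0.05, 2, seed = 1)))
    expect_identical(.Random.seed, before)
})

test_that("decoy peaks avoid the key-ion windows", {
    sp <- genMSMS(spectrumTemplates()[["cpd4_25"]],
                  noiseModel(0, 0, 50, seed = 11))
    decoys <- setdiff(round(sp@mz, 6),
                      round(genMSMS(spectrumTemplates()[["cpd4_25"]])@mz, 6))
    for (key in c(173, 233, 395))
        expect_true(all(abs(decoys - key) > 0.5))
})

test_that("zero-sigma dose-response equals the 4PL closed form", {
    d <- genDoseResponse(ic50 = 12, hill = 2, bottom = 5, top = 95,
                         sigma = 0)
    mu <- 5 + 90 / (1 + exp(-2 * (log(d$dose) - log(12))))
    expect_equal(d$response, mu, tolerance = 1e-12)
})

test_that("tissue generator recovers the generating organ contrast", {
    prof <- data.frame(organ = c("inflorescence", "leaf"),
                       phase = "flowering", mean = c(10, 1))
    tab <- genTissueTable(prof, nPerCell = 5, cv = 0, seed = 1)
    s <- summarizeTissues(tab, "cpdX")
    expect_equal(s$foldDifference, 10, tolerance = 1e-12)
    # cv = 0 gives exact cell means; n = 0 gives the empty-table error path
    expect_true(all(tab$mg_per_g %in% c(10, 1)))
    empty <- genTissueTable(prof, nPerCell = 0, cv = 0, seed = 1)
    expect_identical(nrow(empty), 0L)
    expect_error(summarizeTissues(empty, "cpdX"), "no records")
})

test_that("end-to-end: the key classifies every zero-noise template", {
    tpl <- spectrumTemplates()
    for (iso in c("cpd4", "cpd5", "cpd6", "cpd7")) {
        call <- classifyIsomer(genMSMS(tpl[[paste0(iso, "_25")]]),
                               genMSMS(tpl[[paste0(iso, "_45")]]))
        expect_identical(call@label, iso)
    }
})

test_that("doses far below the IC50 feed the censoring path downstream", {
    d <- genDoseResponse(ic50 = 1e4, doses = 2^(0:7), sigma = 0)
    expect_lt(max(d$response), 50)
    expect_identical(fitIC50(d$dose, d$response)@status,
                     "censored_above_max")
})
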