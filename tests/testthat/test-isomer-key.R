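# Build a minimal key spectrum from nominal-ion TIC fractions; leftover
# mass goes to a background ion at nominal 439.
.keySpec <- function(fracs, ce) {
    mz <- c("173" = 173.0455, "233" = 233.0667, "395" = 395.0984,
            "439" = 439.0882)
    resid <- 1 - sum(fracs)
    int <- c(fracs, if (resid > 0) c("439" = resid))
    massSpectrum(unname(mz[names(int)]), unname(int),
                 precursorMz = 601.1199, collisionEnergy = ce)
}

test_that("keyIntensity sums TIC fractions of a nominal bin", {
    sp <- massSpectrum(233.07, 0.70, precursorMz = 601.12,
                       collisionEnergy = 25)
    expect_equal(keyIntensity(sp, 233), 1)  # single peak: whole TIC
    sp2 <- .keySpec(c("233" = 0.70), 25)
    expect_equal(keyIntensity(sp2, 233), 0.70, tolerance = 1e-12)
    # two peaks rounding to the same nominal are summed
    sp3 <- massSpectrum(c(394.9, 395.2, 233.07), c(0.2, 0.15, 0.65),
                        precursorMz = 601.12, collisionEnergy = 25)
    expect_equal(keyIntensity(sp3, 395), 0.35, tolerance = 1e-12)
    expect_identical(keyIntensity(massSpectrum(numeric(0), numeric(0)),
                                  233), 0)
})

test_that("stage 1 reproduces the printed 25 eV patterns", {
    expect_identical(as.character(classifyStage1(
        .keySpec(c("233" = 0.70, "395" = 0.02), 25))), "group_4_or_7")
    expect_identical(as.character(classifyStage1(
        .keySpec(c("395" = 0.35, "233" = 0.01), 25))), "cpd5")
    expect_identical(as.character(classifyStage1(
        .keySpec(c("395" = 0.30, "233" = 0.35), 25))), "cpd6")
    expect_identical(as.character(classifyStage1(
        .keySpec(c("233" = 0.10, "395" = 0.10), 25))), "inconclusive")
    expect_error(classifyStage1(.keySpec(c("233" = 0.7), 45)), "25")
})

test_that("stage 2 separates 4 and 7 by the I173/I233 ratio", {
    s <- classifyStage2(.keySpec(c("173" = 0.40, "233" = 0.30), 45))
    expect_identical(as.character(s), "cpd7")
    expect_equal(attr(s, "ratio"), 4 / 3, tolerance = 1e-9)
    s <- classifyStage2(.keySpec(c("173" = 0.08, "233" = 0.30), 45))
    expect_identical(as.character(s), "cpd4")
    expect_equal(attr(s, "ratio"), 8 / 30, tolerance = 1e-9)
    # dead band between 0.5 and 0.7
    expect_identical(as.character(classifyStage2(
        .keySpec(c("173" = 0.18, "233" = 0.30), 45))), "inconclusive")
    expect_error(classifyStage2(.keySpec(c("173" = 0.4), 45)),
                 "denominator")
})

test_that("stage 2 is invariant to intensity units", {
    frac <- .keySpec(c("173" = 0.40, "233" = 0.30), 45)
    counts <- massSpectrum(frac@mz, frac@intensity * 1.7e6,
                           precursorMz = 601.1199, collisionEnergy = 45)
    expect_identical(as.character(classifyStage2(frac)),
                     as.character(classifyStage2(counts)))
})

test_that("the full key assigns all four isomers from zero-noise templates", {
    tpl <- spectrumTemplates()
    for (iso in c("cpd4", "cpd5", "cpd6", "cpd7")) {
        s25 <- genMSMS(tpl[[paste0(iso, "_25")]])
        s45 <- genMSMS(tpl[[paste0(iso, "_45")]])
        call <- classifyIsomer(s25, s45)
        expect_identical(call@label, iso)
        expect_identical(call@confidence, "high")
    }
})

test_that("stage 1 alone resolves cpd5; missing 45 eV leaves the 4/7 group", {
    tpl <- spectrumTemplates()
    call5 <- classifyIsomer(genMSMS(tpl[["cpd5_25"]]))
    expect_identical(call5@label, "cpd5")
    call47 <- classifyIsomer(genMSMS(tpl[["cpd4_25"]]))
    expect_identical(call47@label, "group_4_or_7")
    expect_identical(call47@confidence, "low")
    expect_true(is.na(call47@stage2Ratio))
})

test_that("decisions are invariant to a common intensity scale factor", {
    tpl <- spectrumTemplates()
    for (iso in c("cpd4", "cpd5", "cpd6", "cpd7")) {
        s25 <- genMSMS(tpl[[paste0(iso, "_25")]])
        s45 <- genMSMS(tpl[[paste0(iso, "_45")]])
        ref <- classifyIsomer(s25, s45)@label
        for (scale in c(0.8, 1.0, 1.2)) {
            t25 <- massSpectrum(s25@mz, s25@intensity * scale,
                                precursorMz = s25@precursorMz,
                                collisionEnergy = 25)
            t45 <- massSpectrum(s45@mz, s45@intensity * scale,
                                precursorMz = s45@precursorMz,
                                collisionEnergy = 45)
            expect_identical(classifyIsomer(t25, t45)@label, ref)
        }
    }
})
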