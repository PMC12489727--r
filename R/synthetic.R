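# Seeded generators for every input the pipeline consumes. All are pure
# functions of (parameters, seed): the global RNG state is saved and
# restored around each draw.

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old))
            suppressWarnings(rm(".Random.seed", envir = globalenv()))
        else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Exact negative-mode fragment m/z of the MDiCQA tree, keyed by nominal;
# memoised, the tree is static.
.pkgCache <- new.env(parent = emptyenv())

.mdicqaIonMz <- function() {
    if (is.null(.pkgCache$mdicqaIonMz)) {
        fr <- generateFragments("QA[1:caf,3:mal,5:caf]", maxDepth = 4L)
        .pkgCache$mdicqaIonMz <- setNames(fr$mz, as.character(fr$nominal))
    }
    .pkgCache$mdicqaIonMz
}

#' Noise model for spectrum generation
#'
#' @param mzJitterPpm Gaussian m/z jitter, ppm standard deviation.
#' @param intensityCv Relative standard deviation of multiplicative
#'   lognormal intensity noise (mean-preserving).
#' @param nDecoyPeaks Number of uniform decoy peaks over [150, precursor];
#'   decoys are never placed within 0.5 Da of the key ions 173/233/395 so
#'   that noise-robustness results stay interpretable.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class \code{"NoiseModel"}.
#' @export
noiseModel <- function(mzJitterPpm = 0, intensityCv = 0, nDecoyPeaks = 0L,
                       seed = 1L) {
    stopifnot(mzJitterPpm >= 0, intensityCv >= 0, nDecoyPeaks >= 0)
    structure(list(mzJitterPpm = mzJitterPpm, intensityCv = intensityCv,
                   nDecoyPeaks = as.integer(nDecoyPeaks),
                   seed = as.integer(seed)),
              class = "NoiseModel")
}

#' CID fragment-intensity templates of the four MDiCQA isomers
#'
#' Encodes the diagnostic TIC fractions of the key ions (nominal m/z 173,
#' 233, 395) per isomer and collision energy: ~70% at m/z 233 for compounds
#' 4 and 7 at 25 eV; ~35% at m/z 395 (233 in traces) for compound 5; ~30%
#' and ~35% for compound 6; 40%/30% (compound 7) and 8%/30% (compound 4)
#' for 173/233 at 45 eV. The residual TIC mass is spread uniformly over the
#' non-key background fragments (557, 515, 439, 377, 353, 191, 179). The
#' 45 eV entries for compounds 5 and 6 are synthetic placeholders (no
#' printed values exist); the decision key never consults them, since
#' stage 1 at 25 eV already separates those two isomers.
#'
#' @return Named list of templates \code{cpd4_25 ... cpd7_45}; each is a
#'   list with \code{isomer}, \code{collisionEnergy}, \code{fractions}
#'   (named by nominal m/z, summing to 1) and \code{precursorMz}.
#' @export
spectrumTemplates <- function() {
    key <- list(
        cpd4_25 = c("233" = 0.70, "395" = 0.02),
        cpd7_25 = c("233" = 0.70, "395" = 0.02),
        cpd5_25 = c("395" = 0.35, "233" = 0.01),
        cpd6_25 = c("233" = 0.35, "395" = 0.30),
        cpd4_45 = c("173" = 0.08, "233" = 0.30, "395" = 0.02),
        cpd7_45 = c("173" = 0.40, "233" = 0.30, "395" = 0.02),
        cpd5_45 = c("173" = 0.20, "233" = 0.10, "395" = 0.15),  # placeholder
        cpd6_45 = c("173" = 0.25, "233" = 0.25, "395" = 0.10))  # placeholder
    background <- c("557", "515", "439", "377", "353", "191", "179")
    prec <- mzIon("C28H26O15", "negative")
    out <- lapply(names(key), function(nm) {
        kf <- key[[nm]]
        resid <- 1 - sum(kf)
        fr <- c(kf, setNames(rep(resid / length(background),
                                 length(background)), background))
        parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
        list(isomer = parts[1],
             collisionEnergy = as.numeric(parts[2]),
             fractions = fr, precursorMz = prec)
    })
    names(out) <- names(key)
    out
}

#' Generate a synthetic MS/MS spectrum from an intensity template
#'
#' Places each template ion at its exact theoretical m/z, perturbs m/z by
#' Gaussian ppm jitter and intensities by mean-preserving lognormal noise,
#' and optionally adds uniform decoy peaks. With zero noise the TIC
#' fractions reproduce the template exactly.
#'
#' @param template One element of [spectrumTemplates()].
#' @param noise A [noiseModel()].
#' @return A negative-mode [MassSpectrum-class].
#' @export
genMSMS <- function(template, noise = noiseModel()) {
    ionMz <- .mdicqaIonMz()
    fr <- template$fractions
    mz0 <- unname(ionMz[names(fr)])
    if (anyNA(mz0))
        stop("template ion not present in the MDiCQA fragment tree: ",
             paste(names(fr)[is.na(mz0)], collapse = ", "))
    .withSeed(noise$seed, {
        mz <- mz0 * (1 + stats::rnorm(length(mz0), 0,
                                      noise$mzJitterPpm) * 1e-6)
        int <- unname(fr)
        if (noise$intensityCv > 0) {
            sdl <- sqrt(log(1 + noise$intensityCv^2))
            int <- int * stats::rlnorm(length(int), -sdl^2 / 2, sdl)
        }
        if (noise$nDecoyPeaks > 0L) {
            keyMz <- as.numeric(c(173, 233, 395))
            dmz <- numeric(0)
            while (length(dmz) < noise$nDecoyPeaks) {
                cand <- stats::runif(noise$nDecoyPeaks, 150,
                                     template$precursorMz)
                ok <- vapply(cand, function(m)
                    all(abs(m - keyMz) > 0.5), logical(1))
                dmz <- c(dmz, cand[ok])
            }
            dmz <- dmz[seq_len(noise$nDecoyPeaks)]
            dint <- stats::rlnorm(noise$nDecoyPeaks, log(0.005), 0.5)
            mz <- c(mz, dmz)
            int <- c(int, dint)
        }
        massSpectrum(mz, int, precursorMz = template$precursorMz,
                     collisionEnergy = template$collisionEnergy,
                     polarity = "negative",
                     title = sprintf("%s CE=%g", template$isomer,
                                     template$collisionEnergy))
    })
}

# Satellite intensities relative to the intact species, per eluent preset.
# formic_0.1 uses the midpoints of the reported 5-10% (-4H) and 30-90%
# (-2H) relative-intensity ranges; water encodes the reported inversion
# (doubly oxidized dominant, intact ~10%, singly oxidized ~30%);
# formic_0.3 suppresses satellites below the 0.1% levels.
.oxidationPresets <- list(
    formic_0.1 = c(base = 100, ox1 = 60, ox2 = 7.5),
    formic_0.3 = c(base = 100, ox1 = 15, ox2 = 2),
    water      = c(base = 10, ox1 = 30, ox2 = 100))

#' Generate a synthetic MS1 peak list with oxidation satellites
#'
#' Emits the deprotonated molecule of \code{structure} plus -2H/-4H
#' in-source oxidation satellites whose relative intensities follow an
#' eluent-condition preset. Structures without catechols get no
#' satellites; with a single catechol only the -2H satellite appears.
#'
#' @param structure Structure descriptor (object or string).
#' @param eluentPreset \code{"formic_0.1"} (0.1% formic acid, intact ion
#'   dominant), \code{"formic_0.3"} (satellites further suppressed) or
#'   \code{"water"} (doubly oxidized dominant).
#' @param noise A [noiseModel()].
#' @return Two-column matrix (mz, intensity).
#' @examples
#' genMS1Oxidation("QA[1:caf,3:mal,5:caf]", "water")
#' @export
genMS1Oxidation <- function(structure,
                            eluentPreset = c("formic_0.1", "formic_0.3",
                                             "water"),
                            noise = noiseModel()) {
    eluentPreset <- match.arg(eluentPreset)
    s <- parseDescriptor(structure)
    nCat <- catecholCount(s)
    baseMz <- mzIon(neutralFormula(s), "negative")
    p <- .oxidationPresets[[eluentPreset]]
    states <- 0:min(2L, nCat)
    int <- p[c("base", "ox1", "ox2")[states + 1L]]
    mz <- baseMz - states * 2 * .isotopeMasses[["H"]]
    .withSeed(noise$seed, {
        if (noise$mzJitterPpm > 0)
            mz <- mz * (1 + stats::rnorm(length(mz), 0,
                                         noise$mzJitterPpm) * 1e-6)
        if (noise$intensityCv > 0) {
            sdl <- sqrt(log(1 + noise$intensityCv^2))
            int <- int * stats::rlnorm(length(int), -sdl^2 / 2, sdl)
        }
        cbind(mz = mz, intensity = unname(int))
    })
}

#' Generate a synthetic dose-response table
#'
#' 4PL mean curve plus Gaussian noise on the response scale.
#'
#' @param ic50 True IC50 (> 0).
#' @param hill Hill slope.
#' @param bottom,top Response asymptotes (percent).
#' @param doses Concentration vector (> 0); default 8 two-fold steps
#'   centred on the IC50.
#' @param nReplicates Parallel measurements per dose (default 4, the usual
#'   plate-assay design).
#' @param sigma Gaussian noise standard deviation, percentage points.
#' @param seed Integer seed.
#' @return data.frame with columns \code{dose}, \code{response} and
#'   \code{replicate}.
#' @export
genDoseResponse <- function(ic50, hill = 1, bottom = 0, top = 100,
                            doses = ic50 * 2^seq(-3.5, 3.5, by = 1),
                            nReplicates = 4L, sigma = 0, seed = 1L) {
    stopifnot(ic50 > 0, all(doses > 0), sigma >= 0, nReplicates >= 1)
    dose <- rep(doses, each = as.integer(nReplicates))
    repl <- rep(seq_len(nReplicates), times = length(doses))
    mu <- bottom + (top - bottom) /
        (1 + exp(-hill * (log(dose) - log(ic50))))
    .withSeed(seed, {
        data.frame(dose = dose,
                   response = mu + stats::rnorm(length(dose), 0, sigma),
                   replicate = repl)
    })
}

#' Generate a synthetic tissue-abundance table
#'
#' Lognormal (mean-preserving) concentration draws per organ x phase cell.
#'
#' @param profile data.frame with columns \code{organ}, \code{phase},
#'   \code{mean} (mg/g, >= 0) and optionally \code{species} and
#'   \code{compound} (defaults \code{"synthetic"} / \code{"cpdX"}).
#' @param nPerCell Records per cell (0 gives an empty table).
#' @param cv Relative standard deviation of the draws (0 = exact means).
#' @param seed Integer seed.
#' @return data.frame with columns \code{species}, \code{organ},
#'   \code{phase}, \code{compound}, \code{mg_per_g}.
#' @export
genTissueTable <- function(profile, nPerCell = 3L, cv = 0.2, seed = 1L) {
    stopifnot(all(c("organ", "phase", "mean") %in% names(profile)),
              all(profile$mean >= 0), cv >= 0, nPerCell >= 0)
    if (is.null(profile$species))
        profile$species <- "synthetic"
    if (is.null(profile$compound))
        profile$compound <- "cpdX"
    .withSeed(seed, {
        rows <- lapply(seq_len(nrow(profile)), function(i) {
            n <- as.integer(nPerCell)
            if (!n)
                return(NULL)
            m <- profile$mean[i]
            val <- if (cv > 0 && m > 0) {
                sdl <- sqrt(log(1 + cv^2))
                m * stats::rlnorm(n, -sdl^2 / 2, sdl)
            } else rep(m, n)
            data.frame(species = profile$species[i],
                       organ = profile$organ[i],
                       phase = profile$phase[i],
                       compound = profile$compound[i],
                       mg_per_g = val, stringsAsFactors = FALSE)
        })
        rows <- Filter(Negate(is.null), rows)
        out <- if (length(rows))
            do.call(rbind, c(rows, list(make.row.names = FALSE)))
        else NULL
        if (is.null(out))
            out <- data.frame(species = character(0), organ = character(0),
                              phase = character(0), compound = character(0),
                              mg_per_g = numeric(0))
        out
    })
}
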