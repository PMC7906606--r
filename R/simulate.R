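#' Default kinetic panel for the synthetic generator
#'
#' Twelve galactolipid molecular species (six MGDG, six DGDG, covering
#' both biosynthetic routes) and the three marker subunits, each with a
#' four-parameter-logistic kinetic law: amount(t) = baseline +
#' amplitude / (1 + exp((onset - t) / timescale)). Class defaults place
#' the ER-pathway lipid rise around 10 h (the leap between 8 and 12 h),
#' the plastid-pathway rise around 30 h (after 24 h), and protein onset
#' sequentially (PsbA before PsaC). Baselines and amplitudes are chosen
#' so the noise-free totals resemble the measured seedling scale:
#' about 0.3 nmol total galactolipid in the dark, about 2.2 nmol at 96 h,
#' MGDG/DGDG near 3 at 96 h, and subunit amounts in the 1e-5 to 1e-3 nmol
#' range.
#'
#' @return data.frame with columns \code{analyte}, \code{class},
#'   \code{baseline}, \code{amplitude} (nmol/seedling), \code{onset},
#'   \code{timescale} (hours).
#' @export
defaultKinetics <- function() {
    rbind(
        data.frame(analyte = c("MGDG 18:3/18:3", "MGDG 18:3/18:2",
                               "DGDG 18:3/18:3", "DGDG 18:3/18:2"),
                   class = "ER_lipid",
                   baseline = c(0.14, 0.02, 0.07, 0.01),
                   amplitude = c(0.26, 0.04, 0.18, 0.02),
                   onset = 10, timescale = 2),
        data.frame(analyte = c("MGDG 18:3/16:3", "MGDG 18:3/16:1",
                               "MGDG 18:3/16:0", "MGDG 18:2/16:0",
                               "DGDG 18:3/16:0", "DGDG 18:3/16:1",
                               "DGDG 18:3/16:3", "DGDG 18:2/16:0"),
                   class = "PL_lipid",
                   baseline = c(0.030, 0.005, 0.004, 0.001,
                                0.012, 0.004, 0.003, 0.001),
                   amplitude = c(0.870, 0.145, 0.090, 0.050,
                                 0.168, 0.036, 0.027, 0.019),
                   onset = 30, timescale = 4),
        data.frame(analyte = "PsbA", class = "early_protein",
                   baseline = 6.9e-6, amplitude = 6.1e-4,
                   onset = 6, timescale = 3),
        data.frame(analyte = c("PetC", "PsaC"), class = "late_protein",
                   baseline = c(2.6e-5, 1.0e-6),
                   amplitude = c(7.6e-4, 2.3e-4),
                   onset = 12, timescale = 4))
}

#' Build and validate a simulation configuration
#'
#' Assembles the configuration driving [simulateTimecourse()]: the
#' sampling design (time points, replicates, seed), the per-analyte
#' kinetic laws, the replicate-noise model, and the morphometric forward
#' model that converts the noise-free molecular surface back into a
#' per-chloroplast table.
#'
#' @param timePoints Strictly increasing sampling times (hours); default
#'   the eight-point de-etiolation design 0, 4, 8, 12, 24, 48, 72, 96.
#' @param nReplicates Replicates per time point (default 3).
#' @param seed Integer RNG seed; the same seed and configuration give
#'   bit-identical output tables.
#' @param kinetics Kinetic table as from [defaultKinetics()].
#' @param noiseModel \code{"lognormal"} (multiplicative, mean-preserving;
#'   the default, since amounts are positive and dispersions scale with
#'   the mean) or \code{"gaussian"} (additive, truncated at 0).
#' @param cv Replicate coefficient of variation (default 0.15, inside
#'   the 10--30 percent range of the reference dispersions).
#' @param chloroplastsPerCell data.frame (\code{time_h}, \code{value})
#'   interpolated over the time points; default the measured trajectory
#'   22, 25, 26, 112 at 0, 4, 24, 96 h.
#' @param cellsPerSeedling Cells per seedling (default 3000).
#' @param granaPercent Grana surface percentage used when emitting the
#'   morphometric table (default 0).
#' @param envelopeRatios Thylakoid/envelope ratio table for the forward
#'   model and its inversion; default [referenceEnvelopeRatios()].
#' @param epsilon Unquantified-component surface added to the
#'   morphometric forward model, scalar or per time point
#'   (\eqn{\mu m^2}/seedling; default 0).
#' @return A validated list of class \code{"thylakoidSimConfig"}.
#' @examples
#' cfg <- simulationConfig(seed = 1, cv = 0)
#' @export
simulationConfig <- function(timePoints = c(0, 4, 8, 12, 24, 48, 72, 96),
                             nReplicates = 3, seed = 1,
                             kinetics = defaultKinetics(),
                             noiseModel = c("lognormal", "gaussian"),
                             cv = 0.15,
                             chloroplastsPerCell = data.frame(
                                 time_h = c(0, 4, 24, 96),
                                 value = c(22, 25, 26, 112)),
                             cellsPerSeedling = 3000,
                             granaPercent = 0,
                             envelopeRatios = referenceEnvelopeRatios(),
                             epsilon = 0) {
    noiseModel <- match.arg(noiseModel)
    if (length(timePoints) < 2 || any(diff(timePoints) <= 0))
        stop("timePoints must be strictly increasing", call. = FALSE)
    if (nReplicates < 1 || nReplicates != round(nReplicates))
        stop("nReplicates must be a positive integer", call. = FALSE)
    if (cv < 0)
        stop("cv must be >= 0", call. = FALSE)
    need <- c("analyte", "class", "baseline", "amplitude", "onset",
              "timescale")
    if (!all(need %in% colnames(kinetics)))
        stop("kinetics needs columns ", paste(need, collapse = ", "),
             call. = FALSE)
    if (any(kinetics$timescale <= 0))
        stop("kinetic timescales must be > 0", call. = FALSE)
    if (any(kinetics$baseline < 0) || any(kinetics$amplitude < 0))
        stop("baselines and amplitudes must be >= 0", call. = FALSE)
    badClass <- setdiff(kinetics$class,
                        c("ER_lipid", "PL_lipid", "early_protein",
                          "late_protein"))
    if (length(badClass))
        stop("unknown kinetic class: ", paste(badClass, collapse = ", "),
             call. = FALSE)
    if (anyDuplicated(kinetics$analyte))
        stop("duplicated analyte in kinetics", call. = FALSE)
    structure(list(
        timePoints = timePoints, nReplicates = as.integer(nReplicates),
        seed = as.integer(seed), kinetics = kinetics,
        noise = list(model = noiseModel, cv = cv),
        morpho = list(chloroplastsPerCell = chloroplastsPerCell,
                      cellsPerSeedling = cellsPerSeedling,
                      granaPercent = granaPercent,
                      envelopeRatios = envelopeRatios,
                      epsilon = epsilon)),
        class = "thylakoidSimConfig")
}

.kineticLaw <- function(kinetics, t) {
    out <- vapply(t, function(tt)
        kinetics$baseline + kinetics$amplitude /
            (1 + exp((kinetics$onset - tt) / kinetics$timescale)),
        numeric(nrow(kinetics)))
    matrix(out, nrow = nrow(kinetics),
           dimnames = list(kinetics$analyte, as.character(t)))
}

#' Simulate a de-etiolation time-course dataset
#'
#' Draws a complete synthetic dataset with the statistical structure the
#' analysis expects: a long-format amount table (every analyte at every
#' time point and replicate, 4PL kinetic laws with multiplicative
#' replicate noise), a morphometric table produced by running the
#' molecular surface model forward on the noise-free truth and dividing
#' the per-seedling surface back through the chloroplast-per-cell and
#' cell-per-seedling factors, and a truth record holding every
#' generating parameter (so recovery tests never re-derive truth from
#' the output).
#'
#' @param config A configuration from [simulationConfig()].
#' @return List with elements \code{amounts} (an
#'   \linkS4class{AnalyteExperiment}), \code{morpho} (data.frame), and
#'   \code{truth} (list: \code{config}, \code{kinetics},
#'   \code{amounts} analyte x time matrix of noise-free values,
#'   \code{surface} the noise-free \linkS4class{SurfaceBreakdown},
#'   \code{surfaceAsymptote} in \eqn{\mu m^2}/seedling).
#' @examples
#' sim <- simulateTimecourse(simulationConfig(seed = 7, cv = 0))
#' surfaceTotal(sim$truth$surface)
#' @export
simulateTimecourse <- function(config) {
    if (!inherits(config, "thylakoidSimConfig"))
        stop("config must come from simulationConfig()", call. = FALSE)
    tp <- config$timePoints
    kin <- config$kinetics
    truthAmounts <- .kineticLaw(kin, tp)

    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(oldSeed))
        assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(config$seed)

    cv <- config$noise$cv
    rows <- expand.grid(analyte = kin$analyte, time_h = tp,
                        replicate = seq_len(config$nReplicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- truthAmounts[cbind(match(rows$analyte, rownames(truthAmounts)),
                             match(rows$time_h, tp))]
    amount <- if (cv == 0) {
        mu
    } else if (config$noise$model == "lognormal") {
        sdlog <- sqrt(log1p(cv^2))
        mu * exp(stats::rnorm(nrow(rows), -sdlog^2 / 2, sdlog))
    } else {
        pmax(mu + stats::rnorm(nrow(rows), 0, cv * mu), 0)
    }
    rows$amount <- amount
    ae <- AnalyteExperiment(rows)

    truth <- list(config = config, kinetics = kin, amounts = truthAmounts)
    surface <- forwardSurface(truth)
    asymAmounts <- stats::setNames(kin$baseline + kin$amplitude,
                                   kin$analyte)
    fAsym <- envelopeFractionAt(max(tp), config$morpho$envelopeRatios)
    asym <- suppressWarnings(totalMolecularSurface(
        data.frame(analyte = names(asymAmounts), amount = asymAmounts),
        time_h = Inf, f = fAsym))
    truth$surface <- surface
    truth$surfaceAsymptote <- unname(surfaceTotal(asym))

    ncp <- stats::approx(config$morpho$chloroplastsPerCell$time_h,
                         config$morpho$chloroplastsPerCell$value,
                         xout = tp, rule = 2)$y
    eps <- rep_len(config$morpho$epsilon, length(tp))
    g <- config$morpho$granaPercent
    perSeedling <- unname(surfaceTotal(surface)) + eps
    perChloroplast <- perSeedling /
        (ncp * config$morpho$cellsPerSeedling) / (1 + g / 100)
    er <- config$morpho$envelopeRatios
    morpho <- data.frame(
        time_h = tp,
        thylakoid_surface_um2 = perChloroplast,
        grana_percent = g,
        thylakoid_envelope_ratio = stats::approx(er$time_h, er$ratio,
                                                 xout = tp, rule = 2)$y,
        chloroplasts_per_cell = ncp,
        cells_per_seedling = config$morpho$cellsPerSeedling)

    list(amounts = ae, morpho = morpho, truth = truth)
}

#' Noise-free surface series implied by a truth record
#'
#' Runs the surface-accounting model on the noise-free kinetic-law
#' amounts of a truth record. By construction this equals
#' [surfaceTimecourse()] applied to a noise-free simulated dataset.
#'
#' @param truth Truth record (list with \code{config} and \code{amounts})
#'   as emitted by [simulateTimecourse()].
#' @param footprints A \linkS4class{FootprintTable}.
#' @return A \linkS4class{SurfaceBreakdown}.
#' @export
forwardSurface <- function(truth, footprints = defaultFootprints()) {
    tp <- truth$config$timePoints
    m <- truth$amounts
    f <- envelopeFractionAt(tp, truth$config$morpho$envelopeRatios)
    rows <- lapply(seq_along(tp), function(i)
        totalMolecularSurface(
            data.frame(analyte = rownames(m), amount = m[, i]),
            time_h = tp[i], footprints = footprints, f = f[i]))
    do.call(combineBreakdowns, rows)
}
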