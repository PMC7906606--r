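## Typed conditions so shell wrappers can map failures to exit codes
## (I/O problems vs validation problems).
.ioError <- function(...) {
    stop(structure(class = c("thylakoidIOError", "error", "condition"),
                   list(message = paste0(...), call = NULL)))
}

.validationError <- function(...) {
    stop(structure(
        class = c("thylakoidValidationError", "error", "condition"),
        list(message = paste0(...), call = NULL)))
}

.fmt <- function(x, digits = 6) {
    if (is.numeric(x)) signif(x, digits) else x
}

.writeTable <- function(df, path, digits = 6) {
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], signif, digits = digits)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
}

#' Assemble a pipeline run configuration
#'
#' Collects the inputs, options and output location for the pipeline
#' runners. Every run serializes the resolved configuration (YAML) next
#' to its outputs, so a run can be reproduced from its output directory
#' alone.
#'
#' @param amounts Path to a long-format amount table (see
#'   [readAmountTable()]); default the packaged subunit table.
#' @param morphometrics Path to a morphometric table, or NULL to skip
#'   the comparison stage.
#' @param footprints Path to a footprint file, or NULL for
#'   [defaultFootprints()].
#' @param outputDir Directory for outputs (created if missing).
#' @param envelopeRatios \code{"reference"} (interpolate the packaged
#'   thylakoid/envelope ratios) or \code{"none"} (no envelope
#'   correction).
#' @param epsilon Unquantified-component surface
#'   (\eqn{\mu m^2}/seedling), scalar or per time point.
#' @param fitMode \code{"pooled"} or \code{"mixed"}.
#' @param scaleThreshold,band Comparison settings, see
#'   [compareModelMorpho()].
#' @param seed Integer seed recorded with the run and applied before any
#'   stochastic stage.
#' @param digits Significant digits for serialized numbers (default 6).
#' @param simulation Optional [simulationConfig()] for
#'   [runSimulatePipeline()].
#' @param verbose Emit progress messages.
#' @return List of class \code{"thylakoidRunConfig"}.
#' @export
runConfig <- function(amounts = thylakoidDataFile("subunit_amounts.csv"),
                      morphometrics =
                          thylakoidDataFile("morphometrics.csv"),
                      footprints = NULL,
                      outputDir = tempfile("thylakoid-run-"),
                      envelopeRatios = c("reference", "none"),
                      epsilon = 0,
                      fitMode = c("pooled", "mixed"),
                      scaleThreshold = 0.1, band = c(0.5, 2),
                      seed = 1L, digits = 6L, simulation = NULL,
                      verbose = FALSE) {
    structure(list(
        amounts = amounts, morphometrics = morphometrics,
        footprints = footprints, outputDir = outputDir,
        envelopeRatios = match.arg(envelopeRatios), epsilon = epsilon,
        fitMode = match.arg(fitMode), scaleThreshold = scaleThreshold,
        band = band, seed = as.integer(seed), digits = as.integer(digits),
        simulation = simulation, verbose = isTRUE(verbose)),
        class = "thylakoidRunConfig")
}

.resolveFootprints <- function(config) {
    if (is.null(config$footprints)) defaultFootprints()
    else readFootprintTable(config$footprints)
}

.resolveEnvelope <- function(config) {
    if (config$envelopeRatios == "none") NULL else referenceEnvelopeRatios()
}

.writeResolvedConfig <- function(config, dir) {
    ser <- config
    ser$simulation <- if (is.null(config$simulation)) NULL else
        lapply(config$simulation, function(x)
            if (is.data.frame(x) || is.list(x)) lapply(as.list(x), I) else x)
    ser <- lapply(ser, function(x) if (is.function(x)) NULL else x)
    yaml::write_yaml(ser, file.path(dir, "run_config.yaml"))
}

.runLog <- function(config, dir, lines) {
    fp <- .resolveFootprints(config)
    header <- c(
        paste0("ThylakoidExpansion ",
               as.character(utils::packageVersion("ThylakoidExpansion"))),
        paste0("seed: ", config$seed),
        paste0("avogadro: ", .AVOGADRO),
        paste0("bilayer_divisor: ", .BILAYER_DIVISOR),
        paste0("footprints_nm2: ",
               paste(names(footprintAreas(fp)), footprintAreas(fp),
                     sep = "=", collapse = ", ")))
    writeLines(c(header, lines), file.path(dir, "run_log.txt"))
}

.loadAmounts <- function(config) {
    if (!file.exists(config$amounts))
        .ioError("cannot read amount table: ", config$amounts)
    ae <- tryCatch(readAmountTable(config$amounts),
                   error = function(e)
                       .validationError("invalid amount table: ",
                                        conditionMessage(e)))
    if (nrow(ae) == 0L || ncol(ae) == 0L)
        .validationError("amount table is empty: ", config$amounts)
    ae
}

#' Run the surface-accounting stage
#'
#' Reads the amount table, computes the per-time-point surface breakdown
#' (with bilayer and envelope corrections) and writes
#' \code{surface_breakdown.csv}, a run log recording the constants and
#' correction factors used, and the resolved configuration. Identical
#' configurations produce byte-identical outputs.
#'
#' @param config A [runConfig()].
#' @return The \linkS4class{SurfaceBreakdown}, invisibly; outputs on
#'   disk under \code{config$outputDir}.
#' @examples
#' cfg <- runConfig(morphometrics = NULL, outputDir = tempfile())
#' sb <- suppressWarnings(runSurfacePipeline(cfg))
#' @export
runSurfacePipeline <- function(config) {
    ae <- .loadAmounts(config)
    fp <- .resolveFootprints(config)
    sb <- surfaceTimecourse(ae, footprints = fp,
                            envelopeRatios = .resolveEnvelope(config),
                            epsilon = config$epsilon)
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    .writeTable(as.data.frame(sb),
                file.path(config$outputDir, "surface_breakdown.csv"),
                config$digits)
    .runLog(config, config$outputDir, c(
        paste0("envelope_ratios: ", config$envelopeRatios),
        paste0("envelope_fraction_by_time: ",
               paste(sb@time_h, signif(sb@envelopeFraction, 4),
                     sep = "=", collapse = ", ")),
        paste0("epsilon_um2: ",
               paste(signif(sb@epsilon, 4), collapse = ", "))))
    .writeResolvedConfig(config, config$outputDir)
    if (config$verbose)
        message("surface breakdown written to ", config$outputDir)
    invisible(sb)
}

#' Run the growth-model fit and model-vs-morphometry comparison
#'
#' Computes the molecular surface series, fits the 4PL (pooled over
#' replicate means, or the mixed model on per-replicate series when
#' \code{fitMode = "mixed"} and replicates are present), and, when a
#' morphometric table is available, writes the per-time-point comparison
#' with agree/diverge flags. A fit that fails to converge is reported
#' with its flag rather than raising.
#'
#' @param config A [runConfig()].
#' @return List with \code{fit} (\linkS4class{Logistic4PFit}),
#'   \code{mixed} (\linkS4class{MixedLogistic4PFit} or NULL) and
#'   \code{comparison} (data.frame or NULL), invisibly; outputs
#'   (\code{fit_report.yaml}, \code{comparison.csv}) on disk.
#' @export
runFitComparePipeline <- function(config) {
    ae <- .loadAmounts(config)
    fp <- .resolveFootprints(config)
    env <- .resolveEnvelope(config)
    sb <- surfaceTimecourse(ae, footprints = fp, envelopeRatios = env,
                            epsilon = config$epsilon)
    set.seed(config$seed)
    fit <- fitLogistic4P(timePoints(sb), unname(surfaceTotal(sb)))
    mixed <- NULL
    if (config$fitMode == "mixed") {
        long <- amountLong(ae)
        reps <- sort(unique(long$replicate))
        if (length(reps) >= 2L) {
            perRep <- lapply(reps, function(r) {
                sub <- long[long$replicate == r, , drop = FALSE]
                aeR <- AnalyteExperiment(sub)
                s <- suppressWarnings(
                    surfaceTimecourse(aeR, footprints = fp,
                                      envelopeRatios = env,
                                      epsilon = config$epsilon))
                data.frame(time = timePoints(s),
                           surface = unname(surfaceTotal(s)),
                           replicate = r)
            })
            perRep <- do.call(rbind, perRep)
            mixed <- fitLogistic4PMixed(perRep$time, perRep$surface,
                                        perRep$replicate)
        } else {
            warning("mixed fit requested but only one replicate present; ",
                    "reporting the pooled fit", call. = FALSE)
        }
    }
    comparison <- NULL
    if (!is.null(config$morphometrics)) {
        if (!file.exists(config$morphometrics)) {
            warning("morphometric table not found (",
                    config$morphometrics,
                    "); comparison skipped", call. = FALSE)
        } else {
            morpho <- morphometricSurfaceTable(
                readMorphometricTable(config$morphometrics))
            comparison <- compareModelMorpho(
                fit, morpho, scaleThreshold = config$scaleThreshold,
                band = config$band)
        }
    }
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    report <- list(
        parameters = as.list(.fmt(coef(fit), config$digits)),
        standard_errors = as.list(.fmt(fit@se, config$digits)),
        residual_sd = .fmt(fit@sigma, config$digits),
        rss = .fmt(fit@rss, config$digits),
        convergence = fit@convergence)
    if (!is.null(mixed))
        report$mixed <- list(
            method = mixed@method,
            fixed = as.list(.fmt(mixed@fixed, config$digits)),
            random_sd = as.list(.fmt(mixed@randomSd, config$digits)),
            residual_sd = .fmt(mixed@residualSd, config$digits))
    yaml::write_yaml(report, file.path(config$outputDir,
                                       "fit_report.yaml"))
    if (!is.null(comparison))
        .writeTable(comparison,
                    file.path(config$outputDir, "comparison.csv"),
                    config$digits)
    .writeResolvedConfig(config, config$outputDir)
    invisible(list(fit = fit, mixed = mixed, comparison = comparison))
}

#' Run the synthetic-data stage
#'
#' Generates a synthetic dataset from \code{config$simulation} (or a
#' default configuration seeded with \code{config$seed}) and writes the
#' amount table, the morphometric table, the truth record (YAML) and the
#' resolved configuration. Rerunning with the same seed reproduces the
#' files exactly.
#'
#' @param config A [runConfig()].
#' @return The simulation list (see [simulateTimecourse()]), invisibly.
#' @export
runSimulatePipeline <- function(config) {
    simCfg <- config$simulation
    if (is.null(simCfg))
        simCfg <- simulationConfig(seed = config$seed)
    sim <- tryCatch(simulateTimecourse(simCfg),
                    error = function(e)
                        .validationError(conditionMessage(e)))
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    long <- amountLong(sim$amounts)
    long$amount <- signif(long$amount, 15)
    utils::write.csv(long, file.path(config$outputDir, "amounts.csv"),
                     row.names = FALSE, quote = FALSE)
    .writeTable(sim$morpho, file.path(config$outputDir, "morpho.csv"),
                config$digits)
    truth <- sim$truth
    yaml::write_yaml(list(
        seed = simCfg$seed,
        kinetics = lapply(as.list(truth$kinetics), I),
        surface_asymptote_um2 = .fmt(truth$surfaceAsymptote,
                                     config$digits),
        surface_total_um2 = as.list(.fmt(surfaceTotal(truth$surface),
                                         config$digits))),
        file.path(config$outputDir, "truth.yaml"))
    .writeResolvedConfig(config, config$outputDir)
    invisible(sim)
}
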