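#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Container for absolute analyte amounts over a de-etiolation time course
#'
#' An \code{AnalyteExperiment} is a thin
#' \linkS4class{SummarizedExperiment} holding one assay, \code{"amount"},
#' in nmol per seedling. Rows are analytes (galactolipid molecular species
#' such as \code{"MGDG 18:3/16:3"}, or photosystem marker subunits such as
#' \code{"PsbA"}); columns are samples, one per (time point, replicate)
#' pair. \code{colData} carries \code{time_h} (hours of light exposure)
#' and \code{replicate}; \code{rowData} carries \code{analyte_class}
#' (\code{"lipid_species"} or \code{"protein_subunit"}).
#'
#' Validity requires non-negative amounts (NA allowed for analytes below
#' detection at early time points), non-negative times, positive integer
#' replicates, and unique (analyte, time_h, replicate) triples.
#'
#' @seealso [AnalyteExperiment()], [readAmountTable()], [amountMeans()]
#' @export
setClass("AnalyteExperiment", contains = "SummarizedExperiment")

setValidity("AnalyteExperiment", function(object) {
    msg <- character()
    if (!"amount" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'amount' is required")
    cd <- colData(object)
    if (!all(c("time_h", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'time_h' and 'replicate'")
    if (!"analyte_class" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must contain 'analyte_class'")
    if (length(msg))
        return(msg)
    if (any(cd$time_h < 0, na.rm = TRUE))
        msg <- c(msg, "time_h must be >= 0")
    if (any(cd$replicate < 1 | cd$replicate != round(cd$replicate),
            na.rm = TRUE))
        msg <- c(msg, "replicate must be a positive integer")
    a <- assay(object, "amount")
    if (any(a < 0, na.rm = TRUE))
        msg <- c(msg, "amounts must be >= 0")
    bad <- setdiff(unique(rowData(object)$analyte_class),
                   c("lipid_species", "protein_subunit"))
    if (length(bad))
        msg <- c(msg, paste0("unknown analyte_class: ",
                             paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Molecular footprint table
#'
#' Maps membrane components to the stroma-exposed area one molecule (or one
#' photosynthetic complex) occupies in the membrane, in nm\eqn{^2} per
#' molecule, together with the marker-subunit-to-complex mapping used for
#' absolute complex quantification (one marker subunit per complex by
#' default: PsbA for PSII-LHCII, PetC for cytochrome b6f, PsaC for PSI).
#'
#' @slot areas Named numeric vector, nm\eqn{^2} per molecule; all > 0.
#' @slot subunits data.frame with columns \code{subunit}, \code{complex},
#'   \code{stoichiometry} (marker subunits per complex, > 0).
#' @seealso [defaultFootprints()], [readFootprintTable()], [complexSurface()]
#' @export
setClass("FootprintTable",
    representation(areas = "numeric", subunits = "data.frame"))

setValidity("FootprintTable", function(object) {
    msg <- character()
    if (is.null(names(object@areas)) || any(!nzchar(names(object@areas))))
        msg <- c(msg, "areas must be a named vector")
    if (any(!is.finite(object@areas)) || any(object@areas <= 0))
        msg <- c(msg, "all footprint areas must be finite and > 0")
    su <- object@subunits
    if (!all(c("subunit", "complex", "stoichiometry") %in% colnames(su)))
        msg <- c(msg,
            "subunits needs columns subunit, complex, stoichiometry")
    else {
        if (any(!su$complex %in% names(object@areas)))
            msg <- c(msg, "every mapped complex needs a footprint area")
        if (any(su$stoichiometry <= 0))
            msg <- c(msg, "stoichiometry must be > 0")
        if (anyDuplicated(su$subunit))
            msg <- c(msg, "duplicated subunit in subunit map")
    }
    if (length(msg)) msg else TRUE
})

#' Per-time-point decomposition of the thylakoid surface per seedling
#'
#' Holds, for each time point, the surface contributed by each quantified
#' membrane component (MGDG, DGDG, and the photosynthetic complexes), the
#' explicit epsilon term for unquantified components (SQDG, plastoquinone,
#' ATP synthase, NDH, ...), and their sum. All surfaces are in
#' \eqn{\mu m^2} per seedling. Validity enforces the accounting identity
#' total = sum(components) + epsilon at 1e-9 relative tolerance, and
#' non-negativity of every term.
#'
#' @slot time_h Numeric, hours of light exposure.
#' @slot components Numeric matrix, time points x components
#'   (\eqn{\mu m^2}/seedling).
#' @slot epsilon Numeric, unquantified-component surface per time point.
#' @slot total Numeric, total surface per time point.
#' @slot envelopeFraction Numeric, the envelope share of membrane surface
#'   subtracted from the lipid pools at each time point.
#' @seealso [totalMolecularSurface()], [surfaceTimecourse()]
#' @export
setClass("SurfaceBreakdown",
    representation(time_h = "numeric", components = "matrix",
                   epsilon = "numeric", total = "numeric",
                   envelopeFraction = "numeric"))

setValidity("SurfaceBreakdown", function(object) {
    n <- length(object@time_h)
    msg <- character()
    if (nrow(object@components) != n || length(object@epsilon) != n ||
        length(object@total) != n || length(object@envelopeFraction) != n)
        return("slot lengths disagree")
    if (is.null(colnames(object@components)))
        msg <- c(msg, "components must have column names")
    if (any(object@components < -1e-12, na.rm = TRUE) ||
        any(object@epsilon < 0))
        msg <- c(msg, "surface components and epsilon must be >= 0")
    expect <- rowSums(object@components) + object@epsilon
    tol <- 1e-9 * pmax(abs(expect), 1)
    if (any(abs(object@total - expect) > tol))
        msg <- c(msg, "total must equal sum(components) + epsilon")
    if (any(object@envelopeFraction < 0 | object@envelopeFraction >= 1))
        msg <- c(msg, "envelopeFraction must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' Linear calibration curve for absolute quantification
#'
#' Ordinary least-squares line signal = slope * concentration + intercept
#' fitted to external standards, as used to convert immunoblot or UHPLC-MS
#' signals into absolute concentrations.
#'
#' @slot slope,intercept Numeric scalars; slope must be > 0 for a usable
#'   quantification curve.
#' @slot rSquared Coefficient of determination in [0, 1].
#' @slot standards data.frame with columns \code{concentration},
#'   \code{signal}.
#' @seealso [fitLinearCalibration()], [quantifyConcentration()]
#' @export
setClass("CalibrationCurve",
    representation(slope = "numeric", intercept = "numeric",
                   rSquared = "numeric", standards = "data.frame"))

setValidity("CalibrationCurve", function(object) {
    msg <- character()
    if (nrow(object@standards) < 2 ||
        length(unique(object@standards$concentration)) < 2)
        msg <- c(msg, "need >= 2 distinct standard concentrations")
    if (!is.finite(object@slope) || !is.finite(object@intercept))
        msg <- c(msg, "slope and intercept must be finite")
    if (is.finite(object@rSquared) &&
        (object@rSquared < -1e-8 || object@rSquared > 1 + 1e-8))
        msg <- c(msg, "rSquared must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Four-parameter logistic fit of surface versus time
#'
#' S(t) = a + (d - a) / (1 + exp((tmid - t) / tau)), with lower asymptote
#' \code{a}, upper asymptote \code{d}, inflection time \code{tmid} (where
#' S = (a + d)/2 exactly) and timescale \code{tau} > 0 (hours).
#'
#' @slot coefficients Named numeric: \code{a}, \code{d}, \code{tmid},
#'   \code{tau}.
#' @slot se Named numeric standard errors (NA when unavailable, e.g. for a
#'   degenerate flat fit).
#' @slot data data.frame with \code{time} and \code{surface} used in the fit.
#' @slot rss Residual sum of squares.
#' @slot sigma Residual standard deviation.
#' @slot convergence List: \code{converged}, \code{iterations},
#'   \code{message}, \code{degenerate}.
#' @seealso [fitLogistic4P()], [logistic4pEval()]
#' @export
setClass("Logistic4PFit",
    representation(coefficients = "numeric", se = "numeric",
                   data = "data.frame", rss = "numeric", sigma = "numeric",
                   convergence = "list"))

setValidity("Logistic4PFit", function(object) {
    p <- object@coefficients
    if (!all(c("a", "d", "tmid", "tau") %in% names(p)))
        return("coefficients must be named a, d, tmid, tau")
    if (is.finite(p[["tau"]]) && p[["tau"]] <= 0)
        return("tau must be > 0")
    TRUE
})

#' Mixed-effects four-parameter logistic fit
#'
#' Fixed-effect 4PL parameters plus replicate-level random effects on a
#' subset of three parameters. With all between-replicate SDs equal to
#' zero, predictions coincide with the pooled fit.
#'
#' @slot fixed Named numeric fixed-effect parameters (a, d, tmid, tau).
#' @slot randomSd Named numeric between-replicate SDs for the randomized
#'   parameters (>= 0).
#' @slot perReplicate Numeric matrix of per-replicate parameter offsets
#'   (replicates x parameters), zero for non-randomized parameters.
#' @slot residualSd Residual SD.
#' @slot randomized Character, the three randomized parameter names.
#' @slot method \code{"nlme"} or \code{"twostage"} (the estimator that
#'   actually produced the result).
#' @slot pooled The pooled \linkS4class{Logistic4PFit} on the same data.
#' @slot convergence List of diagnostics, including \code{pooledFallback}
#'   when a single replicate forced a pooled fit.
#' @seealso [fitLogistic4PMixed()]
#' @export
setClass("MixedLogistic4PFit",
    representation(fixed = "numeric", randomSd = "numeric",
                   perReplicate = "matrix", residualSd = "numeric",
                   randomized = "character", method = "character",
                   pooled = "Logistic4PFit", convergence = "list"))

setValidity("MixedLogistic4PFit", function(object) {
    if (any(object@randomSd < 0, na.rm = TRUE))
        return("randomSd must be >= 0")
    if (length(object@randomized) && !all(object@randomized %in%
            c("a", "d", "tmid", "tau")))
        return("randomized must name 4PL parameters")
    TRUE
})
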