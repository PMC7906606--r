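#' Parse galactolipid species names
#'
#' Parses names of the strict form \code{"HEAD c1:d1/c2:d2"} (e.g.
#' \code{"MGDG 18:3/16:3"}) into headgroup and acyl-chain descriptors.
#' The headgroup must be MGDG or DGDG; anything else is rejected rather
#' than guessed, since a silently misparsed name would corrupt the
#' per-headgroup surface sums.
#'
#' @param name Character vector of species names.
#' @return data.frame with columns \code{name}, \code{headgroup},
#'   \code{sn1_carbons}, \code{sn1_double_bonds}, \code{sn2_carbons},
#'   \code{sn2_double_bonds}.
#' @examples
#' parseLipidSpecies("MGDG 18:3/16:3")
#' @export
parseLipidSpecies <- function(name) {
    rx <- "^(MGDG|DGDG) ([0-9]+):([0-9]+)/([0-9]+):([0-9]+)$"
    ok <- grepl(rx, name)
    if (any(!ok))
        stop("not a valid galactolipid species name: ",
             paste(sQuote(name[!ok]), collapse = ", "), call. = FALSE)
    m <- regmatches(name, regexec(rx, name))
    out <- data.frame(
        name = name,
        headgroup = vapply(m, `[`, "", 2L),
        sn1_carbons = as.integer(vapply(m, `[`, "", 3L)),
        sn1_double_bonds = as.integer(vapply(m, `[`, "", 4L)),
        sn2_carbons = as.integer(vapply(m, `[`, "", 5L)),
        sn2_double_bonds = as.integer(vapply(m, `[`, "", 6L)))
    rownames(out) <- NULL
    out
}

#' Serialize parsed lipid species back to canonical names
#'
#' Inverse of [parseLipidSpecies()]; \code{formatLipidSpecies(
#' parseLipidSpecies(x))} reproduces \code{x} exactly.
#'
#' @param parsed data.frame as returned by [parseLipidSpecies()].
#' @return Character vector of canonical species names.
#' @export
formatLipidSpecies <- function(parsed) {
    sprintf("%s %d:%d/%d:%d", parsed$headgroup, parsed$sn1_carbons,
            parsed$sn1_double_bonds, parsed$sn2_carbons,
            parsed$sn2_double_bonds)
}

#' Classify a galactolipid species by biosynthetic pathway
#'
#' Galactolipids made via the endoplasmic-reticulum (ER) route carry an
#' 18-carbon acyl chain at the sn2 position, whereas those made entirely
#' inside the plastid (PL route) carry a 16-carbon sn2 chain. The rule is
#' total on sn2 chain lengths 16 and 18 and errors on anything else; it
#' never silently defaults.
#'
#' @param name Character vector of species names, or a data.frame from
#'   [parseLipidSpecies()].
#' @return Character vector, \code{"ER"} or \code{"PL"}, named by species.
#' @examples
#' classifyPathway(c("MGDG 18:3/16:3", "DGDG 18:3/18:3"))
#' @export
classifyPathway <- function(name) {
    parsed <- if (is.data.frame(name)) name else parseLipidSpecies(name)
    bad <- !parsed$sn2_carbons %in% c(16L, 18L)
    if (any(bad))
        stop("cannot classify pathway for sn2 chain length ",
             paste(unique(parsed$sn2_carbons[bad]), collapse = ", "),
             " (", paste(sQuote(parsed$name[bad]), collapse = ", "),
             "): rule covers sn2 16 (PL) and 18 (ER) only", call. = FALSE)
    out <- ifelse(parsed$sn2_carbons == 18L, "ER", "PL")
    names(out) <- parsed$name
    out
}

#' Build an AnalyteExperiment from a long table
#'
#' Assembles an \linkS4class{AnalyteExperiment} from long-format records
#' (one row per analyte, time point and replicate). Analytes absent from
#' some samples (e.g. PSI subunits below detection before 12 h) get NA.
#'
#' @param amounts data.frame with columns \code{analyte}, \code{time_h},
#'   \code{replicate}, \code{amount}, and optionally \code{analyte_class};
#'   when the class column is missing it is inferred: names parseable as
#'   galactolipid species are \code{"lipid_species"}, everything else
#'   \code{"protein_subunit"}.
#' @return An \linkS4class{AnalyteExperiment}.
#' @examples
#' ae <- AnalyteExperiment(data.frame(
#'     analyte = "PsbA", time_h = c(0, 4), replicate = 1,
#'     amount = c(6.9e-6, 9.2e-6)))
#' amountMeans(ae)
#' @export
AnalyteExperiment <- function(amounts) {
    required <- c("analyte", "time_h", "replicate", "amount")
    miss <- setdiff(required, colnames(amounts))
    if (length(miss))
        stop("missing required column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    amounts$time_h <- as.numeric(amounts$time_h)
    amounts$replicate <- as.integer(amounts$replicate)
    amounts$amount <- as.numeric(amounts$amount)
    neg <- which(!is.na(amounts$amount) & amounts$amount < 0)
    if (length(neg))
        stop("negative amount at row(s) ", paste(neg, collapse = ", "),
             call. = FALSE)
    key <- paste(amounts$analyte, amounts$time_h, amounts$replicate)
    if (anyDuplicated(key))
        stop("duplicated (analyte, time_h, replicate) at row(s) ",
             paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
    if (!"analyte_class" %in% colnames(amounts)) {
        isLipid <- grepl("^(MGDG|DGDG) [0-9]+:[0-9]+/[0-9]+:[0-9]+$",
                         amounts$analyte)
        amounts$analyte_class <-
            ifelse(isLipid, "lipid_species", "protein_subunit")
    }
    analytes <- unique(amounts$analyte)
    samples <- unique(amounts[order(amounts$time_h, amounts$replicate),
                              c("time_h", "replicate")])
    sampleId <- paste0("T", samples$time_h, ".r", samples$replicate)
    mat <- matrix(NA_real_, nrow = length(analytes), ncol = nrow(samples),
                  dimnames = list(analytes, sampleId))
    col <- match(paste(amounts$time_h, amounts$replicate),
                 paste(samples$time_h, samples$replicate))
    mat[cbind(match(amounts$analyte, analytes), col)] <- amounts$amount
    cls <- amounts$analyte_class[match(analytes, amounts$analyte)]
    se <- SummarizedExperiment(
        assays = list(amount = mat),
        rowData = DataFrame(analyte_class = cls, row.names = analytes),
        colData = DataFrame(time_h = samples$time_h,
                            replicate = samples$replicate,
                            row.names = sampleId))
    new("AnalyteExperiment", se)
}

#' Read a long-format amount table
#'
#' Reads a delimiter-separated text file (comma by default, tab accepted)
#' with a header row into an \linkS4class{AnalyteExperiment}. Column names
#' can be remapped through \code{dialect} for files using different
#' headers. Negative amounts and duplicated (analyte, time, replicate)
#' keys are rejected with the offending row numbers.
#'
#' @param path Path to the file.
#' @param dialect Named character vector mapping canonical names
#'   (\code{analyte}, \code{time_h}, \code{replicate}, \code{amount},
#'   optionally \code{analyte_class}) to the file's column names.
#' @param sep Field separator; \code{","} (default) or \code{"\t"}.
#' @return An \linkS4class{AnalyteExperiment}.
#' @examples
#' ae <- readAmountTable(thylakoidDataFile("subunit_amounts.csv"))
#' timePoints(ae)
#' @export
readAmountTable <- function(path, dialect = NULL, sep = ",") {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (!is.null(dialect)) {
        for (canonical in names(dialect)) {
            hit <- match(dialect[[canonical]], colnames(df))
            if (is.na(hit))
                stop("dialect column '", dialect[[canonical]],
                     "' not found in ", path, call. = FALSE)
            colnames(df)[hit] <- canonical
        }
    }
    required <- c("analyte", "time_h", "replicate", "amount")
    miss <- setdiff(required, colnames(df))
    if (length(miss))
        stop("missing required column(s) in ", path, ": ",
             paste(miss, collapse = ", "), call. = FALSE)
    AnalyteExperiment(df)
}

#' Write an AnalyteExperiment back to a long table
#'
#' Writes the required long-format columns (analyte, analyte_class,
#' time_h, replicate, amount); reading the file back reproduces the
#' object (lossless round trip, NA rows dropped).
#'
#' @param x An \linkS4class{AnalyteExperiment}.
#' @param path Output file path.
#' @param sep Field separator.
#' @return \code{path}, invisibly.
#' @export
writeAmountTable <- function(x, path, sep = ",") {
    utils::write.table(amountLong(x), path, sep = sep, row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' Long-format view of the amounts
#'
#' @param x An \linkS4class{AnalyteExperiment}.
#' @return data.frame with columns analyte, analyte_class, time_h,
#'   replicate, amount; NA amounts (analyte not measured in a sample)
#'   are dropped.
#' @export
amountLong <- function(x) {
    a <- assay(x, "amount")
    cd <- colData(x)
    out <- data.frame(
        analyte = rep(rownames(a), times = ncol(a)),
        analyte_class = rep(rowData(x)$analyte_class, times = ncol(a)),
        time_h = rep(cd$time_h, each = nrow(a)),
        replicate = rep(cd$replicate, each = nrow(a)),
        amount = as.vector(a))
    out[!is.na(out$amount), , drop = FALSE]
}

#' Replicate means per analyte and time point
#'
#' Unweighted arithmetic means across replicates (matching how the
#' reference tables report values); use \code{fun = stats::sd} for the
#' sample SD.
#'
#' @param x An \linkS4class{AnalyteExperiment}.
#' @param fun Summary function applied across replicates (default mean).
#' @return Numeric matrix, analytes x time points (columns sorted by
#'   time, named by time in hours).
#' @export
amountMeans <- function(x, fun = mean) {
    a <- assay(x, "amount")
    times <- sort(unique(colData(x)$time_h))
    out <- vapply(times, function(tt) {
        cols <- colData(x)$time_h == tt
        apply(a[, cols, drop = FALSE], 1L, function(v)
            if (all(is.na(v))) NA_real_ else fun(v[!is.na(v)]))
    }, numeric(nrow(a)))
    out <- matrix(out, nrow = nrow(a),
                  dimnames = list(rownames(a), as.character(times)))
    out
}

#' @describeIn timePoints Sorted unique measurement times of the samples.
#' @export
setMethod("timePoints", "AnalyteExperiment",
    function(x) sort(unique(colData(x)$time_h)))

#' Normalize a mean matrix to a reference time point
#'
#' Divides every row of an analyte x time matrix by its value at the
#' reference time (the last time point in the reference heatmaps), so the
#' reference column becomes exactly 1. Rows with a zero or missing
#' reference value are reported by analyte name. The operation is
#' idempotent: normalizing an already-normalized matrix is a no-op.
#'
#' @param mat Numeric matrix, analytes x time; column names are times in
#'   hours.
#' @param referenceTime Time point to normalize to (default: last column).
#' @return Fold-change matrix of the same shape.
#' @examples
#' m <- matrix(c(1, 2, 4), 1, dimnames = list("x", c(0, 4, 8)))
#' normalizeToReference(m)
#' @export
normalizeToReference <- function(mat, referenceTime = NULL) {
    times <- as.numeric(colnames(mat))
    if (is.null(referenceTime))
        referenceTime <- times[length(times)]
    j <- which(times == referenceTime)
    if (length(j) != 1L)
        stop("reference time ", referenceTime, " not a column of the matrix",
             call. = FALSE)
    ref <- mat[, j]
    bad <- which(is.na(ref) | ref == 0)
    if (length(bad))
        stop("zero or missing reference value for analyte(s): ",
             paste(rownames(mat)[bad], collapse = ", "), call. = FALSE)
    sweep(mat, 1L, ref, "/")
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of signal on standard concentration, as used to
#' convert immunoblot band intensities (recombinant-protein standards) or
#' UHPLC-MS peak areas (pure lipid standards) into absolute amounts.
#'
#' @param concentration Numeric standard concentrations (>= 2 distinct
#'   values).
#' @param signal Numeric measured signals, same length.
#' @return A \linkS4class{CalibrationCurve}.
#' @examples
#' conc <- c(1.75, 2.5, 5, 10)
#' fitLinearCalibration(conc, 2 * conc + 1)
#' @export
fitLinearCalibration <- function(concentration, signal) {
    if (length(concentration) != length(signal))
        stop("concentration and signal lengths differ", call. = FALSE)
    if (length(unique(concentration)) < 2)
        stop("degenerate design: need >= 2 distinct standard concentrations",
             call. = FALSE)
    fit <- stats::lm(signal ~ concentration)
    ss <- sum((signal - mean(signal))^2)
    r2 <- if (ss > 0) 1 - sum(stats::residuals(fit)^2) / ss else NA_real_
    new("CalibrationCurve",
        slope = unname(stats::coef(fit)[2L]),
        intercept = unname(stats::coef(fit)[1L]),
        rSquared = r2,
        standards = data.frame(concentration = concentration,
                               signal = signal))
}

#' Predict the signal of a known concentration
#'
#' Forward evaluation of a calibration line; inverse of
#' [quantifyConcentration()].
#'
#' @param curve A \linkS4class{CalibrationCurve}.
#' @param concentration Numeric concentrations.
#' @return Predicted signals.
#' @export
predictSignal <- function(curve, concentration) {
    curve@slope * concentration + curve@intercept
}

#' Quantify a signal against a calibration curve
#'
#' Inverts the calibration line: concentration =
#' (signal - intercept) / slope. Signals below the intercept (blot
#' background) would give negative concentrations; these are clipped to 0
#' and flagged in the \code{"clipped"} attribute, with a warning.
#'
#' @param signal Numeric measured signals.
#' @param curve A \linkS4class{CalibrationCurve} with positive slope.
#' @param clip Clip negative results to zero (default TRUE); with
#'   \code{clip = FALSE} negative concentrations are returned as-is.
#' @return Numeric concentrations with a logical \code{"clipped"}
#'   attribute.
#' @export
quantifyConcentration <- function(signal, curve, clip = TRUE) {
    if (curve@slope <= 0)
        stop("invalid calibration curve: slope must be > 0", call. = FALSE)
    conc <- (signal - curve@intercept) / curve@slope
    clipped <- !is.na(conc) & conc < 0
    if (clip && any(clipped)) {
        warning(sum(clipped), " signal(s) below the calibration intercept; ",
                "concentration clipped to 0", call. = FALSE)
        conc[clipped] <- 0
    }
    attr(conc, "clipped") <- clipped
    conc
}
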