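#' Convert a molar amount to a molecule count
#'
#' nmol per seedling times the Avogadro constant.
#'
#' @param amount Numeric, nmol per seedling (>= 0).
#' @return Molecules per seedling.
#' @examples
#' amountToMolecules(1) # 6.022e14
#' @export
amountToMolecules <- function(amount) {
    if (any(!is.na(amount) & amount < 0))
        stop("amount must be >= 0", call. = FALSE)
    amount * 1e-9 * .AVOGADRO
}

#' Surface occupied by a photosynthetic complex per seedling
#'
#' Converts the absolute amount of a marker subunit into the
#' stroma-exposed surface of its complex: the subunit amount is divided by
#' the subunit:complex stoichiometry (1:1 for PsbA, PetC, PsaC), converted
#' to complexes per seedling with the Avogadro constant, and multiplied by
#' the complex footprint. No bilayer division is applied to proteins: the
#' footprints are already stroma-exposed areas.
#'
#' @param amount Subunit amount, nmol per seedling.
#' @param subunit Marker subunit name present in the subunit map (e.g.
#'   \code{"PsbA"}).
#' @param footprints A \linkS4class{FootprintTable}.
#' @return Surface in \eqn{\mu m^2} per seedling.
#' @examples
#' complexSurface(6.9e-6, "PsbA") # ~2.05e6 um2
#' @export
complexSurface <- function(amount, subunit, footprints = defaultFootprints()) {
    su <- subunitMap(footprints)
    i <- match(subunit, su$subunit)
    if (any(is.na(i)))
        stop("unknown subunit(s): ",
             paste(sQuote(subunit[is.na(i)]), collapse = ", "),
             call. = FALSE)
    area <- footprintAreas(footprints)[su$complex[i]]
    unname(amountToMolecules(amount / su$stoichiometry[i]) * area /
               .NM2_PER_UM2)
}

#' Envelope share of membrane surface from the thylakoid/envelope ratio
#'
#' With thylakoid-to-envelope surface ratio R, the envelope holds a
#' fraction f = 1 / (1 + R) of the total (thylakoid + envelope) membrane
#' surface; this is the share of the galactolipid pool assigned to the
#' envelope and subtracted before thylakoid surface accounting.
#'
#' @param ratio Thylakoid/envelope surface ratio, > 0.
#' @return Fraction in (0, 1).
#' @examples
#' envelopeFraction(6.83) # ~0.128 at T96
#' @export
envelopeFraction <- function(ratio) {
    if (any(!is.na(ratio) & ratio <= 0))
        stop("thylakoid/envelope ratio must be > 0", call. = FALSE)
    1 / (1 + ratio)
}

#' Envelope fraction at arbitrary time points
#'
#' The thylakoid/envelope ratio is only measured at a few time points
#' (T4, T24, T96 in the reference data). Ratios are interpolated
#' piecewise-linearly between measured times and extrapolated as constant
#' outside them, then converted with [envelopeFraction()].
#'
#' @param time_h Numeric times (hours).
#' @param ratios data.frame with columns \code{time_h}, \code{ratio};
#'   default [referenceEnvelopeRatios()].
#' @return Envelope fractions at \code{time_h}.
#' @examples
#' envelopeFractionAt(c(0, 12, 96))
#' @export
envelopeFractionAt <- function(time_h, ratios = referenceEnvelopeRatios()) {
    if (nrow(ratios) == 1L)
        return(envelopeFraction(rep(ratios$ratio, length(time_h))))
    r <- stats::approx(ratios$time_h, ratios$ratio, xout = time_h,
                       rule = 2)$y
    envelopeFraction(r)
}

#' Thylakoid surface of one galactolipid class per seedling
#'
#' Sums the amounts of all species of one headgroup, removes the envelope
#' share (fraction \code{f} of the lipid pool sits in the envelope, not
#' the thylakoids), divides by 2 to account for the two leaflets of the
#' bilayer, and multiplies by molecule count and the headgroup's minimal
#' molecular area.
#'
#' @param species data.frame with columns \code{name} (species names,
#'   e.g. \code{"MGDG 18:3/16:3"}) and \code{amount} (nmol/seedling).
#' @param headgroup \code{"MGDG"} or \code{"DGDG"}; only species of this
#'   headgroup are summed.
#' @param f Envelope fraction in [0, 1).
#' @param footprints A \linkS4class{FootprintTable}.
#' @return Surface in \eqn{\mu m^2} per seedling.
#' @examples
#' lipidClassSurface(data.frame(name = "MGDG 18:3/16:3", amount = 1),
#'                   "MGDG", f = 0)
#' @export
lipidClassSurface <- function(species, headgroup = c("MGDG", "DGDG"),
                              f = 0, footprints = defaultFootprints()) {
    headgroup <- match.arg(headgroup)
    if (length(f) != 1L || is.na(f) || f < 0 || f >= 1)
        stop("envelope fraction f must lie in [0, 1)", call. = FALSE)
    if (any(!is.na(species$amount) & species$amount < 0))
        stop("species amounts must be >= 0", call. = FALSE)
    parsed <- parseLipidSpecies(species$name)
    keep <- parsed$headgroup == headgroup & !is.na(species$amount)
    total <- sum(species$amount[keep])
    area <- footprintAreas(footprints)[[headgroup]]
    amountToMolecules(total * (1 - f) / .BILAYER_DIVISOR) * area /
        .NM2_PER_UM2
}

#' Total molecular thylakoid surface at one time point
#'
#' The surface-accounting step: thylakoid surface per seedling is the sum
#' of the surfaces occupied by MGDG, DGDG, the photosynthetic complexes,
#' and an explicit epsilon term for unquantified components. Lipid pools
#' are bilayer-divided and envelope-corrected; complexes are not. A
#' component with no measured analyte contributes 0 with a warning.
#'
#' @param amounts data.frame with columns \code{analyte} and \code{amount}
#'   (nmol/seedling) for one time point: galactolipid species plus marker
#'   subunits.
#' @param time_h The time point (hours), stored in the result.
#' @param footprints A \linkS4class{FootprintTable}.
#' @param f Envelope fraction at this time (see [envelopeFractionAt()]).
#' @param epsilon Surface of unquantified components, \eqn{\mu m^2}
#'   (default 0; reported explicitly as the model's unaccounted term).
#' @return A single-row \linkS4class{SurfaceBreakdown}.
#' @examples
#' totalMolecularSurface(
#'     data.frame(analyte = c("MGDG 18:3/16:3", "PsbA"),
#'                amount = c(0.5, 6.9e-6)),
#'     time_h = 0)
#' @export
totalMolecularSurface <- function(amounts, time_h = NA_real_,
                                  footprints = defaultFootprints(),
                                  f = 0, epsilon = 0) {
    if (epsilon < 0)
        stop("epsilon must be >= 0", call. = FALSE)
    su <- subunitMap(footprints)
    isSubunit <- amounts$analyte %in% su$subunit
    isLipid <- grepl("^(MGDG|DGDG) ", amounts$analyte)
    lipids <- data.frame(name = amounts$analyte[isLipid],
                         amount = amounts$amount[isLipid])
    comp <- c(
        MGDG = lipidClassSurface(lipids, "MGDG", f, footprints),
        DGDG = lipidClassSurface(lipids, "DGDG", f, footprints))
    protein <- stats::setNames(numeric(nrow(su)), su$complex)
    for (k in seq_len(nrow(su))) {
        j <- which(amounts$analyte == su$subunit[k] & !is.na(amounts$amount))
        if (length(j))
            protein[k] <- complexSurface(sum(amounts$amount[j]),
                                         su$subunit[k], footprints)
    }
    measured <- c(any(isLipid & grepl("^MGDG", amounts$analyte)),
                  any(isLipid & grepl("^DGDG", amounts$analyte)),
                  su$subunit %in% amounts$analyte[!is.na(amounts$amount)])
    if (any(!measured))
        warning("no measured amount for component(s): ",
                paste(c("MGDG", "DGDG", su$complex)[!measured],
                      collapse = ", "),
                "; contributing 0 to the total", call. = FALSE)
    comp <- c(comp, protein)
    new("SurfaceBreakdown",
        time_h = time_h,
        components = matrix(comp, nrow = 1,
                            dimnames = list(NULL, names(comp))),
        epsilon = epsilon,
        total = sum(comp) + epsilon,
        envelopeFraction = f)
}

#' Molecular surface time course from an AnalyteExperiment
#'
#' Applies [totalMolecularSurface()] to the replicate-mean amounts at
#' every measured time point, using time-interpolated envelope fractions.
#'
#' @param x An \linkS4class{AnalyteExperiment}.
#' @param footprints A \linkS4class{FootprintTable}.
#' @param envelopeRatios data.frame (\code{time_h}, \code{ratio}) of
#'   thylakoid/envelope ratios, or NULL for no envelope correction.
#' @param epsilon Scalar or per-time-point vector of unquantified-component
#'   surface (\eqn{\mu m^2}/seedling).
#' @return A \linkS4class{SurfaceBreakdown} with one row per time point.
#' @examples
#' ae <- readAmountTable(thylakoidDataFile("subunit_amounts.csv"))
#' sb <- suppressWarnings(surfaceTimecourse(ae, envelopeRatios = NULL))
#' surfaceTotal(sb)
#' @export
surfaceTimecourse <- function(x, footprints = defaultFootprints(),
                              envelopeRatios = referenceEnvelopeRatios(),
                              epsilon = 0) {
    times <- timePoints(x)
    m <- amountMeans(x)
    f <- if (is.null(envelopeRatios)) rep(0, length(times))
         else envelopeFractionAt(times, envelopeRatios)
    epsilon <- rep_len(epsilon, length(times))
    rows <- lapply(seq_along(times), function(i) {
        totalMolecularSurface(
            data.frame(analyte = rownames(m), amount = m[, i]),
            time_h = times[i], footprints = footprints, f = f[i],
            epsilon = epsilon[i])
    })
    do.call(combineBreakdowns, rows)
}

combineBreakdowns <- function(...) {
    xs <- list(...)
    new("SurfaceBreakdown",
        time_h = unlist(lapply(xs, slot, "time_h")),
        components = do.call(rbind, lapply(xs, slot, "components")),
        epsilon = unlist(lapply(xs, slot, "epsilon")),
        total = unlist(lapply(xs, slot, "total")),
        envelopeFraction = unlist(lapply(xs, slot, "envelopeFraction")))
}

#' @describeIn surfaceComponents Per-component surface matrix.
#' @export
setMethod("surfaceComponents", "SurfaceBreakdown",
    function(x) x@components)

#' @describeIn surfaceTotal Total surface per time point.
#' @export
setMethod("surfaceTotal", "SurfaceBreakdown",
    function(x) stats::setNames(x@total, x@time_h))

#' @describeIn timePoints Time points of a surface breakdown.
#' @export
setMethod("timePoints", "SurfaceBreakdown", function(x) x@time_h)

#' Coerce a SurfaceBreakdown to a data.frame
#'
#' Columns: \code{time_h}, \code{s_mgdg_um2}, \code{s_dgdg_um2}, one
#' \code{s_*_um2} per complex, \code{epsilon_um2}, \code{s_total_um2},
#' \code{envelope_fraction}.
#'
#' @param x A \linkS4class{SurfaceBreakdown}.
#' @param ... Ignored.
#' @return data.frame, one row per time point.
#' @export
setMethod("as.data.frame", "SurfaceBreakdown", function(x, ...) {
    comp <- x@components
    nm <- tolower(gsub("[^A-Za-z0-9]+", "", colnames(comp)))
    nm <- sub("psiilhcii", "psii", nm)
    colnames(comp) <- paste0("s_", nm, "_um2")
    data.frame(time_h = x@time_h, comp, epsilon_um2 = x@epsilon,
               s_total_um2 = x@total, envelope_fraction = x@envelopeFraction)
})

#' @describeIn footprintAreas Areas of a footprint table.
#' @export
setMethod("footprintAreas", "FootprintTable", function(x) x@areas)

#' @describeIn subunitMap Subunit map of a footprint table.
#' @export
setMethod("subunitMap", "FootprintTable", function(x) x@subunits)

#' Read a footprint table file
#'
#' Two-column text (\code{name}, \code{area_nm2}) optionally followed by a
#' \code{[subunits]} section with columns \code{subunit}, \code{complex},
#' \code{stoichiometry}. The packaged \code{footprints.csv} reproduces the
#' default footprints exactly.
#'
#' @param path Path to the file.
#' @param sep Field separator.
#' @return A \linkS4class{FootprintTable}.
#' @examples
#' fp <- readFootprintTable(thylakoidDataFile("footprints.csv"))
#' identical(footprintAreas(fp), footprintAreas(defaultFootprints()))
#' @export
readFootprintTable <- function(path, sep = ",") {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path)
    cut <- grep("^\\[subunits\\]", lines)
    head <- if (length(cut)) lines[seq_len(cut[1L] - 1L)] else lines
    areasDf <- utils::read.table(text = head, header = TRUE, sep = sep,
                                 stringsAsFactors = FALSE)
    if (!all(c("name", "area_nm2") %in% colnames(areasDf)))
        stop("footprint file needs columns name, area_nm2", call. = FALSE)
    subunits <- if (length(cut)) {
        utils::read.table(text = lines[(cut[1L] + 1L):length(lines)],
                          header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
    } else {
        data.frame(subunit = character(), complex = character(),
                   stoichiometry = numeric())
    }
    new("FootprintTable",
        areas = stats::setNames(areasDf$area_nm2, areasDf$name),
        subunits = subunits)
}
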