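#' Read a morphometric table
#'
#' Reads a delimiter-separated table of per-time-point 3D-reconstruction
#' morphometrics. Expected columns (a subset is fine): \code{time_h},
#' \code{chloroplast_volume_um3}, \code{thylakoid_surface_um2} (per
#' chloroplast), \code{grana_percent}, \code{thylakoid_envelope_ratio},
#' \code{chloroplasts_per_cell}, \code{cell_volume_um3},
#' \code{cells_per_seedling}, plus optional \code{*_sd} dispersion
#' columns. The packaged \code{morphometrics.csv} transcribes the
#' reference measurements at T0, T4, T24 and T96.
#'
#' @param path Path to the file.
#' @param sep Field separator.
#' @return data.frame sorted by \code{time_h}.
#' @examples
#' readMorphometricTable(thylakoidDataFile("morphometrics.csv"))
#' @export
readMorphometricTable <- function(path, sep = ",") {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    if (!"time_h" %in% colnames(df))
        stop("morphometric table needs a time_h column", call. = FALSE)
    num <- setdiff(colnames(df), "time_h")
    bad <- vapply(num, function(cn) any(!is.na(df[[cn]]) & df[[cn]] < 0),
                  logical(1L))
    if (any(bad))
        stop("negative morphometric value(s) in column(s): ",
             paste(num[bad], collapse = ", "), call. = FALSE)
    df[order(df$time_h), , drop = FALSE]
}

#' Total thylakoid surface per chloroplast including grana
#'
#' 3D reconstructions measure the thylakoid surface exposed to the stroma;
#' grana lamellae add surface beyond it. Total per-chloroplast surface is
#' stroma surface times (1 + grana_percent / 100). With
#' \code{grana_percent = 0} the stroma-exposed surface is returned
#' unchanged.
#'
#' @param stromaSurface Stroma-exposed surface, \eqn{\mu m^2} (>= 0).
#' @param granaPercent Extra surface contributed by grana lamellae, in
#'   percent (>= 0, default 0).
#' @return Surface in \eqn{\mu m^2} per chloroplast.
#' @examples
#' thylakoidSurfacePerChloroplast(100, 50) # 150
#' @export
thylakoidSurfacePerChloroplast <- function(stromaSurface, granaPercent = 0) {
    if (any(!is.na(stromaSurface) & stromaSurface < 0) ||
        any(!is.na(granaPercent) & granaPercent < 0))
        stop("stroma surface and grana percent must be >= 0", call. = FALSE)
    stromaSurface * (1 + granaPercent / 100)
}

#' Scale a per-chloroplast surface to the seedling
#'
#' Per-seedling thylakoid surface is the product of the per-chloroplast
#' surface, the number of chloroplasts per cell, and the number of
#' mesophyll/palisade cells per seedling.
#'
#' @param surfacePerChloroplast \eqn{\mu m^2} per chloroplast.
#' @param chloroplastsPerCell Chloroplast count per cell.
#' @param cellsPerSeedling Cell count per seedling (default 3000, constant
#'   during cotyledon development).
#' @return Surface in \eqn{\mu m^2} per seedling.
#' @examples
#' surfacePerSeedling(2086, 112, 3000) / 1e6 # ~701 mm2
#' @export
surfacePerSeedling <- function(surfacePerChloroplast, chloroplastsPerCell,
                               cellsPerSeedling = 3000) {
    args <- c(surfacePerChloroplast, chloroplastsPerCell, cellsPerSeedling)
    if (any(!is.na(args) & args < 0))
        stop("all factors must be >= 0", call. = FALSE)
    surfacePerChloroplast * chloroplastsPerCell * cellsPerSeedling
}

#' Estimate cells per seedling from cotyledon volume
#'
#' Mesophyll (palisade + spongy) cells occupy about half the cotyledon
#' volume; dividing that volume by the mean cell volume gives the cell
#' count, reported as a rounded integer (but see Details).
#'
#' @details Counts are rounded for reporting; downstream scaling keeps the
#' real-valued product to avoid compounding rounding.
#'
#' @param cotyledonVolume Total cotyledon volume, \eqn{\mu m^3}.
#' @param mesophyllFraction Fraction of the cotyledon occupied by
#'   mesophyll cells, in (0, 1]; default 0.5.
#' @param meanCellVolume Mean mesophyll cell volume, \eqn{\mu m^3} (> 0).
#' @return Rounded cell count.
#' @examples
#' cellsPerSeedling(3.66e7, 0.5, 6103) # ~3000
#' @export
cellsPerSeedling <- function(cotyledonVolume, mesophyllFraction = 0.5,
                             meanCellVolume) {
    if (any(meanCellVolume <= 0))
        stop("mean cell volume must be > 0", call. = FALSE)
    if (any(mesophyllFraction <= 0 | mesophyllFraction > 1))
        stop("mesophyll fraction must lie in (0, 1]", call. = FALSE)
    if (any(cotyledonVolume < 0))
        stop("cotyledon volume must be >= 0", call. = FALSE)
    round(cotyledonVolume * mesophyllFraction / meanCellVolume)
}

#' Fold change between two values
#'
#' @param later,earlier Numeric values; \code{earlier} must be > 0.
#' @return \code{later / earlier}.
#' @examples
#' foldChange(1476, 67) # ~22
#' @export
foldChange <- function(later, earlier) {
    if (any(earlier <= 0))
        stop("earlier value must be > 0", call. = FALSE)
    later / earlier
}

#' Percent increase between two values
#'
#' @param later,earlier Numeric values; \code{earlier} must be > 0.
#' @return 100 * (later - earlier) / earlier.
#' @examples
#' percentIncrease(2086, 1476) # ~41
#' @export
percentIncrease <- function(later, earlier) {
    if (any(earlier <= 0))
        stop("earlier value must be > 0", call. = FALSE)
    100 * (later - earlier) / earlier
}

#' Protein-to-galactolipid surface ratio
#'
#' Ratio of the summed photosynthetic-complex surface to the summed
#' MGDG + DGDG surface at each time point of a breakdown.
#'
#' @param breakdown A \linkS4class{SurfaceBreakdown}.
#' @return Numeric vector, one ratio per time point.
#' @export
proteinLipidSurfaceRatio <- function(breakdown) {
    comp <- surfaceComponents(breakdown)
    lipidCols <- colnames(comp) %in% c("MGDG", "DGDG")
    lip <- rowSums(comp[, lipidCols, drop = FALSE])
    if (any(lip <= 0))
        stop("zero galactolipid surface at time point(s) ",
             paste(breakdown@time_h[lip <= 0], collapse = ", "),
             call. = FALSE)
    stats::setNames(rowSums(comp[, !lipidCols, drop = FALSE]) / lip,
                    breakdown@time_h)
}

#' MGDG/DGDG amount ratio
#'
#' Ratio of the summed amounts of all MGDG species to all DGDG species.
#'
#' @param species data.frame with columns \code{name} and \code{amount}
#'   (nmol/seedling) at one time point.
#' @return The MGDG/DGDG ratio.
#' @examples
#' mgdgDgdgRatio(data.frame(
#'     name = c("MGDG 18:3/18:3", "MGDG 18:3/16:3", "DGDG 18:3/18:3"),
#'     amount = c(2, 1, 1))) # 3
#' @export
mgdgDgdgRatio <- function(species) {
    parsed <- parseLipidSpecies(species$name)
    mg <- sum(species$amount[parsed$headgroup == "MGDG"], na.rm = TRUE)
    dg <- sum(species$amount[parsed$headgroup == "DGDG"], na.rm = TRUE)
    if (dg <= 0)
        stop("zero total DGDG amount", call. = FALSE)
    mg / dg
}

#' Maximum quantum yield of photosystem II
#'
#' Fv/Fm = (Fm - Fo) / Fm from dark-adapted chlorophyll fluorescence; a
#' fully functional PSII reaches about 0.8.
#'
#' @param fo Minimal fluorescence in the dark-adapted state (0 <= fo <=
#'   fm).
#' @param fm Maximal fluorescence in the dark-adapted state (> 0).
#' @return Fv/Fm in [0, 1].
#' @examples
#' fvFm(0.2, 1.0) # 0.8
#' @export
fvFm <- function(fo, fm) {
    if (any(fm <= 0))
        stop("fm must be > 0", call. = FALSE)
    if (any(fo < 0 | fo > fm))
        stop("fo must satisfy 0 <= fo <= fm", call. = FALSE)
    (fm - fo) / fm
}

#' Morphometric per-seedling surface table
#'
#' Applies [thylakoidSurfacePerChloroplast()] and [surfacePerSeedling()]
#' to every row of a morphometric table.
#'
#' @param morpho data.frame as from [readMorphometricTable()], with
#'   columns \code{time_h}, \code{thylakoid_surface_um2},
#'   \code{chloroplasts_per_cell}, optionally \code{grana_percent} and
#'   \code{cells_per_seedling}.
#' @param cellsPerSeedling Fallback cell count when the table has no
#'   \code{cells_per_seedling} column (default 3000).
#' @return data.frame with columns \code{time_h},
#'   \code{s_per_chloroplast_um2}, \code{s_per_seedling_um2},
#'   \code{s_per_seedling_mm2}. Rows lacking a surface or chloroplast
#'   count are dropped.
#' @examples
#' m <- readMorphometricTable(thylakoidDataFile("morphometrics.csv"))
#' morphometricSurfaceTable(m)
#' @export
morphometricSurfaceTable <- function(morpho, cellsPerSeedling = 3000) {
    g <- if ("grana_percent" %in% colnames(morpho) &&
             any(!is.na(morpho$grana_percent)))
        ifelse(is.na(morpho$grana_percent), 0, morpho$grana_percent)
    else rep(0, nrow(morpho))
    ncells <- if ("cells_per_seedling" %in% colnames(morpho))
        ifelse(is.na(morpho$cells_per_seedling), cellsPerSeedling,
               morpho$cells_per_seedling)
    else rep(cellsPerSeedling, nrow(morpho))
    perCp <- thylakoidSurfacePerChloroplast(morpho$thylakoid_surface_um2, g)
    perSeedling <- surfacePerSeedling(perCp, morpho$chloroplasts_per_cell,
                                      ncells)
    out <- data.frame(time_h = morpho$time_h,
                      s_per_chloroplast_um2 = perCp,
                      s_per_seedling_um2 = perSeedling,
                      s_per_seedling_mm2 = perSeedling / 1e6)
    out[!is.na(out$s_per_seedling_um2), , drop = FALSE]
}
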