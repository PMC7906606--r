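## Package-wide canonical units: time in hours, amounts in nmol/seedling,
## molecular footprints in nm^2, surfaces in um^2 (1 um^2 = 1e6 nm^2),
## volumes in um^3.

.AVOGADRO <- 6.02214076e23      # molecules per mol
.NM2_PER_UM2 <- 1e6
.BILAYER_DIVISOR <- 2           # lipids populate both membrane leaflets

#' Physical constants used in surface accounting
#'
#' The Avogadro constant, the bilayer divisor applied to lipid amounts
#' (each lipid molecule contributes to one of the two membrane leaflets,
#' so the stroma-exposed surface is half the summed molecular area), and
#' the nm\eqn{^2} to \eqn{\mu m^2} conversion. The bilayer divisor applies
#' to lipids only; complex footprints are already stroma-exposed areas.
#'
#' @return Named list: \code{avogadro}, \code{bilayer_divisor},
#'   \code{nm2_per_um2}.
#' @examples
#' physicalConstants()$avogadro
#' @export
physicalConstants <- function() {
    list(avogadro = .AVOGADRO,
         bilayer_divisor = .BILAYER_DIVISOR,
         nm2_per_um2 = .NM2_PER_UM2)
}

#' Default molecular footprint table
#'
#' Literature footprints for the quantified thylakoid components: the
#' minimal molecular areas of MGDG (0.82 nm\eqn{^2}) and DGDG
#' (0.64 nm\eqn{^2}), and the stroma-exposed areas of the PSII-LHCII
#' supercomplex (19 x 26 nm = 494 nm\eqn{^2}), cytochrome b6f
#' (90 x 55 A = 49.5 nm\eqn{^2}) and PSI (20 x 15 nm = 300 nm\eqn{^2}),
#' with the 1:1 marker-subunit mapping PsbA -> PSII-LHCII,
#' PetC -> Cyt b6f, PsaC -> PSI.
#'
#' @return A \linkS4class{FootprintTable}.
#' @examples
#' footprintAreas(defaultFootprints())
#' @export
defaultFootprints <- function() {
    new("FootprintTable",
        areas = c("MGDG" = 0.82, "DGDG" = 0.64, "PSII-LHCII" = 494,
                  "Cyt b6f" = 49.5, "PSI" = 300),
        subunits = data.frame(
            subunit = c("PsbA", "PetC", "PsaC"),
            complex = c("PSII-LHCII", "Cyt b6f", "PSI"),
            stoichiometry = c(1, 1, 1)))
}

#' Reference thylakoid/envelope surface ratios
#'
#' The thylakoid-to-envelope membrane surface ratio measured on 3D
#' reconstructions at T4 (1.02), T24 (7.37) and T96 (6.83). Used to derive
#' the envelope share of the galactolipid pool at each time point; see
#' [envelopeFractionAt()].
#'
#' @return data.frame with columns \code{time_h}, \code{ratio}.
#' @export
referenceEnvelopeRatios <- function() {
    data.frame(time_h = c(4, 24, 96), ratio = c(1.02, 7.37, 6.83))
}

#' Reference per-component surface table as a SurfaceBreakdown
#'
#' Loads the packaged per-component surface table (MGDG, DGDG, PSII,
#' cytochrome b6f and PSI surfaces per seedling at the eight measured
#' time points) into a \linkS4class{SurfaceBreakdown} with epsilon 0.
#' These are the published downstream values; recomputing them from the
#' amount fixtures is what the surface-accounting functions are for.
#'
#' @return A \linkS4class{SurfaceBreakdown}.
#' @examples
#' surfaceTotal(referenceComponentSurfaces())
#' @export
referenceComponentSurfaces <- function() {
    df <- utils::read.csv(thylakoidDataFile("component_surfaces.csv"))
    times <- sort(unique(df$time_h))
    comps <- unique(df$component)
    m <- matrix(NA_real_, length(times), length(comps),
                dimnames = list(NULL, comps))
    m[cbind(match(df$time_h, times), match(df$component, comps))] <-
        df$surface_um2
    new("SurfaceBreakdown", time_h = times, components = m,
        epsilon = rep(0, length(times)), total = rowSums(m),
        envelopeFraction = rep(0, length(times)))
}

#' Path to a packaged reference data file
#'
#' Convenience wrapper around \code{system.file()} for the plain-text
#' reference tables shipped with the package (morphometrics, analyte
#' amounts, component surfaces, footprints).
#'
#' @param file File name under \code{extdata}, e.g.
#'   \code{"morphometrics.csv"}. With no argument, lists available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' thylakoidDataFile()
#' thylakoidDataFile("footprints.csv")
#' @export
thylakoidDataFile <- function(file = NULL) {
    if (is.null(file))
        return(dir(system.file("extdata", package = "ThylakoidExpansion")))
    path <- system.file("extdata", file, package = "ThylakoidExpansion")
    if (!nzchar(path))
        stop("no packaged data file named '", file, "'", call. = FALSE)
    path
}
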