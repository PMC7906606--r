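#' Time points of an object
#'
#' @param x An object with a time dimension.
#' @return Sorted unique time points in hours.
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' Surface components of a breakdown
#'
#' @param x A \linkS4class{SurfaceBreakdown}.
#' @return Matrix of per-component surfaces (\eqn{\mu m^2}/seedling).
#' @export
setGeneric("surfaceComponents",
    function(x) standardGeneric("surfaceComponents"))

#' Total surface of a breakdown
#'
#' @param x A \linkS4class{SurfaceBreakdown}.
#' @return Numeric vector of total surfaces (\eqn{\mu m^2}/seedling).
#' @export
setGeneric("surfaceTotal", function(x) standardGeneric("surfaceTotal"))

#' Footprint areas
#'
#' @param x A \linkS4class{FootprintTable}.
#' @return Named numeric vector of areas (nm\eqn{^2}/molecule).
#' @export
setGeneric("footprintAreas", function(x) standardGeneric("footprintAreas"))

#' Subunit-to-complex map
#'
#' @param x A \linkS4class{FootprintTable}.
#' @return data.frame with columns subunit, complex, stoichiometry.
#' @export
setGeneric("subunitMap", function(x) standardGeneric("subunitMap"))
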