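#' @describeIn AnalyteExperiment-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "AnalyteExperiment", function(object) {
    cls <- table(rowData(object)$analyte_class)
    cat("AnalyteExperiment:", nrow(object), "analytes (",
        paste(names(cls), cls, sep = "=", collapse = ", "),
        ") x", ncol(object), "samples\n")
    cat("  time points (h):",
        paste(timePoints(object), collapse = ", "), "\n")
    cat("  replicates:",
        paste(sort(unique(colData(object)$replicate)), collapse = ", "),
        "\n")
})

#' @describeIn FootprintTable Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "FootprintTable", function(object) {
    cat("FootprintTable (nm2/molecule):\n")
    print(object@areas)
    cat("subunit map:\n")
    print(object@subunits, row.names = FALSE)
})

#' @describeIn SurfaceBreakdown Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "SurfaceBreakdown", function(object) {
    cat("SurfaceBreakdown:", length(object@time_h),
        "time point(s), um2/seedling\n")
    print(format(as.data.frame(object), digits = 4), row.names = FALSE)
})

#' @describeIn Logistic4PFit Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "Logistic4PFit", function(object) {
    cat("Four-parameter logistic fit",
        if (isTRUE(object@convergence$degenerate)) "(degenerate)" else "",
        "\n")
    est <- rbind(estimate = object@coefficients, se = object@se)
    print(signif(est, 5))
    cat("residual SD:", signif(object@sigma, 5),
        "| converged:", isTRUE(object@convergence$converged), "\n")
})

#' @describeIn MixedLogistic4PFit Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "MixedLogistic4PFit", function(object) {
    cat("Mixed-effects 4PL fit (method:", object@method, ")\n")
    cat("fixed effects:\n")
    print(signif(object@fixed, 5))
    cat("between-replicate SD (random:",
        paste(object@randomized, collapse = ", "), "):\n")
    print(signif(object@randomSd, 5))
    cat("residual SD:", signif(object@residualSd, 5), "\n")
})
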