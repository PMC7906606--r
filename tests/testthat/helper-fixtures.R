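## Shared fixtures built in code.

fixturePath <- function(file) thylakoidDataFile(file)

subunitAE <- function() readAmountTable(fixturePath("subunit_amounts.csv"))

morphoTable <- function() readMorphometricTable(
    fixturePath("morphometrics.csv"))

## Published per-component surfaces (um2/seedling) keyed by component,
## then time in hours, for spot checks.
refSurface <- function(component, time_h) {
    df <- utils::read.csv(fixturePath("component_surfaces.csv"))
    df$surface_um2[df$component == component & df$time_h == time_h]
}

## Small long-format amount table for parser tests.
tinyAmountDf <- function() data.frame(
    analyte = c("MGDG 18:3/16:3", "MGDG 18:3/16:3", "PsbA"),
    time_h = c(0, 4, 0), replicate = 1L, amount = c(0.1, 0.2, 1e-5))

writeTempCsv <- function(df) {
    path <- tempfile(fileext = ".csv")
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
}
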