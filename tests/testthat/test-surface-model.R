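test_that("molar amounts convert through the Avogadro constant", {
    expect_equal(amountToMolecules(0), 0)
    expect_equal(amountToMolecules(1), 6.02214076e14)
    expect_equal(amountToMolecules(6.2e-4), 3.734e11, tolerance = 1e8 / 3.7e11)
    expect_error(amountToMolecules(-1), ">= 0")
})

test_that("complex surfaces reproduce the published per-seedling values", {
    ## marker subunit x footprint, 1:1 stoichiometry, nm2 -> um2
    expect_equal(complexSurface(6.9e-6, "PsbA"), 2.05e6, tolerance = 0.005)
    expect_equal(complexSurface(7.3e-5, "PsaC"), 1.32e7, tolerance = 0.005)
    expect_equal(complexSurface(0, "PetC"), 0)
    expect_error(complexSurface(1e-5, "PsbZ"), "unknown subunit")
    ## stoichiometry divides the amount
    fp <- new("FootprintTable", areas = c(X = 100),
              subunits = data.frame(subunit = "sx", complex = "X",
                                    stoichiometry = 2))
    expect_equal(complexSurface(1, "sx", fp),
                 complexSurface(0.5, "sx",
                                new("FootprintTable", areas = c(X = 100),
                                    subunits = data.frame(
                                        subunit = "sx", complex = "X",
                                        stoichiometry = 1))))
})

test_that("all non-anomalous published protein surface cells reproduce", {
    ae <- subunitAE()
    m <- amountMeans(ae)
    cells <- list(
        c("PsbA", "PSII-LHCII"), c("PetC", "Cyt b6f"), c("PsaC", "PSI"))
    for (pair in cells) {
        sub <- pair[1]; comp <- pair[2]
        for (tt in as.numeric(colnames(m))) {
            amt <- m[sub, as.character(tt)]
            if (is.na(amt)) next
            if (comp == "PSI" && tt == 12) next # anomalous printed cell
            got <- complexSurface(amt, sub)
            want <- refSurface(comp, tt)
            ## printed input amounts carry 2 significant figures; the PSI
            ## T48 input (1.1E-04) is quantized by ~4.5%, putting the
            ## recomputed cell 5.3% from the printed one
            tol <- if (comp == "PSI" && tt == 48) 0.06 else 0.05
            expect_equal(got, want, tolerance = tol,
                         label = paste(comp, "at T", tt))
        }
    }
})

test_that("envelope fraction follows f = 1/(1+R) with time interpolation", {
    expect_equal(envelopeFraction(6.83), 0.1277, tolerance = 1e-4 / 0.12)
    expect_equal(envelopeFraction(1.02), 0.4950, tolerance = 1e-4 / 0.49)
    expect_lt(envelopeFraction(1e9), 1e-8)
    expect_error(envelopeFraction(0), "> 0")
    expect_error(envelopeFraction(-2), "> 0")
    ## constant extrapolation outside measured times, linear inside
    f <- envelopeFractionAt(c(0, 4, 14, 96, 200))
    expect_equal(f[1], f[2])               # before T4 -> T4 value
    expect_equal(f[4], f[5])               # after T96 -> T96 value
    rMid <- 1.02 + (7.37 - 1.02) * (14 - 4) / (24 - 4)
    expect_equal(f[3], 1 / (1 + rMid))
})

test_that("lipid class surface applies bilayer and envelope corrections", {
    one <- data.frame(name = "MGDG 18:3/16:3", amount = 1)
    expect_equal(lipidClassSurface(one, "MGDG", f = 0), 2.469e8,
                 tolerance = 0.001)
    ## envelope correction scales by (1 - f)
    expect_equal(lipidClassSurface(one, "MGDG", f = 0.2),
                 0.8 * lipidClassSurface(one, "MGDG", f = 0))
    ## only matching headgroup species are summed
    expect_equal(lipidClassSurface(one, "DGDG", f = 0), 0)
    expect_error(lipidClassSurface(one, "MGDG", f = 1), "\\[0, 1\\)")
    expect_error(lipidClassSurface(one, "MGDG", f = -0.1), "\\[0, 1\\)")
})

test_that("lipid surface is additive and matches a brute-force accumulation", {
    species <- data.frame(
        name = c("MGDG 18:3/18:3", "MGDG 18:3/16:3", "MGDG 18:3/16:1",
                 "DGDG 18:3/18:3", "DGDG 18:3/16:0"),
        amount = c(0.4, 0.9, 0.15, 0.25, 0.18))
    a <- species[1:2, ]; b <- species[3:5, ]
    expect_equal(lipidClassSurface(species, "MGDG", 0.1) +
                     lipidClassSurface(species, "DGDG", 0.1),
                 lipidClassSurface(a, "MGDG", 0.1) +
                     lipidClassSurface(b, "MGDG", 0.1) +
                     lipidClassSurface(a, "DGDG", 0.1) +
                     lipidClassSurface(b, "DGDG", 0.1))
    ## brute force: accumulate one reduced-scale molecule at a time
    unit <- 1e-3 # nmol per "molecule packet"
    for (hg in c("MGDG", "DGDG")) {
        acc <- 0
        area <- footprintAreas(defaultFootprints())[[hg]]
        parsed <- parseLipidSpecies(species$name)
        for (i in seq_len(nrow(species))) {
            if (parsed$headgroup[i] != hg) next
            for (k in seq_len(round(species$amount[i] / unit)))
                acc <- acc + amountToMolecules(unit) / 2 * area / 1e6
        }
        expect_equal(lipidClassSurface(species, hg, 0), acc,
                     tolerance = 1e-9)
    }
})

test_that("surface breakdown conserves, is monotone, and sums the terms", {
    amounts <- data.frame(
        analyte = c("MGDG 18:3/18:3", "DGDG 18:3/16:0", "PsbA", "PetC",
                    "PsaC"),
        amount = c(0.5, 0.2, 1e-4, 5e-5, 8e-5))
    sb <- totalMolecularSurface(amounts, time_h = 24, f = 0.12,
                                epsilon = 1e6)
    expect_equal(unname(surfaceTotal(sb)),
                 sum(surfaceComponents(sb)) + sb@epsilon)
    ## epsilon adds exactly
    sb2 <- totalMolecularSurface(amounts, time_h = 24, f = 0.12,
                                 epsilon = 1e6 + 123)
    expect_equal(unname(surfaceTotal(sb2) - surfaceTotal(sb)), 123)
    ## monotone in every amount
    for (i in seq_len(nrow(amounts))) {
        up <- amounts; up$amount[i] <- up$amount[i] * 1.2
        sbUp <- totalMolecularSurface(up, time_h = 24, f = 0.12,
                                      epsilon = 1e6)
        expect_gt(surfaceTotal(sbUp), surfaceTotal(sb))
    }
    ## non-increasing in the envelope fraction
    sbF <- totalMolecularSurface(amounts, time_h = 24, f = 0.3,
                                 epsilon = 1e6)
    expect_lt(surfaceTotal(sbF), surfaceTotal(sb))
    ## all amounts zero
    z <- amounts; z$amount <- 0
    expect_equal(unname(surfaceTotal(
        totalMolecularSurface(z, time_h = 0))), 0)
    ## missing component warns and contributes zero
    expect_warning(
        noPsi <- totalMolecularSurface(amounts[1:4, ], time_h = 24),
        "PSI")
    expect_equal(unname(surfaceComponents(noPsi)[, "PSI"]), 0)
})

test_that("published component surfaces sum to the printed total scale", {
    ref <- referenceComponentSurfaces()
    tot <- surfaceTotal(ref)
    expect_equal(unname(tot[["96"]]), 5.39e8, tolerance = 0.005)
    expect_true(all(diff(tot) > 0))
})

test_that("footprint file round-trips the default table exactly", {
    fp <- readFootprintTable(fixturePath("footprints.csv"))
    expect_identical(footprintAreas(fp),
                     footprintAreas(defaultFootprints()))
    expect_equal(subunitMap(fp), subunitMap(defaultFootprints()),
                 ignore_attr = TRUE)
    expect_error(readFootprintTable(tempfile()), "not found")
})

test_that("surface time course equals per-time accounting on the fixture", {
    ae <- subunitAE()
    sb <- suppressWarnings(surfaceTimecourse(ae, envelopeRatios = NULL))
    expect_equal(timePoints(sb), c(0, 4, 8, 12, 24, 48, 72, 96))
    m <- amountMeans(ae)
    direct <- complexSurface(m["PsbA", "24"], "PsbA")
    expect_equal(unname(surfaceComponents(sb)[5, "PSII-LHCII"]), direct)
})
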