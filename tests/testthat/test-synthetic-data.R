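test_that("configurations validate before any generation happens", {
    expect_s3_class(simulationConfig(seed = 1), "thylakoidSimConfig")
    expect_error(simulationConfig(timePoints = c(4, 4, 8)),
                 "strictly increasing")
    expect_error(simulationConfig(cv = -0.1), "cv")
    expect_error(simulationConfig(nReplicates = 0), "positive")
    kin <- defaultKinetics(); kin$timescale[1] <- 0
    expect_error(simulationConfig(kinetics = kin), "timescale")
    kin <- defaultKinetics(); kin$class[1] <- "mystery"
    expect_error(simulationConfig(kinetics = kin), "mystery")
    expect_error(simulateTimecourse(list()), "simulationConfig")
})

test_that("zero noise reproduces the kinetic law exactly across replicates", {
    sim <- simulateTimecourse(simulationConfig(seed = 3, cv = 0,
                                               nReplicates = 3))
    a <- SummarizedExperiment::assay(sim$amounts, "amount")
    cd <- SummarizedExperiment::colData(sim$amounts)
    for (tt in unique(cd$time_h)) {
        cols <- which(cd$time_h == tt)
        expect_equal(a[, cols[2]], a[, cols[1]])
        expect_equal(a[, cols[3]], a[, cols[1]])
        expect_equal(unname(a[, cols[1]]),
                     unname(sim$truth$amounts[, as.character(tt)]))
    }
})

test_that("the seed contract gives bit-identical tables, new noise otherwise", {
    s1 <- simulateTimecourse(simulationConfig(seed = 42))
    s2 <- simulateTimecourse(simulationConfig(seed = 42))
    s3 <- simulateTimecourse(simulationConfig(seed = 43))
    expect_identical(amountLong(s1$amounts), amountLong(s2$amounts))
    expect_identical(s1$morpho, s2$morpho)
    expect_false(identical(amountLong(s1$amounts),
                           amountLong(s3$amounts)))
    ## truth is seed-independent
    expect_identical(s1$truth$amounts, s3$truth$amounts)
    ## generation does not disturb the caller's RNG stream
    set.seed(1); before <- runif(1)
    set.seed(1); invisible(simulateTimecourse(simulationConfig(seed = 9)))
    expect_identical(runif(1), before)
})

test_that("lipid classes separate: ER leap by 12 h, PL flat until later", {
    sim <- simulateTimecourse(simulationConfig(seed = 1))
    m <- amountMeans(sim$amounts)
    kin <- sim$truth$kinetics
    er <- kin$analyte[kin$class == "ER_lipid"]
    pl <- kin$analyte[kin$class == "PL_lipid"]
    erRatio <- sum(m[er, "12"]) / sum(m[er, "8"])
    plRatio <- sum(m[pl, "12"]) / sum(m[pl, "8"])
    expect_gte(erRatio, 1.5)
    ## the PL class shows no leap: its noise-free 8-to-12 h rise is the
    ## shallow pre-onset tail, and the noisy ratio stays below the
    ## ER-class leap factor
    tr <- sim$truth$amounts
    expect_lt(sum(tr[pl, "12"]) / sum(tr[pl, "8"]), 1.15)
    expect_lt(plRatio, 1.5)
    expect_gt(erRatio, plRatio)
    ## PL rise happens after 24 h
    expect_gt(sum(m[pl, "96"]) / sum(m[pl, "24"]), 2)
    ## sequential protein onset: PsbA is well past its half-rise at 12 h
    ## while PsaC is at it
    psbaFrac <- (sim$truth$amounts["PsbA", "12"] - 6.9e-6) / 6.1e-4
    psacFrac <- (sim$truth$amounts["PsaC", "12"] - 1.0e-6) / 2.3e-4
    expect_gt(psbaFrac, psacFrac)
})

test_that("empirical replicate CV matches the configured cv", {
    cv <- 0.2
    cvs <- unlist(lapply(1:50, function(seed) {
        sim <- simulateTimecourse(simulationConfig(
            seed = seed, cv = cv, nReplicates = 4,
            timePoints = c(0, 24, 96)))
        a <- SummarizedExperiment::assay(sim$amounts, "amount")
        cd <- SummarizedExperiment::colData(sim$amounts)
        unlist(lapply(unique(cd$time_h), function(tt) {
            sub <- a[, cd$time_h == tt, drop = FALSE]
            apply(sub, 1L, function(v) sd(v) / mean(v))
        }))
    }))
    expect_equal(mean(cvs), cv, tolerance = 0.3)
})

test_that("forward surface equals the accounting model on noise-free data", {
    cfg <- simulationConfig(seed = 2, cv = 0)
    sim <- simulateTimecourse(cfg)
    fwd <- sim$truth$surface
    acc <- surfaceTimecourse(sim$amounts,
                             envelopeRatios = cfg$morpho$envelopeRatios)
    expect_equal(unname(surfaceTotal(acc)), unname(surfaceTotal(fwd)),
                 tolerance = 1e-9)
    expect_equal(surfaceComponents(acc), surfaceComponents(fwd),
                 tolerance = 1e-9)
    ## zero-amplitude kinetics give a flat baseline-implied series
    kin <- defaultKinetics(); kin$amplitude <- 0
    flat <- simulateTimecourse(simulationConfig(seed = 2, cv = 0,
                                                kinetics = kin))
    tot <- unname(surfaceTotal(flat$truth$surface))
    ## envelope interpolation varies slightly over time; each time point
    ## must match its own direct evaluation
    f <- envelopeFractionAt(cfg$timePoints)
    direct <- vapply(seq_along(f), function(i)
        unname(surfaceTotal(totalMolecularSurface(
            data.frame(analyte = kin$analyte, amount = kin$baseline),
            f = f[i]))), numeric(1))
    expect_equal(tot, direct, tolerance = 1e-12)
})

test_that("doubling all amplitudes doubles the surface gain at every time", {
    kin <- defaultKinetics()
    kin2 <- kin; kin2$amplitude <- 2 * kin$amplitude
    s1 <- simulateTimecourse(simulationConfig(seed = 4, cv = 0,
                                              kinetics = kin))
    s2 <- simulateTimecourse(simulationConfig(seed = 4, cv = 0,
                                              kinetics = kin2))
    t1 <- unname(surfaceTotal(s1$truth$surface))
    t2 <- unname(surfaceTotal(s2$truth$surface))
    base <- simulateTimecourse(simulationConfig(
        seed = 4, cv = 0,
        kinetics = within(kin, amplitude <- 0)))
    t0 <- unname(surfaceTotal(base$truth$surface))
    expect_equal(t2 - t0, 2 * (t1 - t0), tolerance = 1e-9)
})

test_that("the emitted morphometric table inverts back to the forward surface", {
    cfg <- simulationConfig(seed = 6, cv = 0, epsilon = 5e6,
                            granaPercent = 20)
    sim <- simulateTimecourse(cfg)
    tab <- morphometricSurfaceTable(sim$morpho)
    expect_equal(tab$s_per_seedling_um2,
                 unname(surfaceTotal(sim$truth$surface)) + 5e6,
                 tolerance = 1e-9)
})
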