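test_that("the 4PL evaluates with inflection symmetry and asymptotes", {
    p <- c(a = 1e7, d = 5e8, tmid = 30, tau = 10)
    expect_equal(logistic4pEval(30, p["a"], p["d"], p["tmid"], p["tau"]),
                 (1e7 + 5e8) / 2, ignore_attr = TRUE)
    expect_equal(
        logistic4pEval(30 + 50 * 10, p["a"], p["d"], p["tmid"], p["tau"]),
        5e8, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(logistic4pEval(c(-10, 55, 300), 2, 2, 30, 10),
                 rep(2, 3))
    expect_error(logistic4pEval(0, 1, 2, 3, 0), "tau")
})

test_that("the 4PL is monotone non-decreasing whenever d >= a", {
    set.seed(101)
    for (i in 1:50) {
        a <- runif(1, 0, 1e8); d <- a + runif(1, 0, 1e9)
        tmid <- runif(1, -20, 120); tau <- runif(1, 0.1, 50)
        t <- sort(runif(20, -50, 150))
        s <- logistic4pEval(t, a, d, tmid, tau)
        expect_true(all(diff(s) >= 0))
    }
})

test_that("noise-free data recover the generating parameters", {
    t <- c(0, 4, 8, 12, 24, 48, 72, 96)
    truth <- c(a = 1e7, d = 5e8, tmid = 30, tau = 10)
    s <- logistic4pEval(t, truth["a"], truth["d"], truth["tmid"],
                        truth["tau"])
    fit <- fitLogistic4P(t, s)
    expect_true(fit@convergence$converged)
    expect_equal(coef(fit), truth, tolerance = 1e-6)
    expect_lt(fit@rss, (1e-10 * max(s))^2 * length(s))
    ## residual-free predictions
    expect_equal(predict(fit), s, tolerance = 1e-10)
})

test_that("estimator error shrinks with the noise level and is small at CV 10%", {
    t <- c(0, 4, 8, 12, 24, 48, 72, 96)
    truth <- c(a = 2e7, d = 6e8, tmid = 28, tau = 9)
    mu <- logistic4pEval(t, truth["a"], truth["d"], truth["tmid"],
                         truth["tau"])
    errAt <- function(cv, nSeeds = 25) {
        vapply(seq_len(nSeeds), function(seed) {
            set.seed(seed)
            tt <- rep(t, 3)
            s <- rep(mu, 3) * exp(rnorm(24, 0, sqrt(log1p(cv^2))))
            abs(coef(fitLogistic4P(tt, s))[["d"]] - truth[["d"]]) /
                truth[["d"]]
        }, numeric(1))
    }
    e10 <- errAt(0.10)
    expect_lt(median(e10), 0.05)
    ## bias vanishes as noise vanishes
    medians <- c(median(errAt(0.15)), median(errAt(0.05)),
                 median(errAt(0.01)))
    expect_true(all(diff(medians) < 0))
    expect_lt(medians[3], 0.005)
})

test_that("flat input gives a flagged degenerate fit, small n errors", {
    t <- c(0, 4, 8, 12, 24)
    fit <- fitLogistic4P(t, rep(3.3, 5))
    expect_true(fit@convergence$degenerate)
    expect_false(fit@convergence$converged)
    expect_equal(coef(fit)[["a"]], coef(fit)[["d"]])
    expect_error(fitLogistic4P(c(0, 4, 8), c(1, 2, 3)), ">= 5")
})

test_that("the fit is scale-equivariant in the surface unit", {
    t <- c(0, 4, 8, 12, 24, 48, 72, 96)
    set.seed(5)
    s <- logistic4pEval(t, 1e7, 5e8, 30, 10) * exp(rnorm(8, 0, 0.05))
    f1 <- coef(fitLogistic4P(t, s))
    f2 <- coef(fitLogistic4P(t, 1000 * s))
    expect_equal(f2[["a"]], 1000 * f1[["a"]], tolerance = 1e-6)
    expect_equal(f2[["d"]], 1000 * f1[["d"]], tolerance = 1e-6)
    expect_equal(f2[["tmid"]], f1[["tmid"]], tolerance = 1e-6)
    expect_equal(f2[["tau"]], f1[["tau"]], tolerance = 1e-6)
})

test_that("mixed fit reduces to the pooled fit at zero replicate variance", {
    t <- rep(c(0, 4, 8, 12, 24, 48, 72, 96), 3)
    r <- rep(1:3, each = 8)
    s <- logistic4pEval(t, 1e7, 5e8, 30, 10)
    mf <- fitLogistic4PMixed(t, s, r)
    expect_equal(mf@fixed, coef(mf@pooled), tolerance = 1e-10)
    expect_equal(unname(mf@randomSd), rep(0, 4), tolerance = 1e-8)
    expect_equal(predict(mf, newtimes = c(0, 24, 96)),
                 predict(mf@pooled, newtimes = c(0, 24, 96)),
                 tolerance = 1e-8)
})

test_that("replicate-level asymptote offsets are recovered as random effects", {
    t8 <- c(0, 4, 8, 12, 24, 48, 72, 96)
    offs <- c(0.9, 1.0, 1.1)
    t <- rep(t8, 3); r <- rep(1:3, each = 8)
    s <- unlist(lapply(offs, function(k)
        logistic4pEval(t8, 1e7, 5e8 * k, 30, 10)))
    mf <- fitLogistic4PMixed(t, s, r)
    expect_gt(mf@randomSd[["d"]], 0)
    expect_equal(mf@fixed[["d"]], 5e8, tolerance = 0.05)
    ## per-replicate offsets reproduce the imposed ordering
    expect_true(all(diff(mf@perReplicate[, "d"]) > 0))
    ## the joint nlme estimator agrees on clearly separated replicates
    set.seed(9)
    sN <- s * exp(rnorm(24, 0, 0.02))
    mfN <- fitLogistic4PMixed(t, sN, r, method = "nlme")
    expect_equal(mfN@fixed[["d"]], 5e8, tolerance = 0.05)
})

test_that("a single replicate falls back to the pooled fit with a warning", {
    t <- c(0, 4, 8, 12, 24, 48, 72, 96)
    s <- logistic4pEval(t, 1e7, 5e8, 30, 10)
    expect_warning(mf <- fitLogistic4PMixed(t, s, rep(1, 8)), "single")
    expect_true(mf@convergence$pooledFallback)
    expect_equal(mf@fixed, coef(mf@pooled))
    expect_error(
        fitLogistic4PMixed(t, s, c(1, 1, 1, 1, 2, 2, 2, 2)), ">= 5")
    expect_error(
        fitLogistic4PMixed(rep(t, 2), rep(s, 2), rep(1:2, each = 8),
                           randomized = c("a", "d")), "exactly 3")
})

test_that("model-vs-morphometry comparison flags by scaled residual", {
    t <- c(4, 24, 96)
    fit <- fitLogistic4P(c(0, 4, 8, 12, 24, 48, 72, 96),
                         logistic4pEval(c(0, 4, 8, 12, 24, 48, 72, 96),
                                        1e7, 5e8, 30, 10))
    ## identical series: all agree, ratio 1
    morpho <- data.frame(time_h = t,
                         s_per_seedling_um2 = predict(fit, newtimes = t))
    cmp <- compareModelMorpho(fit, morpho)
    expect_equal(cmp$ratio, rep(1, 3))
    expect_equal(cmp$flag, rep("agree", 3))
    ## a zero morpho row is flagged invalid, not an error
    morpho$s_per_seedling_um2[2] <- 0
    cmp2 <- compareModelMorpho(fit, morpho)
    expect_equal(cmp2$flag[2], "invalid")
    expect_true(is.na(cmp2$ratio[2]))
    ## no overlap / no valid values error
    expect_error(compareModelMorpho(
        fit, data.frame(time_h = 1, s_per_seedling_um2 = 0)), "valid")
    expect_error(compareModelMorpho(
        fit, data.frame(time_h = numeric(),
                        s_per_seedling_um2 = numeric())), "time points")
})
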