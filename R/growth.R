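#' Evaluate the four-parameter logistic growth curve
#'
#' S(t) = a + (d - a) / (1 + exp((tmid - t) / tau)): lower asymptote
#' \code{a}, upper asymptote \code{d}, inflection time \code{tmid} (where
#' the curve passes (a + d)/2 exactly), timescale \code{tau} > 0. The
#' curve is strictly increasing in t whenever d > a.
#'
#' @param t Numeric times (hours).
#' @param a,d Lower and upper asymptotes (\eqn{\mu m^2}/seedling).
#' @param tmid Inflection time (hours).
#' @param tau Timescale (hours), > 0.
#' @return Surface values at \code{t}.
#' @examples
#' logistic4pEval(24, a = 1e7, d = 5e8, tmid = 30, tau = 10)
#' @export
logistic4pEval <- function(t, a, d, tmid, tau) {
    if (any(tau <= 0))
        stop("tau must be > 0", call. = FALSE)
    a + (d - a) / (1 + exp((tmid - t) / tau))
}

## Deterministic self-start: asymptotes from the data range, inflection
## from the first linear-interpolated crossing of the half range,
## timescale a quarter of the time span.
.logistic4pInit <- function(t, s) {
    o <- order(t)
    t <- t[o]; s <- s[o]
    a0 <- min(s); d0 <- max(s)
    half <- (a0 + d0) / 2
    above <- s >= half
    i <- which(above)[1L]
    tmid0 <- if (is.na(i) || i == 1L) stats::median(t) else {
        t[i - 1L] + (half - s[i - 1L]) / (s[i] - s[i - 1L]) *
            (t[i] - t[i - 1L])
    }
    tau0 <- (max(t) - min(t)) / 4
    c(a = a0, d = d0, tmid = tmid0, tau = max(tau0, 1e-6))
}

.degenerateFit <- function(t, s, message) {
    p <- c(a = mean(s), d = mean(s), tmid = mean(range(t)),
           tau = max(diff(range(t)) / 4, 1e-6))
    fitted <- rep(p[["a"]], length(t))
    new("Logistic4PFit",
        coefficients = p,
        se = stats::setNames(rep(NA_real_, 4), names(p)),
        data = data.frame(time = t, surface = s),
        rss = sum((s - fitted)^2),
        sigma = stats::sd(s),
        convergence = list(converged = FALSE, iterations = 0L,
                           message = message, degenerate = TRUE))
}

#' Fit a four-parameter logistic curve to surface-versus-time data
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the 4PL to surface
#' measurements over time, with a deterministic self-start (asymptotes
#' from the data range, inflection from the first half-range crossing,
#' timescale a quarter of the time span). Non-convergence and flat
#' (degenerate, d = a) inputs are flagged in the result rather than
#' raising.
#'
#' @param time Numeric times (hours), >= 5 points.
#' @param surface Numeric surfaces (\eqn{\mu m^2}/seedling).
#' @param weights Optional non-negative case weights.
#' @param start Optional named starting values overriding the self-start.
#' @param maxIter Maximum optimizer iterations.
#' @return A \linkS4class{Logistic4PFit}.
#' @examples
#' t <- c(0, 4, 8, 12, 24, 48, 72, 96)
#' s <- logistic4pEval(t, 1e7, 5e8, 30, 10)
#' coef(fitLogistic4P(t, s))
#' @export
fitLogistic4P <- function(time, surface, weights = NULL, start = NULL,
                          maxIter = 1000L) {
    keep <- !is.na(time) & !is.na(surface)
    time <- time[keep]; surface <- surface[keep]
    if (length(time) < 5)
        stop("need >= 5 (time, surface) points to fit a 4PL", call. = FALSE)
    if (diff(range(surface)) <= 1e-12 * max(abs(surface), 1))
        return(.degenerateFit(time, surface, "constant surface data"))
    if (is.null(start))
        start <- .logistic4pInit(time, surface)
    if (is.null(weights))
        weights <- rep(1, length(time))
    df <- data.frame(t = time, s = surface, w = weights)
    fit <- tryCatch(
        minpack.lm::nlsLM(
            s ~ a + (d - a) / (1 + exp((tmid - t) / tau)),
            data = df, start = as.list(start), weights = df$w,
            control = minpack.lm::nls.lm.control(
                maxiter = maxIter, ftol = 1e-15, ptol = 1e-15)),
        error = function(e) e)
    if (inherits(fit, "error"))
        return(.degenerateFit(time, surface, conditionMessage(fit)))
    p <- stats::coef(fit)[c("a", "d", "tmid", "tau")]
    if (!is.finite(p[["tau"]]) || p[["tau"]] <= 0)
        return(.degenerateFit(time, surface,
                              "optimizer left the tau > 0 domain"))
    if (p[["d"]] < p[["a"]]) {
        ## the 4PL is symmetric under (a, d, tau) -> (d, a, -tau); report
        ## the increasing-branch parameterization
        p <- c(a = p[["d"]], d = p[["a"]], tmid = p[["tmid"]],
               tau = -p[["tau"]])
        if (p[["tau"]] <= 0)
            return(.degenerateFit(time, surface,
                                  "optimizer left the tau > 0 domain"))
    }
    sm <- tryCatch(summary(fit), error = function(e) NULL)
    se <- if (is.null(sm)) stats::setNames(rep(NA_real_, 4), names(p))
          else sm$coefficients[c("a", "d", "tmid", "tau"), "Std. Error"]
    if (p[["a"]] != stats::coef(fit)[["a"]])
        se <- se[c(2L, 1L, 3L, 4L)]
    conv <- fit$convInfo
    new("Logistic4PFit",
        coefficients = p,
        se = stats::setNames(as.numeric(se), names(p)),
        data = data.frame(time = time, surface = surface),
        rss = sum(stats::residuals(fit)^2),
        sigma = if (is.null(sm)) NA_real_ else sm$sigma,
        convergence = list(
            converged = isTRUE(conv$isConv),
            iterations = conv$finIter,
            message = conv$stopMessage,
            degenerate = abs(p[["d"]] - p[["a"]]) <=
                1e-8 * max(abs(p[["d"]]), 1)))
}

#' @describeIn fitLogistic4P Extract fitted 4PL coefficients.
#' @param object A \linkS4class{Logistic4PFit}.
#' @param ... Ignored.
#' @export
setMethod("coef", "Logistic4PFit", function(object, ...)
    object@coefficients)

#' Predict from a fitted 4PL
#'
#' @param object A \linkS4class{Logistic4PFit}.
#' @param newtimes Times at which to evaluate the fitted curve; defaults
#'   to the fitted data's times.
#' @param ... Ignored.
#' @return Predicted surfaces.
#' @export
setMethod("predict", "Logistic4PFit",
    function(object, newtimes = NULL, ...) {
        if (is.null(newtimes))
            newtimes <- object@data$time
        p <- object@coefficients
        logistic4pEval(newtimes, p[["a"]], p[["d"]], p[["tmid"]],
                       p[["tau"]])
    })

.twostageMixed <- function(time, surface, replicate, randomized, maxIter) {
    reps <- sort(unique(replicate))
    params <- t(vapply(reps, function(r) {
        sel <- replicate == r
        coef(fitLogistic4P(time[sel], surface[sel], maxIter = maxIter))
    }, numeric(4L)))
    rownames(params) <- as.character(reps)
    fixed <- colMeans(params)
    randomSd <- stats::setNames(rep(0, 4L), colnames(params))
    randomSd[randomized] <- apply(params[, randomized, drop = FALSE], 2L,
                                  stats::sd)
    offsets <- sweep(params, 2L, fixed)
    offsets[, setdiff(colnames(params), randomized)] <- 0
    resid <- unlist(lapply(seq_along(reps), function(i) {
        sel <- replicate == reps[i]
        p <- fixed + offsets[i, ]
        surface[sel] - logistic4pEval(time[sel], p[["a"]], p[["d"]],
                                      p[["tmid"]], p[["tau"]])
    }))
    list(fixed = fixed, randomSd = randomSd, perReplicate = offsets,
         residualSd = stats::sd(resid),
         convergence = list(converged = TRUE, method = "twostage",
                            message = "per-replicate fits + moment estimates",
                            pooledFallback = FALSE))
}

.nlmeMixed <- function(time, surface, replicate, randomized, start) {
    df <- data.frame(t = time, s = surface,
                     rep = factor(replicate))
    randomForm <- stats::as.formula(
        paste(paste(randomized, collapse = " + "), "~ 1 | rep"))
    fit <- nlme::nlme(
        s ~ a + (d - a) / (1 + exp((tmid - t) / tau)),
        data = df,
        fixed = a + d + tmid + tau ~ 1,
        random = randomForm,
        start = start)
    fixed <- nlme::fixef(fit)[c("a", "d", "tmid", "tau")]
    vc <- nlme::VarCorr(fit)
    randomSd <- stats::setNames(rep(0, 4L), names(fixed))
    randomSd[randomized] <-
        as.numeric(vc[randomized, "StdDev"])
    re <- nlme::ranef(fit)
    offsets <- matrix(0, nrow = nrow(re), ncol = 4L,
                      dimnames = list(rownames(re), names(fixed)))
    offsets[, colnames(re)] <- as.matrix(re)
    list(fixed = fixed, randomSd = randomSd, perReplicate = offsets,
         residualSd = fit$sigma,
         convergence = list(converged = TRUE, method = "nlme",
                            message = "nlme converged",
                            pooledFallback = FALSE))
}

#' Fit a mixed-effects four-parameter logistic model
#'
#' Fits the 4PL with fixed effects for all four parameters and
#' replicate-level random effects on three of them (by default the upper
#' asymptote, inflection time and timescale). Two estimators are
#' available: \code{"twostage"} (the default and reference
#' implementation: an unconstrained 4PL fit per replicate followed by
#' moment estimates -- fixed effects are the per-replicate means, the
#' between-replicate SDs are the moments of the randomized parameters),
#' and \code{"nlme"} (joint nonlinear mixed-effects estimation), which
#' falls back to the two-stage estimator when it fails to converge (as it
#' commonly does when the between-replicate variance is near zero). With
#' a single replicate the pooled fit is returned with a warning.
#'
#' @param time,surface Numeric measurement vectors.
#' @param replicate Replicate labels, same length; >= 5 points per
#'   replicate.
#' @param randomized Exactly three parameter names carrying random
#'   effects; default \code{c("d", "tmid", "tau")}.
#' @param method \code{"twostage"} or \code{"nlme"}.
#' @param maxIter Maximum optimizer iterations for the per-replicate and
#'   pooled fits.
#' @return A \linkS4class{MixedLogistic4PFit}.
#' @examples
#' t <- rep(c(0, 4, 8, 12, 24, 48, 72, 96), 2)
#' r <- rep(1:2, each = 8)
#' s <- logistic4pEval(t, 1e7, 5e8, 30, 10)
#' fitLogistic4PMixed(t, s, r)@fixed
#' @export
fitLogistic4PMixed <- function(time, surface, replicate,
                               randomized = c("d", "tmid", "tau"),
                               method = c("twostage", "nlme"),
                               maxIter = 1000L) {
    method <- match.arg(method)
    if (length(randomized) != 3L ||
        !all(randomized %in% c("a", "d", "tmid", "tau")))
        stop("randomized must name exactly 3 of a, d, tmid, tau",
             call. = FALSE)
    keep <- !is.na(time) & !is.na(surface) & !is.na(replicate)
    time <- time[keep]; surface <- surface[keep]
    replicate <- replicate[keep]
    pooled <- fitLogistic4P(time, surface, maxIter = maxIter)
    reps <- unique(replicate)
    if (length(reps) < 2L) {
        warning("single replicate: falling back to the pooled fit",
                call. = FALSE)
        return(new("MixedLogistic4PFit",
            fixed = coef(pooled),
            randomSd = stats::setNames(rep(0, 4L), names(coef(pooled))),
            perReplicate = matrix(0, 1L, 4L,
                dimnames = list(as.character(reps), names(coef(pooled)))),
            residualSd = pooled@sigma,
            randomized = randomized, method = "pooled", pooled = pooled,
            convergence = list(converged = pooled@convergence$converged,
                               method = "pooled",
                               message = "single replicate",
                               pooledFallback = TRUE)))
    }
    counts <- table(replicate)
    if (any(counts < 5))
        stop("every replicate needs >= 5 points; replicate(s) ",
             paste(names(counts)[counts < 5], collapse = ", "),
             " have fewer", call. = FALSE)
    res <- if (method == "nlme") {
        tryCatch(.nlmeMixed(time, surface, replicate, randomized,
                            coef(pooled)),
                 error = function(e) {
                     out <- .twostageMixed(time, surface, replicate,
                                           randomized, maxIter)
                     out$convergence$message <- paste0(
                         "nlme failed (", conditionMessage(e),
                         "); two-stage fallback used")
                     out$convergence$method <- "twostage"
                     out
                 })
    } else {
        .twostageMixed(time, surface, replicate, randomized, maxIter)
    }
    new("MixedLogistic4PFit",
        fixed = res$fixed, randomSd = res$randomSd,
        perReplicate = res$perReplicate, residualSd = res$residualSd,
        randomized = randomized, method = res$convergence$method,
        pooled = pooled, convergence = res$convergence)
}

#' Predict from a mixed 4PL fit
#'
#' @param object A \linkS4class{MixedLogistic4PFit}.
#' @param newtimes Times at which to evaluate.
#' @param replicate Optional single replicate label; when given, the
#'   replicate's parameter offsets are added to the fixed effects.
#' @param ... Ignored.
#' @return Predicted surfaces.
#' @export
setMethod("predict", "MixedLogistic4PFit",
    function(object, newtimes, replicate = NULL, ...) {
        p <- object@fixed
        if (!is.null(replicate)) {
            i <- match(as.character(replicate),
                       rownames(object@perReplicate))
            if (is.na(i))
                stop("unknown replicate ", replicate, call. = FALSE)
            p <- p + object@perReplicate[i, ]
        }
        logistic4pEval(newtimes, p[["a"]], p[["d"]], p[["tmid"]],
                       p[["tau"]])
    })

#' Compare the fitted molecular model with the morphometric estimate
#'
#' Evaluates a fitted 4PL (from the molecular surface-accounting series)
#' at the time points where a morphometric per-seedling estimate exists,
#' and flags each time point. Because the series spans two orders of
#' magnitude, agreement is judged on the absolute residual relative to
#' the scale of the series (the largest morphometric value): time points
#' whose |model - morpho| exceeds \code{scaleThreshold} of that scale are
#' flagged \code{"diverge"}, the rest \code{"agree"}. The model/morpho
#' ratio and whether it falls inside \code{band} are also reported. Rows
#' with a missing or zero morphometric value are flagged
#' \code{"invalid"}.
#'
#' @param fit A \linkS4class{Logistic4PFit}.
#' @param morpho data.frame with columns \code{time_h} and
#'   \code{s_per_seedling_um2} (as from [morphometricSurfaceTable()]).
#' @param scaleThreshold Scaled-residual threshold for the agree flag
#'   (default 0.1).
#' @param band Length-2 numeric, the ratio band reported in
#'   \code{ratio_in_band} (default c(0.5, 2)).
#' @return data.frame: \code{time_h}, \code{model_um2},
#'   \code{morpho_um2}, \code{ratio}, \code{residual_um2} (absolute),
#'   \code{scaled_residual}, \code{ratio_in_band}, \code{flag}.
#' @export
compareModelMorpho <- function(fit, morpho, scaleThreshold = 0.1,
                               band = c(0.5, 2)) {
    if (!all(c("time_h", "s_per_seedling_um2") %in% colnames(morpho)))
        stop("morpho needs columns time_h, s_per_seedling_um2",
             call. = FALSE)
    if (nrow(morpho) == 0L)
        stop("no morphometric time points to compare against",
             call. = FALSE)
    model <- predict(fit, newtimes = morpho$time_h)
    mv <- morpho$s_per_seedling_um2
    valid <- !is.na(mv) & mv > 0
    if (!any(valid))
        stop("no valid (positive) morphometric values to compare against",
             call. = FALSE)
    scale <- max(mv[valid])
    ratio <- ifelse(valid, model / mv, NA_real_)
    resid <- abs(model - mv)
    scaled <- ifelse(valid, resid / scale, NA_real_)
    flag <- ifelse(!valid, "invalid",
                   ifelse(scaled <= scaleThreshold, "agree", "diverge"))
    data.frame(time_h = morpho$time_h,
               model_um2 = model,
               morpho_um2 = mv,
               ratio = ratio,
               residual_um2 = resid,
               scaled_residual = scaled,
               ratio_in_band = valid & ratio >= band[1L] &
                   ratio <= band[2L],
               flag = flag)
}
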