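## Per-time-course kinetics: ratio normalisation, log-linear first-order
## fitting, percent decrease over a storage horizon, trapezoidal AUC.

#' @describeIn ResidueTimeCourse-class divide all concentrations by the
#'   day-0 value so the series becomes a residue ratio (1 at day 0).
#'   Idempotent; errors when day 0 is missing or non-positive.
#' @param tc a `ResidueTimeCourse`.
#' @export
setMethod("toRatios", "ResidueTimeCourse", function(tc) {
    d <- tc@data
    i0 <- which(d$day == 0)
    if (!length(i0))
        stop("normalization error: no day-0 observation")
    c0 <- d$concentration[i0[1]]
    if (!is.finite(c0) || c0 <= 0)
        stop("normalization error: day-0 concentration must be > 0")
    d$concentration <- d$concentration / c0
    initialize(tc, data = d)
})

#' @describeIn ResidueTimeCourse-class ordinary least squares of
#'   `ln(concentration)` on `day` over the uncensored positive points:
#'   `k = -slope`, `c0Hat = exp(intercept)`, half-life `ln(2)/k`
#'   (infinite, with a warning, when `k <= 0`). Censored or non-positive
#'   points are excluded with a warning.
#' @export
setMethod("fitFirstOrder", "ResidueTimeCourse", function(tc, ...) {
    d <- tc@data
    use <- !d$censored & is.finite(d$concentration) & d$concentration > 0
    if (any(!use))
        warning(sum(!use), " censored or non-positive point(s) excluded ",
                "from the first-order fit")
    d <- d[use, ]
    if (nrow(d) < 2L)
        stop("fit error: fewer than 2 usable points")
    fit <- stats::lm(log(concentration) ~ day, data = d)
    slope <- unname(stats::coef(fit)[["day"]])
    k <- -slope
    sst <- sum((log(d$concentration) - mean(log(d$concentration)))^2)
    sse <- sum(stats::residuals(fit)^2)
    r2 <- if (sst < 1e-300) {
        if (sse < 1e-300) 1 else 0
    } else max(0, min(1, 1 - sse / sst))
    if (k <= 0) {
        warning("non-positive rate constant; half-life reported as infinite")
        hl <- Inf
    } else hl <- log(2) / k
    new("FirstOrderFit", k = k,
        c0Hat = unname(exp(stats::coef(fit)[["(Intercept)"]])),
        halfLifeDays = hl, r2LogLinear = r2, nUsed = nrow(d))
})

#' @describeIn ResidueTimeCourse-class percent decrease of the residue from
#'   day 0 to `horizon`: `100 * (1 - C(horizon)/C(0))`. The concentration at
#'   the horizon is linearly interpolated when it falls between sampling
#'   days; a horizon outside the observed span is an error.
#' @param horizon evaluation day (within the observed span).
#' @export
setMethod("percentDecrease", "ResidueTimeCourse", function(tc, horizon) {
    d <- tc@data
    if (!any(d$day == 0))
        stop("percent decrease requires a day-0 observation")
    if (horizon < min(d$day) || horizon > max(d$day))
        stop("range error: horizon ", horizon,
             " outside observed span [", min(d$day), ", ", max(d$day), "]")
    c0 <- d$concentration[d$day == 0][1]
    if (c0 <= 0) stop("normalization error: day-0 concentration must be > 0")
    ch <- stats::approx(d$day, d$concentration, xout = horizon)$y
    100 * (1 - ch / c0)
})

#' @describeIn ResidueTimeCourse-class trapezoidal-rule area under the
#'   concentration curve over the observed days (no extrapolation). Censored
#'   points contribute their substituted value. Set `asRatios = TRUE` to
#'   integrate the day-0-normalised ratio curve instead.
#' @param asRatios integrate ratios rather than concentrations.
#' @param ... unused.
#' @export
setMethod("aucTrapezoid", "ResidueTimeCourse",
    function(tc, asRatios = FALSE, ...) {
        if (isTRUE(asRatios)) tc <- toRatios(tc)
        d <- tc@data
        if (nrow(d) < 2L) stop("AUC requires at least 2 points")
        new("AUCResult",
            value = pracma::trapz(d$day, d$concentration),
            nPoints = nrow(d),
            tSpan = max(d$day) - min(d$day))
    })

#' Condition-level AUC summary of a study
#'
#' Computes the trapezoidal AUC of every time course in a study, returning
#' the table consumed by [effectAnova()].
#'
#' @param tcs list of [ResidueTimeCourse-class] (e.g. from
#'   [generateStudy()]).
#' @param asRatios integrate ratio curves instead of concentrations.
#' @return `data.frame` with columns `pesticide`, `matrix`, `temperature_C`,
#'   `rh_pct`, `replicate`, `auc`.
#' @export
aucByCondition <- function(tcs, asRatios = FALSE) {
    rows <- lapply(tcs, function(tc) {
        data.frame(pesticide = tc@pesticide, matrix = tc@foodMatrix,
                   temperature_C = tc@temperatureC, rh_pct = tc@rhPct,
                   replicate = tc@replicate,
                   auc = aucTrapezoid(tc, asRatios = asRatios)@value,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Kinetic summary of a study
#'
#' First-order fit plus AUC for every time course: the per-condition
#' dissipation summary (rate constant, half-life, log-linear R2, AUC).
#'
#' @inheritParams aucByCondition
#' @return `data.frame` with one row per time course.
#' @export
kineticsSummary <- function(tcs) {
    rows <- lapply(tcs, function(tc) {
        f <- fitFirstOrder(tc)
        data.frame(pesticide = tc@pesticide, matrix = tc@foodMatrix,
                   temperature_C = tc@temperatureC, rh_pct = tc@rhPct,
                   replicate = tc@replicate, k_per_day = f@k,
                   half_life_days = f@halfLifeDays,
                   r2_loglinear = f@r2LogLinear,
                   auc = aucTrapezoid(tc)@value,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
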