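## Synthetic factorial storage studies. Stands in for unreleased raw decay
## time courses: first-order decay with a log-linear rate law in temperature
## and humidity, multiplicative lognormal assay noise, LOD censoring.

#' Construct a rate-law parameter set
#'
#' @param kRef rate constant at the reference condition, per day (> 0).
#' @param tRef,rhRef reference condition (deg C, %RH).
#' @param aT,aRH log-rate slopes in temperature and humidity (>= 0).
#' @return A [RateModelParams-class].
#' @export
rateModelParams <- function(kRef, tRef = 20, rhRef = 50, aT = 0, aRH = 0) {
    new("RateModelParams", kRef = kRef, tRef = tRef, rhRef = rhRef,
        aT = aT, aRH = aRH)
}

#' @describeIn RateModelParams-class rate constant
#'   \eqn{k(T,RH) = k_{ref} e^{a_T (T - T_{ref}) + a_{RH} (RH - RH_{ref})}}
#'   at a storage condition (vectorized).
#' @param params a `RateModelParams`.
#' @param temperatureC,rhPct storage condition.
#' @export
setMethod("rateConstant", "RateModelParams",
    function(params, temperatureC, rhPct) {
        params@kRef * exp(params@aT * (temperatureC - params@tRef) +
                          params@aRH * (rhPct - params@rhRef))
    })

#' Construct a factorial storage-study design
#'
#' Defaults reproduce the experimental layout the analysis assumes: a 4 x 4
#' factorial of 20/30/40/50 deg C by 50/60/70/80 %RH, followed for 90 days
#' in wheat or 60 days in flour, with multiplicative assay noise at CV 5%
#' (the middle of the reported assay-precision range) and an LOD of
#' 0.002 mg/kg.
#'
#' @param foodMatrix `"wheat"` or `"flour"`; sets the default horizon and
#'   sampling schedule.
#' @param temperatures,humidities factorial levels.
#' @param samplingDays increasing sampling days including 0; defaults to
#'   `0, 1, 3, 5, 7, 14, 21, 30, 45, 60` plus `75, 90` for wheat.
#' @param horizon study length in days (90 wheat, 60 flour).
#' @param replicates replicates per condition.
#' @param noiseCv assay noise CV (fraction).
#' @param lod limit of detection, mg/kg (values below are reported at
#'   `lod/2` and flagged censored).
#' @param c0 initial concentration, mg/kg.
#' @param seed integer seed; drives every noise stream of the study.
#' @return A [StudyDesign-class].
#' @export
studyDesign <- function(foodMatrix = "wheat",
                        temperatures = c(20, 30, 40, 50),
                        humidities = c(50, 60, 70, 80),
                        horizon = if (foodMatrix == "wheat") 90 else 60,
                        samplingDays =
                            c(0, 1, 3, 5, 7, 14, 21, 30, 45, 60, 75, 90),
                        replicates = 1L, noiseCv = 0.05, lod = 0.002,
                        c0 = 1, seed = 1L) {
    samplingDays <- samplingDays[samplingDays <= horizon]
    new("StudyDesign", foodMatrix = foodMatrix,
        temperatures = temperatures, humidities = humidities,
        samplingDays = samplingDays, horizon = horizon,
        replicates = as.integer(replicates), noiseCv = noiseCv,
        lod = lod, c0 = c0, seed = as.integer(seed))
}

## deterministic per-course substream seed, kept < 2^31 - 1
.courseSeed <- function(seed, index) {
    m <- 2147483647
    as.integer((as.numeric(seed) %% m + 48271 * as.numeric(index)) %% m)
}

## multiplicative lognormal noise with median 1 and CV = cv
.lognormNoise <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    sigma <- sqrt(log(1 + cv^2))
    exp(stats::rnorm(n, mean = 0, sd = sigma))
}

#' @describeIn StudyDesign-class simulate one residue decay time course at a
#'   single condition. Concentrations are
#'   `c0 * exp(-k(T, RH) * day) * eps` with `eps` lognormal (median 1,
#'   CV `noiseCv`); values below `lod` are substituted by `lod/2` and
#'   flagged censored. Deterministic given `seed`.
#' @param params a [RateModelParams-class].
#' @param temperatureC,rhPct the storage condition.
#' @param design a `StudyDesign`.
#' @param pesticide label stored on the result.
#' @param replicate replicate index stored on the result.
#' @param seed substream seed; defaults to the design seed.
#' @param ... unused.
#' @export
setMethod("generateTimecourse", "RateModelParams",
    function(params, temperatureC, rhPct, design,
             pesticide = "simulated", replicate = 1L,
             seed = design@seed, ...) {
        stopifnot(is(design, "StudyDesign"))
        days <- design@samplingDays
        if (!length(days)) stop("design has no sampling days")
        k <- rateConstant(params, temperatureC, rhPct)
        true <- design@c0 * exp(-k * days)
        if (design@noiseCv > 0) {
            set.seed(seed)
            eps <- .lognormNoise(length(days), design@noiseCv)
        } else eps <- rep(1, length(days))
        conc <- true * eps
        cens <- conc < design@lod
        conc[cens] <- design@lod / 2
        new("ResidueTimeCourse",
            pesticide = pesticide, foodMatrix = design@foodMatrix,
            temperatureC = temperatureC, rhPct = rhPct,
            replicate = as.integer(replicate),
            data = data.frame(day = days, concentration = conc,
                              censored = cens))
    })

#' @describeIn StudyDesign-class simulate the full factorial study: one time
#'   course per pesticide x temperature x humidity x replicate, with
#'   deterministic per-course noise substreams derived from the design seed
#'   (so any subset of the study is reproducible).
#' @param params for `generateStudy`, a named list of
#'   [RateModelParams-class], one per pesticide.
#' @return `generateStudy` returns a named list of
#'   [ResidueTimeCourse-class] objects.
#' @export
setMethod("generateStudy", "list",
    function(params, design, ...) {
        stopifnot(is(design, "StudyDesign"))
        if (!length(params)) stop("design error: empty pesticide list")
        if (is.null(names(params)) || any(!nzchar(names(params))))
            stop("params must be a named list (names = pesticides)")
        if (anyDuplicated(names(params)))
            stop("design error: duplicate pesticide labels")
        grid <- expand.grid(rep = seq_len(design@replicates),
                            rh = design@humidities,
                            temp = design@temperatures,
                            pest = names(params),
                            stringsAsFactors = FALSE)
        out <- vector("list", nrow(grid))
        for (i in seq_len(nrow(grid))) {
            g <- grid[i, ]
            out[[i]] <- generateTimecourse(
                params[[g$pest]], g$temp, g$rh, design,
                pesticide = g$pest, replicate = g$rep,
                seed = .courseSeed(design@seed, i))
        }
        names(out) <- sprintf("%s.%gC.%g%%.r%d",
                              grid$pest, grid$temp, grid$rh, grid$rep)
        out
    })

#' Calibrate the generator's rate law to published half-lives
#'
#' Fits `(log kRef, aT, aRH)` by least squares to
#' `log(ln 2 / half_life)` at the anchor conditions, so simulated decay
#' reproduces stated half-lives. With two or three anchors at suitable
#' conditions the fit interpolates them exactly. A slope whose factor does
#' not vary across anchors is fixed at 0; a fitted negative slope is clamped
#' to 0 with a warning (the rate law is non-decreasing in both factors).
#'
#' @param anchors `data.frame` with columns `temperature_C`, `rh_pct`,
#'   `half_life_days` (> 0).
#' @param tRef,rhRef reference condition of the returned parameter set.
#' @return A [RateModelParams-class].
#' @examples
#' a <- data.frame(temperature_C = c(20, 50), rh_pct = 60,
#'                 half_life_days = c(10.27, 6.97))
#' p <- calibrateToHalfLives(a)
#' log(2) / rateConstant(p, 20, 60)  # 10.27
#' @export
calibrateToHalfLives <- function(anchors, tRef = 20, rhRef = 50) {
    req <- c("temperature_C", "rh_pct", "half_life_days")
    if (!all(req %in% names(anchors)))
        stop("anchors must have columns ", paste(req, collapse = ", "))
    if (any(anchors$half_life_days <= 0)) stop("half-lives must be > 0")
    n <- nrow(anchors)
    if (n < 1L) stop("need at least one anchor")
    cond <- unique(anchors[, c("temperature_C", "rh_pct")])
    if (n >= 2L && nrow(cond) < 2L)
        stop("rank error: anchors lie at a single condition")
    logk <- log(log(2) / anchors$half_life_days)
    dT <- anchors$temperature_C - tRef
    dRH <- anchors$rh_pct - rhRef
    useT <- length(unique(anchors$temperature_C)) > 1L
    useRH <- length(unique(anchors$rh_pct)) > 1L
    X <- cbind(intercept = rep(1, n),
               if (useT) cbind(dT = dT),
               if (useRH) cbind(dRH = dRH))
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        stop("rank error: anchor conditions do not identify the rate law")
    beta <- qr.coef(qrX, logk)
    aT <- if (useT) beta[["dT"]] else 0
    aRH <- if (useRH) beta[["dRH"]] else 0
    if (aT < 0 || aRH < 0) {
        warning("fitted log-rate slope negative; clamped to 0 ",
                "(rate law is non-decreasing in T and RH)")
        aT <- max(aT, 0); aRH <- max(aRH, 0)
    }
    rateModelParams(kRef = exp(beta[["intercept"]]), tRef = tRef,
                    rhRef = rhRef, aT = aT, aRH = aRH)
}
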