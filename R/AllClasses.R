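## Central S4 classes. Validity methods enforce the structural invariants the
## downstream fitting and prediction code relies on.

.PESTICIDES <- c("carbendazim", "bensulfuron-methyl", "triazophos",
                 "chlorpyrifos", "carbosulfan")
.MATRICES <- c("wheat", "flour")

## canonical coefficient order of the second-order surface in (t, T, RH)
.COEF_NAMES <- c("b0", "t", "T", "RH", "t2", "T2", "RH2", "tT", "tRH", "TRH")

#' Second-order residue-ratio surface model
#'
#' A 10-coefficient quadratic polynomial giving the residue ratio (C/C0 for
#' wheat storage, C3/C2 for flour storage) as a function of storage time
#' \eqn{t} (days), temperature \eqn{T} (deg C) and relative humidity
#' \eqn{RH} (percentage points):
#' \deqn{b_0 + b_t t + b_T T + b_{RH} RH + b_{tt} t^2 + b_{TT} T^2 +
#'       b_{RHRH} RH^2 + b_{tT} tT + b_{tRH} tRH + b_{TRH} T\,RH.}
#'
#' @slot pesticide lowercase hyphenated pesticide identifier.
#' @slot foodMatrix `"wheat"` or `"flour"`.
#' @slot coefficients named numeric of length 10 in the canonical order
#'   `b0, t, T, RH, t2, T2, RH2, tT, tRH, TRH`.
#' @slot coefficientStrings the coefficients exactly as printed in the source
#'   table, for registry entries (empty for fitted models); kept so the
#'   registry is auditable digit-for-digit.
#' @slot r2Reported reported coefficient of determination, or `NA_real_`.
#' @slot note free-text provenance note (e.g. typographical caveats).
#'
#' @seealso [builtinModel()], [evaluateSurface()], [fitQuadraticSurface()]
#' @export
setClass("QuadraticSurfaceModel",
    representation(
        pesticide = "character",
        foodMatrix = "character",
        coefficients = "numeric",
        coefficientStrings = "character",
        r2Reported = "numeric",
        note = "character"),
    prototype(
        coefficientStrings = character(),
        r2Reported = NA_real_,
        note = ""))

setValidity("QuadraticSurfaceModel", function(object) {
    msg <- character()
    if (length(object@pesticide) != 1L || !nzchar(object@pesticide))
        msg <- c(msg, "'pesticide' must be a single non-empty string")
    if (length(object@foodMatrix) != 1L ||
        !object@foodMatrix %in% .MATRICES)
        msg <- c(msg, "'foodMatrix' must be one of: wheat, flour")
    if (length(object@coefficients) != 10L ||
        !identical(names(object@coefficients), .COEF_NAMES))
        msg <- c(msg, sprintf("'coefficients' must be named %s",
                              paste(.COEF_NAMES, collapse = ", ")))
    else if (!all(is.finite(object@coefficients)))
        msg <- c(msg, "all ten coefficients must be finite")
    if (length(object@r2Reported) != 1L ||
        (!is.na(object@r2Reported) &&
         (object@r2Reported < 0 || object@r2Reported > 1)))
        msg <- c(msg, "'r2Reported' must be NA or in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Residue decay time course
#'
#' One pesticide x matrix x (temperature, humidity) x replicate series of
#' residue concentrations over storage time.
#'
#' @slot pesticide pesticide identifier.
#' @slot foodMatrix `"wheat"` or `"flour"`.
#' @slot temperatureC storage temperature, deg C.
#' @slot rhPct storage relative humidity, percentage points.
#' @slot replicate replicate index (>= 1).
#' @slot data `data.frame` with columns `day` (strictly increasing, >= 0),
#'   `concentration` (mg/kg, >= 0) and `censored` (logical; `TRUE` for values
#'   below the detection limit, stored at their substituted value).
#'
#' @seealso [fitFirstOrder()], [toRatios()], [aucTrapezoid()]
#' @export
setClass("ResidueTimeCourse",
    representation(
        pesticide = "character",
        foodMatrix = "character",
        temperatureC = "numeric",
        rhPct = "numeric",
        replicate = "integer",
        data = "data.frame"),
    prototype(replicate = 1L))

setValidity("ResidueTimeCourse", function(object) {
    msg <- character()
    if (length(object@foodMatrix) != 1L ||
        !object@foodMatrix %in% .MATRICES)
        msg <- c(msg, "'foodMatrix' must be one of: wheat, flour")
    d <- object@data
    req <- c("day", "concentration", "censored")
    if (!all(req %in% names(d)))
        msg <- c(msg, sprintf("'data' must have columns %s",
                              paste(req, collapse = ", ")))
    else {
        if (nrow(d) && any(d$day < 0)) msg <- c(msg, "days must be >= 0")
        if (nrow(d) > 1L && any(diff(d$day) <= 0))
            msg <- c(msg, "days must be strictly increasing")
        if (nrow(d) && any(d$concentration < 0, na.rm = TRUE))
            msg <- c(msg, "concentrations must be >= 0")
        if (!is.logical(d$censored))
            msg <- c(msg, "'censored' must be logical")
    }
    if (length(object@replicate) != 1L || object@replicate < 1L)
        msg <- c(msg, "'replicate' must be a single integer >= 1")
    if (length(msg)) msg else TRUE
})

#' First-order kinetic fit of a residue time course
#'
#' @slot k first-order rate constant, per day (`-slope` of the log-linear
#'   regression of ln concentration on day).
#' @slot c0Hat back-transformed intercept, mg/kg.
#' @slot halfLifeDays `ln(2)/k` days; `Inf` when `k <= 0`.
#' @slot r2LogLinear coefficient of determination of the log-linear fit.
#' @slot nUsed number of uncensored positive points used.
#' @export
setClass("FirstOrderFit",
    representation(
        k = "numeric",
        c0Hat = "numeric",
        halfLifeDays = "numeric",
        r2LogLinear = "numeric",
        nUsed = "integer"))

setValidity("FirstOrderFit", function(object) {
    msg <- character()
    if (object@k > 0 &&
        abs(object@halfLifeDays - log(2) / object@k) >
            1e-8 * object@halfLifeDays)
        msg <- c(msg, "halfLifeDays must equal ln(2)/k when k > 0")
    if (!is.na(object@r2LogLinear) &&
        (object@r2LogLinear < 0 || object@r2LogLinear > 1))
        msg <- c(msg, "r2LogLinear must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Trapezoidal area under a residue decay curve
#'
#' @slot value integral of concentration over the observed days,
#'   (mg/kg) x day.
#' @slot nPoints number of points integrated (>= 2).
#' @slot tSpan span of the observed days, days.
#' @export
setClass("AUCResult",
    representation(value = "numeric", nPoints = "integer", tSpan = "numeric"))

setValidity("AUCResult", function(object) {
    if (object@nPoints < 2L) "nPoints must be >= 2" else TRUE
})

#' Log-linear decay-rate law for the synthetic generator
#'
#' The generator's first-order rate constant depends log-linearly on the
#' storage condition:
#' \deqn{k(T, RH) = k_{ref} \exp\{a_T (T - T_{ref}) + a_{RH}(RH - RH_{ref})\},}
#' non-decreasing in both factors (`aT, aRH >= 0`), matching the observed
#' acceleration of dissipation with temperature and humidity.
#'
#' @slot kRef rate at the reference condition, per day (> 0).
#' @slot tRef reference temperature, deg C.
#' @slot rhRef reference relative humidity, percentage points.
#' @slot aT log-rate slope in temperature, per deg C (>= 0).
#' @slot aRH log-rate slope in humidity, per percentage point (>= 0).
#' @seealso [calibrateToHalfLives()], [rateConstant()]
#' @export
setClass("RateModelParams",
    representation(
        kRef = "numeric", tRef = "numeric", rhRef = "numeric",
        aT = "numeric", aRH = "numeric"),
    prototype(tRef = 20, rhRef = 50, aT = 0, aRH = 0))

setValidity("RateModelParams", function(object) {
    msg <- character()
    if (!is.finite(object@kRef) || object@kRef <= 0)
        msg <- c(msg, "kRef must be finite and > 0")
    if (object@aT < 0 || object@aRH < 0)
        msg <- c(msg, "aT and aRH must be >= 0 (rates non-decreasing in T, RH)")
    if (length(msg)) msg else TRUE
})

#' Factorial storage-study design
#'
#' Layout of a simulated storage experiment: the temperature x humidity
#' factorial, the sampling schedule, replication, assay noise and censoring.
#' Defaults mirror a 4 x 4 factorial of 20/30/40/50 deg C by 50/60/70/80 %RH
#' followed for 90 days (wheat) or 60 days (flour).
#'
#' @slot foodMatrix `"wheat"` or `"flour"`.
#' @slot temperatures temperature levels, deg C.
#' @slot humidities relative-humidity levels, percentage points.
#' @slot samplingDays increasing sampling days including day 0.
#' @slot horizon study length, days.
#' @slot replicates replicates per condition (>= 1).
#' @slot noiseCv coefficient of variation of the multiplicative lognormal
#'   assay noise (fraction; 0 disables noise).
#' @slot lod limit of detection, mg/kg; observations below it are substituted
#'   by `lod/2` and flagged censored.
#' @slot c0 true initial concentration, mg/kg.
#' @slot seed integer seed driving all noise streams.
#' @seealso [studyDesign()], [generateStudy()]
#' @export
setClass("StudyDesign",
    representation(
        foodMatrix = "character",
        temperatures = "numeric",
        humidities = "numeric",
        samplingDays = "numeric",
        horizon = "numeric",
        replicates = "integer",
        noiseCv = "numeric",
        lod = "numeric",
        c0 = "numeric",
        seed = "integer"))

setValidity("StudyDesign", function(object) {
    msg <- character()
    if (!object@foodMatrix %in% .MATRICES)
        msg <- c(msg, "'foodMatrix' must be one of: wheat, flour")
    if (!length(object@samplingDays))
        msg <- c(msg, "samplingDays must be non-empty")
    else {
        if (any(diff(object@samplingDays) <= 0))
            msg <- c(msg, "samplingDays must be strictly increasing")
        if (min(object@samplingDays) < 0 ||
            max(object@samplingDays) > object@horizon)
            msg <- c(msg, "samplingDays must lie in [0, horizon]")
    }
    if (anyDuplicated(object@temperatures) || anyDuplicated(object@humidities))
        msg <- c(msg, "condition levels must be distinct")
    if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
    if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be >= 0")
    if (object@lod < 0 || object@c0 <= object@lod)
        msg <- c(msg, "need c0 > lod >= 0")
    if (length(msg)) msg else TRUE
})

#' Supply-chain scenario: wheat storage, milling, flour storage
#'
#' Initial concentration `c0` on wheat, the wheat-storage stage conditions,
#' a milling processing factor `pf` (ratio of the concentration after milling
#' to before; `pf < 1` means milling removes residue), and the flour-storage
#' stage conditions.
#'
#' @slot pesticide pesticide identifier.
#' @slot c0 initial concentration on wheat, mg/kg (> 0).
#' @slot wheatStage named numeric `c(t=, T=, RH=)`: days, deg C, %RH.
#' @slot pf processing factor across milling, dimensionless (> 0).
#' @slot flourStage named numeric `c(t=, T=, RH=)`.
#' @seealso [supplyChainScenario()], [predictChain()]
#' @export
setClass("SupplyChainScenario",
    representation(
        pesticide = "character",
        c0 = "numeric",
        wheatStage = "numeric",
        pf = "numeric",
        flourStage = "numeric"))

setValidity("SupplyChainScenario", function(object) {
    msg <- character()
    if (!is.finite(object@c0) || object@c0 <= 0)
        msg <- c(msg, "c0 must be finite and > 0")
    if (!is.finite(object@pf) || object@pf < 0)
        msg <- c(msg, "pf must be finite and >= 0")
    for (nm in c("wheatStage", "flourStage")) {
        st <- slot(object, nm)
        if (!identical(names(st), c("t", "T", "RH")) || !all(is.finite(st)))
            msg <- c(msg, sprintf("'%s' must be finite, named c(t=, T=, RH=)",
                                  nm))
        else if (st[["t"]] < 0)
            msg <- c(msg, sprintf("'%s' time must be >= 0", nm))
    }
    if (length(msg)) msg else TRUE
})

#' Predicted concentrations along the supply chain
#'
#' @slot c1 concentration after wheat storage, mg/kg.
#' @slot c2 concentration after milling, mg/kg (`pf * c1` exactly).
#' @slot c3 concentration after flour storage, mg/kg.
#' @slot clampEvents character record of every ratio clamped into [0, 1].
#' @slot modelsUsed identifiers of the wheat and flour models applied.
#' @export
setClass("SupplyChainPrediction",
    representation(
        c1 = "numeric", c2 = "numeric", c3 = "numeric",
        clampEvents = "character", modelsUsed = "character"))

#' Fitted quadratic surface with inference
#'
#' @slot model the fitted [QuadraticSurfaceModel-class].
#' @slot r2,r2Adj coefficient of determination and its adjusted form.
#' @slot coefSe,coefP per-coefficient standard errors and two-sided p-values
#'   (t distribution on `residualDf`).
#' @slot nObs,residualDf observation count and residual degrees of freedom
#'   (`nObs - 10`).
#' @export
setClass("SurfaceFit",
    representation(
        model = "QuadraticSurfaceModel",
        r2 = "numeric", r2Adj = "numeric",
        coefSe = "numeric", coefP = "numeric",
        nObs = "integer", residualDf = "integer"))

setValidity("SurfaceFit", function(object) {
    msg <- character()
    if (!is.na(object@r2) && (object@r2 < -1e-12 || object@r2 > 1 + 1e-12))
        msg <- c(msg, "r2 must be in [0, 1]")
    if (object@residualDf != object@nObs - 10L)
        msg <- c(msg, "residualDf must equal nObs - 10")
    if (length(msg)) msg else TRUE
})

#' Two-factor effect analysis of condition-level AUC
#'
#' @slot response response label (`"AUC"`).
#' @slot pT,pRH,pInt p-values for the temperature and humidity main effects
#'   and their interaction. Without replicates the interaction is Tukey's
#'   one-degree-of-freedom test for nonadditivity.
#' @slot table the underlying ANOVA table.
#' @slot method `"two-way ANOVA with interaction"` or
#'   `"additive ANOVA + Tukey 1-df nonadditivity"`.
#' @export
setClass("EffectTable",
    representation(
        response = "character",
        pT = "numeric", pRH = "numeric", pInt = "numeric",
        table = "data.frame", method = "character"))

setValidity("EffectTable", function(object) {
    p <- c(object@pT, object@pRH, object@pInt)
    p <- p[!is.na(p)]
    if (length(p) && (any(p < 0) || any(p > 1)))
        "p-values must be in [0, 1]" else TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "QuadraticSurfaceModel", function(object) {
    cat(sprintf("QuadraticSurfaceModel: %s / %s\n",
                object@pesticide, object@foodMatrix))
    cat("  coefficients (b0, t, T, RH, t2, T2, RH2, tT, tRH, TRH):\n")
    print(object@coefficients)
    if (!is.na(object@r2Reported))
        cat(sprintf("  reported R2: %.3f\n", object@r2Reported))
    if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

setMethod("show", "ResidueTimeCourse", function(object) {
    cat(sprintf(
        "ResidueTimeCourse: %s / %s at %g degC, %g %%RH (replicate %d)\n",
        object@pesticide, object@foodMatrix, object@temperatureC,
        object@rhPct, object@replicate))
    cat(sprintf("  %d points over days [%g, %g]; %d censored\n",
                nrow(object@data), min(object@data$day), max(object@data$day),
                sum(object@data$censored)))
})

setMethod("show", "FirstOrderFit", function(object) {
    cat(sprintf(
        "FirstOrderFit: k = %.5g /day, half-life = %.4g days, R2 = %.4f (n = %d)\n",
        object@k, object@halfLifeDays, object@r2LogLinear, object@nUsed))
})

setMethod("show", "SurfaceFit", function(object) {
    cat(sprintf("SurfaceFit: %s / %s, R2 = %.4f (adj %.4f), n = %d\n",
                object@model@pesticide, object@model@foodMatrix,
                object@r2, object@r2Adj, object@nObs))
})

setMethod("show", "SupplyChainPrediction", function(object) {
    cat(sprintf("SupplyChainPrediction: C1 = %.5g, C2 = %.5g, C3 = %.5g mg/kg\n",
                object@c1, object@c2, object@c3))
    if (length(object@clampEvents))
        cat("  clamped:", paste(object@clampEvents, collapse = "; "), "\n")
})

setMethod("show", "EffectTable", function(object) {
    cat(sprintf("EffectTable (%s): p_T = %.4g, p_RH = %.4g, p_TxRH = %.4g\n",
                object@method, object@pT, object@pRH, object@pInt))
})

## ---- accessors --------------------------------------------------------

#' @describeIn QuadraticSurfaceModel-class named coefficient vector.
#' @param model,x a `QuadraticSurfaceModel` (or, for `halfLife`, a
#'   `FirstOrderFit`).
#' @export
setMethod("surfaceCoefficients", "QuadraticSurfaceModel",
          function(model) model@coefficients)

#' @describeIn QuadraticSurfaceModel-class reported R-squared (`NA` if none).
#' @export
setMethod("reportedR2", "QuadraticSurfaceModel",
          function(model) model@r2Reported)

#' @describeIn FirstOrderFit-class estimated half-life in days.
#' @export
setMethod("halfLife", "FirstOrderFit", function(x) x@halfLifeDays)

#' @describeIn SupplyChainPrediction-class record of clamped ratios.
#' @export
setMethod("clampEvents", "SupplyChainPrediction", function(x) x@clampEvents)
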