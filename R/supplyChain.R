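## Chained predictor for the wheat-flour supply chain: wheat storage
## (quadratic ratio surface), milling (processing factor), flour storage
## (quadratic ratio surface). Ratios are clamped to [0, 1] before chaining
## so predicted concentrations stay physical.

#' Construct a supply-chain scenario
#'
#' @param pesticide pesticide identifier.
#' @param c0 initial concentration on wheat, mg/kg (> 0).
#' @param wheatStage numeric `c(t, T, RH)` (days, deg C, %RH) for wheat
#'   storage.
#' @param pf milling processing factor (concentration after milling over
#'   before; > 1 triggers a warning since milling is expected to remove
#'   residue). Default 1 (no milling effect).
#' @param flourStage numeric `c(t, T, RH)` for flour storage.
#' @return A [SupplyChainScenario-class].
#' @export
supplyChainScenario <- function(pesticide, c0, wheatStage, pf = 1,
                                flourStage) {
    ws <- stats::setNames(as.numeric(wheatStage), c("t", "T", "RH"))
    fs <- stats::setNames(as.numeric(flourStage), c("t", "T", "RH"))
    if (is.finite(pf) && pf > 1)
        warning("processing factor > 1: milling is predicted to increase ",
                "the residue concentration")
    new("SupplyChainScenario", pesticide = pesticide, c0 = c0,
        wheatStage = ws, pf = pf, flourStage = fs)
}

#' @describeIn SupplyChainScenario-class predict concentrations along the
#'   chain: `C1 = C0 * ratio_wheat(t_w, T_w, RH_w)` (clamped),
#'   `C2 = PF * C1`, `C3 = C2 * ratio_flour(t_f, T_f, RH_f)` (clamped).
#'   Milling is treated as instantaneous; any degradation during it is part
#'   of the processing factor.
#' @param scenario a `SupplyChainScenario`.
#' @param wheatModel,flourModel [QuadraticSurfaceModel-class]s for the two
#'   storage stages; default to the built-in models for the scenario's
#'   pesticide.
#' @param ... unused.
#' @export
setMethod("predictChain", "SupplyChainScenario",
    function(scenario,
             wheatModel = builtinModel(scenario@pesticide, "wheat"),
             flourModel = builtinModel(scenario@pesticide, "flour"), ...) {
        if (wheatModel@pesticide != scenario@pesticide ||
            flourModel@pesticide != scenario@pesticide)
            stop("consistency error: model pesticide does not match scenario")
        if (wheatModel@foodMatrix != "wheat" ||
            flourModel@foodMatrix != "flour")
            stop("consistency error: need a wheat model and a flour model")
        events <- character()
        ws <- scenario@wheatStage
        rw <- evaluateClamped(wheatModel, ws[["t"]], ws[["T"]], ws[["RH"]],
                              warn = FALSE)
        if (attr(rw, "clamped"))
            events <- c(events, sprintf(
                "wheat ratio %.4g clamped to %g",
                evaluateSurface(wheatModel, ws[["t"]], ws[["T"]], ws[["RH"]]),
                as.numeric(rw)))
        c1 <- scenario@c0 * as.numeric(rw)
        c2 <- scenario@pf * c1
        fs <- scenario@flourStage
        rf <- evaluateClamped(flourModel, fs[["t"]], fs[["T"]], fs[["RH"]],
                              warn = FALSE)
        if (attr(rf, "clamped"))
            events <- c(events, sprintf(
                "flour ratio %.4g clamped to %g",
                evaluateSurface(flourModel, fs[["t"]], fs[["T"]], fs[["RH"]]),
                as.numeric(rf)))
        c3 <- c2 * as.numeric(rf)
        new("SupplyChainPrediction", c1 = c1, c2 = c2, c3 = c3,
            clampEvents = events,
            modelsUsed = c(
                wheat = paste(wheatModel@pesticide, "wheat", sep = "."),
                flour = paste(flourModel@pesticide, "flour", sep = ".")))
    })

#' Scan supply-chain predictions over a grid of stage conditions
#'
#' Evaluates [predictChain()] over the crossing of a grid of wheat-storage
#' conditions with a grid of flour-storage conditions, at fixed `c0` and
#' processing factor.
#'
#' @param pesticide pesticide identifier (registry models are used).
#' @param c0 initial concentration, mg/kg.
#' @param pf milling processing factor.
#' @param wheatGrid,flourGrid `data.frame`s with columns `t`, `T`, `RH`;
#'   a single-row grid fixes that stage.
#' @return `data.frame` with one row per wheat x flour grid cell: the six
#'   stage conditions, `c1`, `c2`, `c3`, and `clamped` (number of clamped
#'   ratios in that cell).
#' @export
scanConditions <- function(pesticide, c0, pf, wheatGrid, flourGrid) {
    wheatGrid <- as.data.frame(wheatGrid)
    flourGrid <- as.data.frame(flourGrid)
    if (!nrow(wheatGrid) || !nrow(flourGrid))
        stop("design error: empty condition grid")
    for (g in list(wheatGrid, flourGrid))
        if (!all(c("t", "T", "RH") %in% names(g)))
            stop("grids must have columns t, T, RH")
    wm <- builtinModel(pesticide, "wheat")
    fm <- builtinModel(pesticide, "flour")
    idx <- expand.grid(f = seq_len(nrow(flourGrid)),
                       w = seq_len(nrow(wheatGrid)))
    rows <- lapply(seq_len(nrow(idx)), function(i) {
        w <- wheatGrid[idx$w[i], ]
        f <- flourGrid[idx$f[i], ]
        sc <- suppressWarnings(supplyChainScenario(
            pesticide, c0, unlist(w[c("t", "T", "RH")]), pf,
            unlist(f[c("t", "T", "RH")])))
        pr <- predictChain(sc, wm, fm)
        data.frame(t_w = w$t, T_w = w$T, RH_w = w$RH,
                   t_f = f$t, T_f = f$T, RH_f = f$RH,
                   c1 = pr@c1, c2 = pr@c2, c3 = pr@c3,
                   clamped = length(pr@clampEvents))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
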