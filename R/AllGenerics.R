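#' @title Generics for ResidueChain
#' @name ResidueChain-generics
#' @description S4 generics for surface evaluation, kinetic fitting and
#'   supply-chain prediction. Methods are documented with their classes.
#' @keywords internal
NULL

#' @export
setGeneric("evaluateSurface", function(model, t, temperatureC, rhPct, ...)
    standardGeneric("evaluateSurface"))

#' @export
setGeneric("evaluateClamped", function(model, t, temperatureC, rhPct, ...)
    standardGeneric("evaluateClamped"))

#' @export
setGeneric("surfaceCoefficients", function(model)
    standardGeneric("surfaceCoefficients"))

#' @export
setGeneric("reportedR2", function(model) standardGeneric("reportedR2"))

#' @export
setGeneric("toRatios", function(tc) standardGeneric("toRatios"))

#' @export
setGeneric("fitFirstOrder", function(tc, ...) standardGeneric("fitFirstOrder"))

#' @export
setGeneric("percentDecrease", function(tc, horizon)
    standardGeneric("percentDecrease"))

#' @export
setGeneric("aucTrapezoid", function(tc, ...) standardGeneric("aucTrapezoid"))

#' @export
setGeneric("generateTimecourse",
    function(params, temperatureC, rhPct, design, ...)
    standardGeneric("generateTimecourse"))

#' @export
setGeneric("generateStudy", function(params, design, ...)
    standardGeneric("generateStudy"))

#' @export
setGeneric("rateConstant", function(params, temperatureC, rhPct)
    standardGeneric("rateConstant"))

#' @export
setGeneric("predictChain", function(scenario, ...)
    standardGeneric("predictChain"))

#' @export
setGeneric("clampEvents", function(x) standardGeneric("clampEvents"))

#' @export
setGeneric("halfLife", function(x) standardGeneric("halfLife"))
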