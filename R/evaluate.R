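## Polynomial evaluation of the quadratic residue-ratio surface, raw and
## clamped to the physical range [0, 1].

.checkFiniteArgs <- function(t, temperatureC, rhPct) {
    if (!length(t) || !all(is.finite(t)) || !all(is.finite(temperatureC)) ||
        !all(is.finite(rhPct)))
        stop("t, temperatureC and rhPct must be finite")
    if (any(t < 0)) stop("t must be >= 0")
}

#' @describeIn QuadraticSurfaceModel-class evaluate the raw polynomial at
#'   `(t, T, RH)`; vectorized with recycling, no range restriction.
#' @param t storage time, days (>= 0).
#' @param temperatureC storage temperature, deg C.
#' @param rhPct relative humidity, percentage points (50 means 50%).
#' @param warn for `evaluateClamped`, emit a warning when clamping fires.
#' @param ... unused.
#' @export
setMethod("evaluateSurface", "QuadraticSurfaceModel",
    function(model, t, temperatureC, rhPct, ...) {
        .checkFiniteArgs(t, temperatureC, rhPct)
        b <- model@coefficients
        n <- max(length(t), length(temperatureC), length(rhPct))
        t <- rep_len(t, n)
        Tc <- rep_len(temperatureC, n)
        rh <- rep_len(rhPct, n)
        b[["b0"]] + b[["t"]] * t + b[["T"]] * Tc + b[["RH"]] * rh +
            b[["t2"]] * t^2 + b[["T2"]] * Tc^2 + b[["RH2"]] * rh^2 +
            b[["tT"]] * t * Tc + b[["tRH"]] * t * rh + b[["TRH"]] * Tc * rh
    })

#' @describeIn QuadraticSurfaceModel-class evaluate and clamp into `[0, 1]`
#'   (fitted quadratics can leave the physical ratio range when
#'   extrapolated). Returns the clamped values with a logical attribute
#'   `"clamped"` marking affected elements; warns when any fired unless
#'   `warn = FALSE`.
#' @export
setMethod("evaluateClamped", "QuadraticSurfaceModel",
    function(model, t, temperatureC, rhPct, warn = TRUE, ...) {
        raw <- evaluateSurface(model, t, temperatureC, rhPct)
        out <- pmin(1, pmax(0, raw))
        hit <- out != raw
        if (any(hit) && isTRUE(warn))
            warning(sprintf(
                "%s/%s: %d of %d ratio value(s) clamped into [0, 1]",
                model@pesticide, model@foodMatrix, sum(hit), length(raw)))
        attr(out, "clamped") <- hit
        out
    })
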