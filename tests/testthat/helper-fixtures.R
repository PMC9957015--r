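# Programmatic fixtures shared across the suite.

# bare time course from vectors
makeTimecourse <- function(day, concentration, censored = FALSE,
                           pesticide = "carbendazim", foodMatrix = "wheat",
                           temperatureC = 20, rhPct = 50, replicate = 1L) {
    new("ResidueTimeCourse", pesticide = pesticide, foodMatrix = foodMatrix,
        temperatureC = temperatureC, rhPct = rhPct,
        replicate = as.integer(replicate),
        data = data.frame(day = day, concentration = concentration,
                          censored = rep_len(censored, length(day))))
}

# noiseless exponential decay series
expCourse <- function(k, c0 = 1, days = c(0, 1, 3, 5, 7, 14, 21, 30, 45, 60),
                      ...) {
    makeTimecourse(days, c0 * exp(-k * days), ...)
}

# surface model with arbitrary coefficients (canonical order)
makeSurface <- function(coefs, pesticide = "carbendazim",
                        foodMatrix = "wheat") {
    co <- as.numeric(coefs)
    names(co) <- c("b0", "t", "T", "RH", "t2", "T2", "RH2", "tT", "tRH", "TRH")
    new("QuadraticSurfaceModel", pesticide = pesticide,
        foodMatrix = foodMatrix, coefficients = co)
}

# ratio observations generated exactly from a surface model on a grid
surfaceObservations <- function(model,
                                days = c(0, 1, 3, 5, 7, 14, 21, 30, 45, 90),
                                temps = c(20, 30, 40, 50),
                                hums = c(50, 60, 70, 80)) {
    grid <- expand.grid(t = days, T = temps, RH = hums)
    grid$ratio <- evaluateSurface(model, grid$t, grid$T, grid$RH)
    grid
}
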