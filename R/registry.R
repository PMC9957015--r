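## Registry of the published degradation models: ten second-order surfaces
## (five pesticides x wheat/flour). Coefficients are stored exactly as printed
## and parsed once at load, so the registry can be audited digit-for-digit
## against the source tables.

## columns: b0, t, T, RH, t2, T2, RH2, tT, tRH, TRH (canonical order)
.REGISTRY_STRINGS <- list(
    wheat = list(
        "carbendazim" = list(
            coef = c("0.438", "-0.00246", "0.0217", "-0.00184", "0.0000736",
                     "-0.000312", "-0.00004015", "0.0000674", "0.00000585",
                     "0.00005695"),
            r2 = "0.830",
            note = paste("printed row lists two apparent T*RH cross terms and",
                         "no t*RH term; the three cross coefficients are",
                         "assigned in printed order to (t*T, t*RH, T*RH)")),
        "bensulfuron-methyl" = list(
            coef = c("0.5", "-0.034575", "0.035875", "-0.007", "0.000285",
                     "-0.00047", "0.000035", "0.000025", "-0.00003",
                     "0.000001"),
            r2 = "0.817", note = ""),
        "triazophos" = list(
            coef = c("0.298", "-0.02986", "0.046", "-0.00346", "0.000244",
                     "-0.000666", "-0.000004", "-0.000008", "0.000002",
                     "0.000036"),
            r2 = "0.852", note = ""),
        "chlorpyrifos" = list(
            coef = c("0.586", "-0.03286", "0.02572", "-0.00434", "0.000276",
                     "-0.000328", "0.000016", "-0.000028", "0.00001",
                     "0.000006"),
            r2 = "0.868", note = ""),
        "carbosulfan" = list(
            coef = c("0.728", "-0.02008", "0.01628", "-0.00171", "0.000157",
                     "-0.000259", "-0.000007", "0.000019", "-0.000025",
                     "-0.000017"),
            r2 = "0.863", note = "")),
    flour = list(
        "carbendazim" = list(
            coef = c("1.756", "-0.05176", "-0.0042", "-0.01902", "0.000575",
                     "0.000043", "0.0001", "0.0000412", "0.0000768",
                     "-0.0000162"),
            r2 = "0.796", note = ""),
        "bensulfuron-methyl" = list(
            coef = c("1.738", "-0.05116", "0.0033", "0.0185", "0.000549",
                     "-0.000095", "0.00007", "0.000006", "0.000116",
                     "0.000081"),
            r2 = "0.802", note = ""),
        "triazophos" = list(
            coef = c("1.253", "-0.0411", "-0.0022", "-0.006", "0.000491",
                     "0.00021", "-0.0000165", "0.0000065", "0.0000115",
                     "0.0001"),
            r2 = "0.878", note = ""),
        "chlorpyrifos" = list(
            coef = c("0.968", "-0.05488", "-0.0106", "-0.00196", "0.00063",
                     "-0.000192", "0.00002", "0.000018", "0.0000656",
                     "0.000005"),
            r2 = "0.840", note = ""),
        "carbosulfan" = list(
            coef = c("1.314", "-0.03604", "0.01218", "-0.01", "0.000467",
                     "0.000225", "0.0000344", "0.000023", "-0.000045",
                     "-0.000008"),
            r2 = "0.863", note = "")))

#' Published degradation model for one pesticide and matrix
#'
#' Looks up the second-order residue-ratio surface published for a pesticide
#' during wheat or flour storage. The response is the residue ratio (final
#' over initial concentration for the stage); predictors are storage time
#' (days), temperature (deg C) and relative humidity (percentage points).
#'
#' @param pesticide one of `"carbendazim"`, `"bensulfuron-methyl"`,
#'   `"triazophos"`, `"chlorpyrifos"`, `"carbosulfan"`.
#' @param foodMatrix `"wheat"` (raw-grain storage) or `"flour"`.
#' @return A [QuadraticSurfaceModel-class].
#' @examples
#' m <- builtinModel("carbendazim", "wheat")
#' evaluateSurface(m, t = 0, temperatureC = 0, rhPct = 0)  # the intercept
#' @export
builtinModel <- function(pesticide, foodMatrix) {
    if (length(foodMatrix) != 1L || !foodMatrix %in% names(.REGISTRY_STRINGS))
        stop("unknown matrix '", paste(foodMatrix, collapse = ","),
             "'; valid: ", paste(names(.REGISTRY_STRINGS), collapse = ", "))
    tab <- .REGISTRY_STRINGS[[foodMatrix]]
    if (length(pesticide) != 1L || !pesticide %in% names(tab))
        stop("unknown pesticide '", paste(pesticide, collapse = ","),
             "'; valid: ", paste(names(tab), collapse = ", "))
    entry <- tab[[pesticide]]
    co <- as.numeric(entry$coef)
    names(co) <- .COEF_NAMES
    new("QuadraticSurfaceModel",
        pesticide = pesticide, foodMatrix = foodMatrix,
        coefficients = co, coefficientStrings = entry$coef,
        r2Reported = as.numeric(entry$r2), note = entry$note)
}

#' All ten published models
#'
#' @return Named list of [QuadraticSurfaceModel-class] objects, names of the
#'   form `"<pesticide>.<matrix>"`.
#' @export
builtinModels <- function() {
    out <- list()
    for (m in names(.REGISTRY_STRINGS))
        for (p in names(.REGISTRY_STRINGS[[m]]))
            out[[paste(p, m, sep = ".")]] <- builtinModel(p, m)
    out
}

#' Model registry as a flat table
#'
#' One row per model: pesticide, matrix, the ten coefficients in canonical
#' order and the reported R-squared. Accepts fitted models too, so a refit
#' can be exported in the same layout as the published tables.
#'
#' @param models list of [QuadraticSurfaceModel-class]; defaults to the
#'   built-in registry.
#' @return `data.frame` with 13 columns.
#' @export
registryTable <- function(models = builtinModels()) {
    rows <- lapply(models, function(m) {
        co <- as.list(m@coefficients)
        names(co) <- paste0("b_", .COEF_NAMES)
        cbind(data.frame(pesticide = m@pesticide, matrix = m@foodMatrix,
                         stringsAsFactors = FALSE),
              as.data.frame(co),
              data.frame(r2_reported = m@r2Reported))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write the model registry to a delimited file
#'
#' @param path output file path (CSV, UTF-8, header row).
#' @param models as in [registryTable()].
#' @return `path`, invisibly.
#' @export
writeRegistry <- function(path, models = builtinModels()) {
    utils::write.csv(registryTable(models), path, row.names = FALSE)
    invisible(path)
}
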