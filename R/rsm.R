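## Response-surface refitting: the ten-term quadratic in (t, T, RH) fitted to
## ratio data by QR-based least squares, and the two-factor effect analysis
## of condition-level AUC.

#' Design matrix of the quadratic surface
#'
#' Expands points `(t, T, RH)` into the ten monomials of the second-order
#' model, in the canonical column order
#' `1, t, T, RH, t^2, T^2, RH^2, t*T, t*RH, T*RH`.
#'
#' @param points `data.frame` (or matrix) with columns `t`, `T`, `RH`.
#' @return numeric matrix with 10 named columns, one row per point.
#' @examples
#' buildDesignMatrix(data.frame(t = 2, T = 3, RH = 5))
#' @export
buildDesignMatrix <- function(points) {
    points <- as.data.frame(points)
    if (!all(c("t", "T", "RH") %in% names(points)))
        stop("points must have columns t, T, RH")
    if (!nrow(points)) stop("need at least one point")
    t <- points$t; Tc <- points$T; rh <- points$RH
    if (!all(is.finite(t)) || !all(is.finite(Tc)) || !all(is.finite(rh)))
        stop("non-finite values in design points")
    X <- cbind(1, t, Tc, rh, t^2, Tc^2, rh^2, t * Tc, t * rh, Tc * rh)
    colnames(X) <- .COEF_NAMES
    X
}

#' Fit the second-order residue-ratio surface
#'
#' Least-squares fit of the full ten-term quadratic in storage time,
#' temperature and relative humidity to observed residue ratios, solved by
#' QR (orthogonal) decomposition via [stats::lm()]. Coefficient standard
#' errors and two-sided p-values use the t distribution on `n - 10` degrees
#' of freedom.
#'
#' @param observations `data.frame` with columns `t` (days), `T` (deg C),
#'   `RH` (%RH) and `ratio` (the residue ratio response).
#' @param pesticide,foodMatrix labels stored on the fitted model.
#' @return A [SurfaceFit-class].
#' @examples
#' m <- builtinModel("carbendazim", "wheat")
#' grid <- expand.grid(t = c(0, 10, 30, 60, 90), T = c(20, 50), RH = c(50, 80))
#' grid$ratio <- evaluateSurface(m, grid$t, grid$T, grid$RH)
#' fitQuadraticSurface(grid)@r2  # 1: exact recovery
#' @export
fitQuadraticSurface <- function(observations, pesticide = "fitted",
                                foodMatrix = "wheat") {
    obs <- as.data.frame(observations)
    if (!all(c("t", "T", "RH", "ratio") %in% names(obs)))
        stop("observations must have columns t, T, RH, ratio")
    n <- nrow(obs)
    if (n <= 10L)
        stop("insufficient data: need more than 10 observations, got ", n)
    X <- buildDesignMatrix(obs)
    df <- as.data.frame(X[, -1, drop = FALSE])
    names(df) <- .COEF_NAMES[-1]
    df$.ratio <- obs$ratio
    fit <- stats::lm(.ratio ~ ., data = df)
    co <- stats::coef(fit)
    if (anyNA(co))
        stop("rank error: aliased design columns: ",
             paste(names(co)[is.na(co)], collapse = ", "))
    ## summary.lm warns on exact (zero-residual) data; that case is expected
    ## here when refitting data generated from a registry model
    sm <- withCallingHandlers(summary(fit),
        warning = function(w) {
            if (grepl("essentially perfect fit", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    co <- stats::setNames(unname(co), .COEF_NAMES)
    se <- stats::setNames(unname(sm$coefficients[, "Std. Error"]),
                          .COEF_NAMES)
    pv <- stats::setNames(unname(sm$coefficients[, "Pr(>|t|)"]), .COEF_NAMES)
    model <- new("QuadraticSurfaceModel", pesticide = pesticide,
                 foodMatrix = foodMatrix, coefficients = co)
    new("SurfaceFit", model = model,
        r2 = sm$r.squared, r2Adj = sm$adj.r.squared,
        coefSe = se, coefP = pv,
        nObs = as.integer(n), residualDf = as.integer(n - 10L))
}

#' Two-factor effect analysis of condition-level AUC
#'
#' Tests whether storage temperature, relative humidity and their
#' interaction affect the area under the residue decay curve across a
#' factorial of conditions. With replicated cells this is the two-way ANOVA
#' with interaction; with one observation per cell the interaction is
#' assessed by Tukey's one-degree-of-freedom test for nonadditivity and the
#' main effects come from the additive model.
#'
#' @param aucTable `data.frame` with columns `temperature_C`, `rh_pct`,
#'   `auc` (e.g. from [aucByCondition()]); any `replicate` column is
#'   ignored, replication is inferred from duplicated cells.
#' @return An [EffectTable-class] with p-values `pT`, `pRH`, `pInt`.
#' @export
effectAnova <- function(aucTable) {
    d <- as.data.frame(aucTable)
    req <- c("temperature_C", "rh_pct", "auc")
    if (!all(req %in% names(d)))
        stop("aucTable must have columns ", paste(req, collapse = ", "))
    d$Tf <- factor(d$temperature_C)
    d$RHf <- factor(d$rh_pct)
    if (nlevels(d$Tf) < 2L || nlevels(d$RHf) < 2L)
        stop("design error: need at least 2 levels per factor")
    ncell <- nrow(unique(d[, c("Tf", "RHf")]))
    replicated <- nrow(d) > ncell
    if (stats::var(d$auc) < 1e-300) {
        ## degenerate: identical response everywhere -> F = 0, p = 1
        tab <- data.frame(term = c("temperature", "humidity", "interaction"),
                          F = c(0, 0, 0), p = c(1, 1, 1))
        return(new("EffectTable", response = "AUC", pT = 1, pRH = 1, pInt = 1,
                   table = tab,
                   method = if (replicated) "two-way ANOVA with interaction"
                            else "additive ANOVA + Tukey 1-df nonadditivity"))
    }
    if (replicated) {
        av <- stats::aov(auc ~ Tf * RHf, data = d)
        s <- summary(av)[[1]]
        rn <- trimws(rownames(s))
        pT <- s[rn == "Tf", "Pr(>F)"]
        pRH <- s[rn == "RHf", "Pr(>F)"]
        pInt <- s[rn == "Tf:RHf", "Pr(>F)"]
        tab <- data.frame(term = rn, df = s$Df, F = s$`F value`,
                          p = s$`Pr(>F)`)
        method <- "two-way ANOVA with interaction"
    } else {
        m1 <- stats::lm(auc ~ Tf + RHf, data = d)
        s <- stats::anova(m1)
        pT <- s["Tf", "Pr(>F)"]
        pRH <- s["RHf", "Pr(>F)"]
        ## Tukey's 1-df nonadditivity: add the squared additive prediction
        d$q <- stats::fitted(m1)^2
        m2 <- stats::lm(auc ~ Tf + RHf + q, data = d)
        cmp <- stats::anova(m1, m2)
        pInt <- cmp$`Pr(>F)`[2]
        tab <- data.frame(term = c(trimws(rownames(s)), "nonadditivity"),
                          df = c(s$Df, 1),
                          F = c(s$`F value`, cmp$F[2]),
                          p = c(s$`Pr(>F)`, pInt))
        method <- "additive ANOVA + Tukey 1-df nonadditivity"
    }
    new("EffectTable", response = "AUC", pT = pT, pRH = pRH, pInt = pInt,
        table = tab, method = method)
}
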