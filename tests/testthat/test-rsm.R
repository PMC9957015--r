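test_that("design matrix expands points into the ten canonical monomials", {
    expect_identical(unname(buildDesignMatrix(
        data.frame(t = 0, T = 0, RH = 0))[1, ]),
        c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0))
    expect_identical(unname(buildDesignMatrix(
        data.frame(t = 1, T = 1, RH = 1))[1, ]), rep(1, 10))
    expect_identical(unname(buildDesignMatrix(
        data.frame(t = 2, T = 3, RH = 5))[1, ]),
        c(1, 2, 3, 5, 4, 9, 25, 6, 10, 15))
    expect_error(buildDesignMatrix(data.frame(t = NA, T = 1, RH = 1)),
                 "finite")
})

test_that("noiseless data from each wheat registry model are recovered", {
    for (p in c("carbendazim", "bensulfuron-methyl", "triazophos",
                "chlorpyrifos", "carbosulfan")) {
        m <- builtinModel(p, "wheat")
        fit <- fitQuadraticSurface(surfaceObservations(m), pesticide = p)
        relerr <- abs(surfaceCoefficients(fit@model) - surfaceCoefficients(m)) /
            abs(surfaceCoefficients(m))
        expect_lt(max(relerr), 1e-6)
        expect_equal(fit@r2, 1, tolerance = 1e-9)
        expect_identical(fit@residualDf, fit@nObs - 10L)
    }
})

test_that("random full-rank surfaces are recovered from exact data", {
    set.seed(17)
    for (i in 1:10) {
        m <- makeSurface(runif(10, -0.5, 0.5))
        fit <- fitQuadraticSurface(surfaceObservations(m))
        expect_equal(unname(surfaceCoefficients(fit@model)),
                     unname(surfaceCoefficients(m)), tolerance = 1e-8)
    }
})

test_that("fitted residuals are orthogonal to the design columns", {
    set.seed(29)
    obs <- surfaceObservations(builtinModel("triazophos", "wheat"))
    obs$ratio <- obs$ratio * exp(rnorm(nrow(obs), 0, 0.05))
    fit <- fitQuadraticSurface(obs)
    X <- buildDesignMatrix(obs)
    resid <- obs$ratio - drop(X %*% surfaceCoefficients(fit@model))
    expect_lt(max(abs(crossprod(X, resid))), 1e-7 * nrow(obs))
})

test_that("R-squared is invariant under rescaling of the response", {
    obs <- surfaceObservations(builtinModel("chlorpyrifos", "wheat"))
    set.seed(31)
    obs$ratio <- obs$ratio + rnorm(nrow(obs), 0, 0.02)
    f1 <- fitQuadraticSurface(obs)
    obs$ratio <- obs$ratio * 37
    f2 <- fitQuadraticSurface(obs)
    expect_equal(f1@r2, f2@r2, tolerance = 1e-12)
})

test_that("degenerate designs raise informative errors", {
    one <- data.frame(t = rep(c(0, 1, 3, 5, 7, 14, 21, 30, 45, 60, 90), 2),
                      T = 20, RH = 50)
    one$ratio <- exp(-0.05 * one$t)
    expect_error(fitQuadraticSurface(one), "rank|aliased")
    few <- surfaceObservations(builtinModel("carbendazim", "wheat"))[1:10, ]
    expect_error(fitQuadraticSurface(few), "insufficient|10")
})

test_that("a pure-noise response gives a small R-squared", {
    set.seed(43)
    obs <- expand.grid(t = c(0, 10, 30, 60, 90), T = c(20, 30, 40, 50),
                       RH = c(50, 60, 70, 80))
    obs$ratio <- rnorm(nrow(obs))
    fit <- fitQuadraticSurface(obs)
    expect_lt(fit@r2, 0.4)
    expect_true(all(fit@coefP >= 0 & fit@coefP <= 1))
})

test_that("effect analysis flags an injected temperature effect only", {
    set.seed(57)
    cells <- expand.grid(temperature_C = c(20, 30, 40, 50),
                         rh_pct = c(50, 60, 70, 80))
    hitsT <- 0; hitsRH <- 0
    for (r in 1:20) {
        d <- cells[rep(seq_len(nrow(cells)), each = 3), ]
        d$auc <- 10 + 0.2 * (d$temperature_C - 35) + rnorm(nrow(d), 0, 1)
        et <- effectAnova(d)
        hitsT <- hitsT + (et@pT < 0.05)
        hitsRH <- hitsRH + (et@pRH < 0.05)
    }
    expect_gte(hitsT, 19)   # strong true temperature effect
    expect_lte(hitsRH, 4)   # null humidity factor rejects rarely
})

test_that("identical AUC in every cell gives F = 0 and p = 1", {
    d <- expand.grid(temperature_C = c(20, 30), rh_pct = c(50, 60))
    d <- d[rep(1:4, each = 2), ]
    d$auc <- 5
    et <- effectAnova(d)
    expect_identical(c(et@pT, et@pRH, et@pInt), c(1, 1, 1))
    expect_true(all(et@table$F == 0))
})

test_that("unreplicated tables use Tukey's one-degree nonadditivity test", {
    set.seed(61)
    d <- expand.grid(temperature_C = c(20, 30, 40, 50),
                     rh_pct = c(50, 60, 70, 80))
    d$auc <- 10 - 0.1 * d$temperature_C + 0.05 * d$rh_pct + rnorm(16, 0, 0.2)
    et <- effectAnova(d)
    expect_match(et@method, "Tukey")
    expect_true(all(c(et@pT, et@pRH, et@pInt) >= 0 &
                    c(et@pT, et@pRH, et@pInt) <= 1))
    expect_error(effectAnova(data.frame(temperature_C = 20,
                                        rh_pct = c(50, 60),
                                        auc = c(1, 2))),
                 "2 levels")
})
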