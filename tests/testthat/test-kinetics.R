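test_that("ratio normalisation divides by the day-0 value and is idempotent", {
    tc <- makeTimecourse(c(0, 10), c(2, 1))
    r <- toRatios(tc)
    expect_identical(r@data$concentration, c(1, 0.5))
    expect_identical(toRatios(r)@data, r@data)
    expect_identical(r@temperatureC, tc@temperatureC)  # metadata preserved

    expect_error(toRatios(makeTimecourse(c(0, 10), c(0, 1))),
                 "normalization")
    expect_error(toRatios(makeTimecourse(c(1, 10), c(2, 1))),
                 "normalization")
})

test_that("first-order fit recovers the rate of noiseless exponentials", {
    tc <- expCourse(k = log(2) / 10)
    fit <- fitFirstOrder(tc)
    expect_equal(fit@k, 0.0693147, tolerance = 1e-5)
    expect_equal(halfLife(fit), 10, tolerance = 1e-9)
    expect_equal(fit@r2LogLinear, 1, tolerance = 1e-12)

    set.seed(23)  # randomized rates, initial levels and schedules
    for (i in 1:25) {
        k <- runif(1, 0.01, 0.5)
        c0 <- runif(1, 0.05, 5)
        days <- sort(sample(0:90, sample(5:15, 1)))
        fit <- fitFirstOrder(expCourse(k, c0, days))
        expect_equal(fit@k, k, tolerance = 1e-9)
        expect_equal(fit@c0Hat, c0, tolerance = 1e-9)
        expect_equal(halfLife(fit), log(2) / k, tolerance = 1e-9)
    }
})

test_that("flat or censored series are handled explicitly", {
    expect_warning(fit <- fitFirstOrder(makeTimecourse(c(0, 5, 10),
                                                       rep(0.4, 3))),
                   "infinite")
    expect_equal(fit@k, 0, tolerance = 1e-12)
    expect_identical(halfLife(fit), Inf)

    tc <- makeTimecourse(c(0, 5, 10, 20), c(1, 0.5, 0.1, 0.001),
                         censored = c(FALSE, FALSE, FALSE, TRUE))
    expect_warning(fit <- fitFirstOrder(tc), "excluded")
    expect_identical(fit@nUsed, 3L)

    expect_error(suppressWarnings(
        fitFirstOrder(makeTimecourse(c(0, 5), c(1, 0.5),
                                     censored = c(FALSE, TRUE)))),
        "fewer than 2")
})

test_that("percent decrease matches direct arithmetic and interpolates", {
    tc <- makeTimecourse(c(0, 45, 90), c(1, 0.4, 0.1317))
    expect_equal(percentDecrease(tc, 90), 86.83, tolerance = 1e-12)
    expect_identical(percentDecrease(makeTimecourse(c(0, 90), c(1, 1)), 90), 0)
    # linear interpolation between days 45 and 90
    expect_equal(percentDecrease(tc, 67.5), 100 * (1 - (0.4 + 0.1317) / 2),
                 tolerance = 1e-12)
    expect_error(percentDecrease(tc, 120), "range")
})

test_that("trapezoidal AUC matches geometric and closed-form oracles", {
    const <- makeTimecourse(seq(0, 90, by = 5), rep(1, 19))
    a <- aucTrapezoid(const)
    expect_identical(a@value, 90)
    expect_identical(a@tSpan, 90)

    tri <- aucTrapezoid(makeTimecourse(c(0, 10), c(1, 0)))
    expect_identical(tri@value, 5)

    # dense exponential vs (1 - exp(-k t_end)) / k within the trapezoid
    # error bound (t_span * max|c''| / 12) * h^2
    k <- 0.07; h <- 0.5; days <- seq(0, 90, by = h)
    a <- aucTrapezoid(makeTimecourse(days, exp(-k * days)))
    exact <- (1 - exp(-k * 90)) / k
    bound <- 90 * k^2 / 12 * h^2
    expect_lt(abs(a@value - exact), bound)

    expect_error(aucTrapezoid(makeTimecourse(0, 1)), "2 points")
})

test_that("kinetic summaries are scale-equivariant in concentration", {
    days <- c(0, 3, 7, 14, 30, 60)
    tc <- makeTimecourse(days, 0.8 * exp(-0.05 * days))
    sc <- makeTimecourse(days, 7 * 0.8 * exp(-0.05 * days))
    expect_equal(fitFirstOrder(sc)@k, fitFirstOrder(tc)@k, tolerance = 1e-12)
    expect_equal(halfLife(fitFirstOrder(sc)), halfLife(fitFirstOrder(tc)),
                 tolerance = 1e-12)
    expect_equal(percentDecrease(sc, 60), percentDecrease(tc, 60),
                 tolerance = 1e-12)
    expect_equal(aucTrapezoid(sc)@value, 7 * aucTrapezoid(tc)@value,
                 tolerance = 1e-12)
})

test_that("AUC decreases as the decay rate increases", {
    days <- c(0, 3, 7, 14, 30, 60, 90)
    aucs <- vapply(c(0.01, 0.03, 0.1, 0.3),
                   function(k) aucTrapezoid(
                       makeTimecourse(days, exp(-k * days)))@value,
                   numeric(1))
    expect_true(all(diff(aucs) < 0))
})

test_that("study-level summaries have one row per time course", {
    des <- studyDesign("flour", noiseCv = 0, lod = 0, seed = 3L)
    tcs <- generateStudy(list(triazophos = rateModelParams(0.08, aT = 0.02,
                                                           aRH = 0.01)), des)
    ks <- kineticsSummary(tcs)
    expect_identical(nrow(ks), 16L)
    expect_true(all(ks$half_life_days > 0))
    ab <- aucByCondition(tcs)
    expect_identical(nrow(ab), 16L)
    expect_true(all(ab$auc > 0))
})
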