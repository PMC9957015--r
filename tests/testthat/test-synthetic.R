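test_that("noiseless generation follows the closed-form decay", {
    des <- studyDesign("wheat", noiseCv = 0, c0 = 1, samplingDays = c(0, 10),
                       horizon = 90)
    p <- rateModelParams(kRef = 0.1, tRef = 20, rhRef = 50)
    tc <- generateTimecourse(p, 20, 50, des)
    expect_identical(tc@data$concentration[1], 1)        # day 0 exactly c0
    expect_equal(tc@data$concentration[2], exp(-1), tolerance = 1e-12)
})

test_that("generation is deterministic given the seed", {
    des <- studyDesign("wheat", noiseCv = 0.05, seed = 7L)
    p <- rateModelParams(0.05, aT = 0.02, aRH = 0.01)
    a <- generateTimecourse(p, 30, 60, des)
    b <- generateTimecourse(p, 30, 60, des)
    expect_identical(a@data, b@data)
    s1 <- generateStudy(list(carbendazim = p), des)
    s2 <- generateStudy(list(carbendazim = p), des)
    expect_identical(timecourseTable(s1), timecourseTable(s2))
})

test_that("study row counts follow the factorial layout", {
    des <- studyDesign("flour", noiseCv = 0, replicates = 1L)
    expect_length(des@samplingDays, 10)   # 60-day schedule
    p <- rateModelParams(0.05, aT = 0.02, aRH = 0.01)
    one <- generateStudy(list(a = p), des)
    expect_identical(nrow(timecourseTable(one)), 160L)
    five <- generateStudy(list(a = p, b = p, c = p, d = p, e = p), des)
    expect_identical(nrow(timecourseTable(five)), 800L)
    expect_error(generateStudy(list(), des), "empty")
    expect_error(generateStudy(list(a = p, a = p), des), "duplicate")
})

test_that("noiseless decay is strictly monotone in temperature and humidity", {
    p <- rateModelParams(0.03, tRef = 20, rhRef = 50, aT = 0.03, aRH = 0.01)
    des <- studyDesign("wheat", noiseCv = 0)
    atDay30 <- function(Tc, rh)
        generateTimecourse(p, Tc, rh, des)@data$concentration[
            des@samplingDays == 30]
    byT <- vapply(c(20, 30, 40, 50), atDay30, numeric(1), rh = 60)
    expect_true(all(diff(byT) < 0))
    byRH <- vapply(c(50, 60, 70, 80), atDay30, numeric(1), Tc = 30)
    expect_true(all(diff(byRH) < 0))
})

test_that("median-1 lognormal noise preserves the noiseless median", {
    des <- studyDesign("wheat", noiseCv = 0.05, replicates = 400L,
                       temperatures = 20, humidities = 50,
                       samplingDays = c(0, 30), seed = 11L)
    p <- rateModelParams(0.02)
    tcs <- generateStudy(list(x = p), des)
    tab <- timecourseTable(tcs)
    obs <- tab$concentration_mg_kg[tab$day == 30]
    expect_length(obs, 400)
    expect_equal(median(obs), exp(-0.02 * 30), tolerance = 0.01)
})

test_that("values below the LOD are substituted and flagged censored", {
    des <- studyDesign("wheat", noiseCv = 0, lod = 0.01, c0 = 1,
                       samplingDays = c(0, 30, 90))
    p <- rateModelParams(0.1)
    tc <- generateTimecourse(p, 20, 50, des)   # exp(-9) << lod at day 90
    expect_identical(tc@data$censored, c(FALSE, FALSE, TRUE))
    expect_identical(tc@data$concentration[3], 0.005)
})

test_that("rate-law calibration interpolates two half-life anchors exactly", {
    anchors <- data.frame(temperature_C = c(20, 50), rh_pct = 60,
                          half_life_days = c(10.27, 6.97))
    p <- calibrateToHalfLives(anchors)
    expect_equal(log(2) / rateConstant(p, 20, 60), 10.27, tolerance = 1e-12)
    expect_equal(log(2) / rateConstant(p, 50, 60), 6.97, tolerance = 1e-12)
    expect_identical(p@aRH, 0)  # humidity did not vary across anchors
    expect_gt(p@aT, 0)          # faster decay when warmer
})

test_that("a single anchor fixes both slopes at zero", {
    p <- calibrateToHalfLives(data.frame(temperature_C = 30, rh_pct = 60,
                                         half_life_days = 8))
    expect_identical(p@aT, 0)
    expect_identical(p@aRH, 0)
    expect_equal(p@kRef, log(2) / 8, tolerance = 1e-12)
})

test_that("anchors at a single condition are a rank error", {
    bad <- data.frame(temperature_C = c(30, 30), rh_pct = c(60, 60),
                      half_life_days = c(8, 10))
    expect_error(calibrateToHalfLives(bad), "rank")
})

test_that("generator round-trips the rate constant through the kinetic fit", {
    set.seed(5)
    des <- studyDesign("wheat", noiseCv = 0, lod = 0)
    for (i in 1:10) {
        p <- rateModelParams(runif(1, 0.01, 0.3), aT = runif(1, 0, 0.05),
                             aRH = runif(1, 0, 0.02))
        Tc <- sample(c(20, 30, 40, 50), 1)
        rh <- sample(c(50, 60, 70, 80), 1)
        fit <- fitFirstOrder(generateTimecourse(p, Tc, rh, des))
        expect_equal(fit@k, rateConstant(p, Tc, rh), tolerance = 1e-9)
    }
})
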