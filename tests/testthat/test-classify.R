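test_that("skeleton gate applies the 23.67-24.33 h period window", {
    spp <- buildRegime("SPP", intensity = 450)
    simE <- simulateFly(flySpec("entrained_locked", baseRate = 2,
                                seed = 51), spp, 8)
    callE <- classifySkeleton(simE$table)
    expect_equal(verdict(callE), "entrained")
    expect_true(evidence(callE)$peak_period_h >= 23.67 &&
                evidence(callE)$peak_period_h <= 24.33)

    simF <- simulateFly(flySpec("free_running", tauH = 23.2, baseRate = 2,
                                seed = 52), buildRegime("DD"), 8)
    callF <- classifySkeleton(simF$table)
    expect_equal(verdict(callF), "free_running")
    expect_lt(evidence(callF)$peak_period_h, 23.67)

    simA <- simulateFly(flySpec("arrhythmic", startleAmp = 0, baseRate = 2,
                                seed = 53), buildRegime("DD"), 8)
    callA <- classifySkeleton(simA$table)
    expect_equal(verdict(callA), "arrhythmic")
    expect_true(is.na(evidence(callA)$peak_period_h))

    short <- ActivityTable(activityCounts(simE$table)[1:(1440 * 4), ,
                                                      drop = FALSE])
    expect_error(classifySkeleton(short), "insufficient")
})

test_that("the skeleton gate is invariant to uniform count scaling", {
    spp <- buildRegime("SPP", intensity = 450)
    sim <- simulateFly(flySpec("entrained_locked", baseRate = 2,
                               seed = 54), spp, 8)
    tab5 <- ActivityTable(activityCounts(sim$table) * 5)
    c1 <- classifySkeleton(sim$table)
    c5 <- classifySkeleton(tab5)
    expect_equal(verdict(c1), verdict(c5))
    expect_equal(evidence(c1)$peak_period_h, evidence(c5)$peak_period_h)
    expect_equal(evidence(c1)$rhythmic_power,
                 evidence(c5)$rhythmic_power, tolerance = 1e-9)
})

test_that("ramp classification separates locked, free-running, arrhythmic", {
    ramp <- buildRegime("RAMP", iMin = 10, iMax = 45)
    simL <- simulateFly(flySpec("entrained_locked", baseRate = 2,
                                seed = 61), ramp, 9)
    expect_equal(verdict(classifyRamp(simL$table)), "entrained")

    simF <- simulateFly(flySpec("free_running", tauH = 25, baseRate = 2,
                                seed = 62), ramp, 9)
    expect_equal(verdict(classifyRamp(simF$table)), "free_running")

    simA <- simulateFly(flySpec("arrhythmic", baseRate = 2, seed = 63),
                        ramp, 9)
    expect_equal(verdict(classifyRamp(simA$table)), "arrhythmic")

    short <- ActivityTable(activityCounts(simL$table)[1:(1440 * 5), ,
                                                      drop = FALSE])
    expect_error(classifyRamp(short), "insufficient")
})

test_that("alternating-period segments read as relative coordination", {
    # period switches 23.3 -> 24.8 -> 23.3 in 3-day blocks: daily wavelet
    # periods leave the stable band and the phase drift reverses sign
    at <- simulateAlternatingFly(23.3, 24.8, blockDays = 3, nBlocks = 3,
                                 seed = 400)
    call <- classifyRamp(at)
    ev <- evidence(call)
    expect_equal(verdict(call), "relative_coordination")
    expect_false(ev$dailies_stable)
    # the wavelet tracks the programmed period excursion above the band
    expect_gt(max(ev$daily_periods_h, na.rm = TRUE), 24.5)
})

test_that("a parametrically entrained oscillator passes the ramp gate", {
    ramp <- buildRegime("RAMP", iMin = 10, iMax = 45)
    sim <- simulateFly(flySpec("oscillator", tauH = 24, psi0H = 10,
                               baseRate = 2, seed = 64), ramp, 9)
    call <- classifyRamp(sim$table)
    expect_equal(verdict(call), "entrained")
    ev <- evidence(call)
    expect_true(abs(ev$drift_min_per_cycle) <= 20)
    expect_true(ev$dailies_stable)
})

test_that("clock-mutant rhythmicity calls use peak or ridge evidence", {
    ramp <- buildRegime("RAMP", iMin = 10, iMax = 45)
    simA <- simulateFly(flySpec("arrhythmic", baseRate = 2, seed = 65),
                        ramp, 9)
    expect_false(isRhythmic(classifyRamp(simA$table)))
    simM <- simulateFly(flySpec("masker", baseRate = 3, seed = 66),
                        ramp, 9)
    expect_true(isRhythmic(classifyRamp(simM$table)))
})

test_that("cohort summaries report exact percentages", {
    mk <- function(v) new("EntrainmentCall", verdict = v, evidence = list())
    calls <- c(replicate(8, mk("entrained")),
               replicate(2, mk("free_running")))
    cs <- cohortSummary(calls)
    expect_equal(cs$percent[cs$verdict == "entrained"], 80)
    expect_equal(cs$percent[cs$verdict == "free_running"], 20)
    expect_equal(sum(cs$percent), 100)

    all4 <- cohortSummary(replicate(5, mk("arrhythmic")))
    expect_equal(all4$percent, 100)
    expect_error(cohortSummary(list()), "at least one")
})

test_that("verdicts are exhaustive and mutually exclusive on a mixed set", {
    ramp <- buildRegime("RAMP", iMin = 10, iMax = 45)
    specs <- c(makeSpecs(2, "entrained_locked", 700, baseRate = 2),
               makeSpecs(2, "free_running", 710, tauH = 25, baseRate = 2),
               makeSpecs(2, "arrhythmic", 720, baseRate = 2))
    co <- simulateCohort(specs, ramp, 9)
    calls <- lapply(co$tables, classifyRamp)
    vs <- vapply(calls, verdict, character(1))
    expect_true(all(vs %in% c("entrained", "relative_coordination",
                              "free_running", "arrhythmic")))
    cs <- cohortSummary(calls)
    expect_equal(sum(cs$n), 6L)
    expect_equal(sum(cs$percent), 100)
})
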