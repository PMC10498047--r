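test_that("simulation is deterministic under a fixed seed", {
    sp <- flySpec("oscillator", seed = 123)
    ramp <- buildRegime("RAMP", iMin = 10, iMax = 45)
    a <- simulateFly(sp, ramp, 3)
    b <- simulateFly(sp, ramp, 3)
    expect_identical(activityCounts(a$table), activityCounts(b$table))
    expect_identical(a$truth, b$truth)
    d <- simulateFly(sp, ramp, 3, seed = 124)
    expect_false(identical(activityCounts(a$table),
                           activityCounts(d$table)))
})

test_that("dark-limit phase advances at exactly 24/tau per hour", {
    sp <- flySpec("free_running", tauH = 25, psi0H = 3, seed = 1)
    # one Euler hour in darkness
    phi <- 3
    for (i in 1:60) phi <- advancePhase(phi, 0, 1, sp)
    expect_equal(phi, 3 + 24 / 25, tolerance = 1e-9)
})

test_that("realized dark period equals tau within one grid step", {
    for (tau in c(23.0, 25.5)) {
        sp <- flySpec("free_running", tauH = tau, baseRate = 2, seed = 17)
        sim <- simulateFly(sp, buildRegime("DD"), 10)
        call <- classifySkeleton(sim$table)
        expect_lt(abs(evidence(call)$peak_period_h - tau), 0.34)
    }
})

test_that("parametric gain lengthens the realized LL period beyond tau", {
    tau <- 23.8
    ll <- buildRegime("LL", intensity = 45)
    per <- vapply(c(0, 0.4), function(eps) {
        sp <- flySpec("oscillator", tauH = tau, epsP = eps, prcAmpH = 0,
                      baseRate = 2, seed = 19)
        sim <- simulateFly(sp, ll, 10)
        evidence(classifySkeleton(sim$table))$peak_period_h
    }, numeric(1))
    expect_lt(abs(per[1] - tau), 0.34)  # eps = 0: LL period is tau
    expect_gt(per[2], per[1] + 0.3)     # eps > 0: lengthening
})

test_that("realized LL period is non-decreasing in gain and intensity", {
    tau <- 23.8
    perByEps <- vapply(c(0.1, 0.25, 0.4), function(eps) {
        sp <- flySpec("oscillator", tauH = tau, epsP = eps, prcAmpH = 0,
                      baseRate = 2, seed = 23)
        sim <- simulateFly(sp, buildRegime("LL", intensity = 45), 10,
                           iRef = 45)
        evidence(classifySkeleton(sim$table))$peak_period_h
    }, numeric(1))
    expect_true(all(diff(perByEps) >= 0))

    perByI <- vapply(c(16, 30, 50), function(I) {
        sp <- flySpec("oscillator", tauH = tau, epsP = 0.4, prcAmpH = 0,
                      baseRate = 2, seed = 29)
        sim <- simulateFly(sp, buildRegime("LL", intensity = I), 10,
                           iRef = 50)
        evidence(classifySkeleton(sim$table))$peak_period_h
    }, numeric(1))
    expect_true(all(diff(perByI) >= 0))
})

test_that("transition jumps have the stated sign structure", {
    sp <- flySpec("oscillator", prcAmpH = 1, seed = 1)
    expect_gt(transitionJump(23, 1, sp), 23)        # subjective dawn: advance
    expect_lt(transitionJump(13, 1, sp), 13)        # early night: delay
    spNo <- flySpec("free_running", seed = 1)       # prcAmp 0: no-op
    expect_equal(transitionJump(13, 1, spNo), 13)
})

test_that("daily discrete pulses entrain a tau = 24.5 oscillator", {
    # skeleton pulses acting only through jumps (no parametric action)
    sp <- flySpec("oscillator", tauH = 24.5, epsP = 0, prcAmpH = 1.2,
                  psi0H = 2, baseRate = 2, seed = 37)
    spp <- buildRegime("SPP", intensity = 450)
    sim <- simulateFly(sp, spp, 12)
    ph <- sim$truth$phase_by_cycle
    # phase at cycle starts converges: last three cycles nearly constant
    drift <- abs(diff(tail(ph, 3)))
    expect_true(all(drift < 0.1))
    # and the realized period is 24 h
    call <- classifySkeleton(sim$table)
    expect_equal(evidence(call)$peak_period_h, 24)
})

test_that("emission rate composes waveform, masking and startle", {
    wf <- list(centers = c(0, 12), kappas = c(4, 4), weights = c(0.5, 0.5),
               baseline = 0.1)
    sp <- flySpec("oscillator", waveform = wf, baseRate = 3,
                  startleAmp = 6, startleDecayMin = 12, maskCoeff = 0,
                  seed = 1)
    rNo <- emissionRate(6, 0, Inf, sp)
    expect_gt(emissionRate(0, 0, Inf, sp), rNo)  # waveform bump at 0
    # immediately after lights-on the startle adds its full amplitude
    expect_equal(emissionRate(6, 1, 0, sp), rNo + 6, tolerance = 1e-9)
    # startle acts only within 60 min of a transition
    expect_equal(emissionRate(6, 1, 61, sp), rNo, tolerance = 1e-9)

    spMask <- flySpec("masker", maskCoeff = 1.5, baseRate = 3, seed = 1)
    expect_equal(emissionRate(4, 1, Inf, spMask),
                 3 * exp(-1.5), tolerance = 1e-9)
    expect_equal(emissionRate(4, 0, Inf, spMask), 3, tolerance = 1e-9)
})

test_that("masker activity under a ramp peaks near the intensity nadir", {
    ramp <- buildRegime("RAMP", iMin = 10, iMax = 45)
    sim <- simulateFly(flySpec("masker", baseRate = 3, seed = 9), ramp, 9)
    prof <- colMeans(splitDays(binActivity(sim$table, 15)))
    sm <- savitzkyGolay(prof, 1L, 41L)
    peakZt <- (which.max(sm) - 1) * 0.25
    dist <- pmin(peakZt, 24 - peakZt)  # circular distance from ZT00
    expect_lt(dist, 2)
})

test_that("cohort simulation writes monitor files plus truth", {
    dir <- withr::local_tempdir()
    flies <- c(makeSpecs(3, "entrained_locked", 100),
               makeSpecs(2, "arrhythmic", 200))
    ramp <- buildRegime("RAMP", iMin = 10, iMax = 45)
    co <- simulateCohort(flies, ramp, 2, dir = dir)
    expect_length(co$tables, 5)
    expect_equal(nrow(co$truth), 5)
    expect_true(file.exists(file.path(dir, "Monitor1.txt")))
    truth <- read.csv(file.path(dir, "truth.csv"))
    expect_equal(truth$mode,
                 rep(c("entrained_locked", "arrhythmic"), c(3, 2)))
    back <- readMonitorFile(file.path(dir, "Monitor1.txt"))
    expect_equal(unname(activityCounts(back)[, 1]),
                 unname(activityCounts(co$tables[[1]])[, 1]))
})

test_that("release switches to constant nadir light after the given cycle", {
    ramp <- buildRegime("RAMP", iMin = 10, iMax = 45)
    sched <- entrainR:::.lightSchedule(ramp, 12, releaseAfter = 9)
    expect_equal(sched$I[9 * 1440 + 1:10], rep(10, 10))
    expect_equal(sched$I[(9 * 1440 - 5):(9 * 1440)],
                 intensityAt(ramp, (1435:1440) - 1))
    expect_equal(max(sched$I[(9 * 1440 + 1):(12 * 1440)]), 10)
})
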