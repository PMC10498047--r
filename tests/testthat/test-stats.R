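test_that("ZT/angle conversion round-trips and wraps", {
    expect_equal(ztToAngle(6), pi / 2)
    expect_equal(ztToAngle(0), ztToAngle(24))
    set.seed(1)
    z <- runif(1000, -48, 96)
    expect_equal(angleToZt(ztToAngle(z)), z %% 24, tolerance = 1e-12)
})

test_that("Rayleigh R is exact in degenerate configurations", {
    expect_equal(unname(rayleighTest(rep(1.234, 12))$statistic), 1)
    grid <- 2 * pi * (0:7) / 8
    expect_equal(unname(rayleighTest(grid)$statistic), 0,
                 tolerance = 1e-12)
    expect_error(rayleighTest(0.3), "two angles")
})

test_that("Rayleigh R matches the direct complex-sum oracle", {
    set.seed(8)
    th <- rvonmises(32, mu = 1, kappa = 2)
    R <- unname(rayleighTest(th)$statistic)
    expect_equal(R, Mod(sum(exp(1i * th))) / 32, tolerance = 1e-12)
    # concentrated samples reject uniformity
    expect_lt(rayleighTest(th)$p.value, 0.01)
})

test_that("V-test hits its analytic extremes", {
    mu0 <- 0.7
    conc <- rep(mu0, 10)
    vt <- vTest(conc, mu0)
    expect_equal(unname(vt$estimate["V"]), 1)
    expect_lt(vt$p.value, 0.001)

    anti <- rep(mu0 + pi, 10)
    vtA <- vTest(anti, mu0)
    expect_equal(unname(vtA$estimate["V"]),
                 -unname(vtA$estimate["R"]))
    expect_gt(vtA$p.value, 0.99)
})

test_that("circular statistics are rotation invariant", {
    set.seed(12)
    th <- rvonmises(20, mu = 2, kappa = 1.5)
    for (rot in c(0.5, 2, 5)) {
        expect_equal(resultantLength((th + rot) %% (2 * pi)),
                     resultantLength(th), tolerance = 1e-12)
        expect_equal(rayleighTest((th + rot) %% (2 * pi))$p.value,
                     rayleighTest(th)$p.value, tolerance = 1e-12)
        expect_equal(vTest((th + rot) %% (2 * pi), (1 + rot))$p.value,
                     vTest(th, 1)$p.value, tolerance = 1e-10)
        m1 <- (circularMedian((th + rot) %% (2 * pi)) - rot) %% (2 * pi)
        expect_equal(m1, circularMedian(th), tolerance = 1e-10)
    }
})

test_that("V-test equals Rayleigh direction when mu0 is the sample mean", {
    set.seed(3)
    th <- rvonmises(25, mu = 4, kappa = 2)
    vt <- vTest(th, circularMean(th))
    expect_equal(unname(vt$estimate["V"]), unname(vt$estimate["R"]),
                 tolerance = 1e-12)
})

test_that("phase control is detected for locked and not for scattered", {
    set.seed(90)
    entrained <- (19 + rnorm(16, 0, 0.4)) %% 24
    lockedRelease <- (19 + rnorm(16, 0, 0.6)) %% 24
    pc <- assessPhaseControl(entrained, lockedRelease)
    expect_lt(pc$p.value, 0.01)

    scattered <- runif(16, 0, 24)
    pcS <- assessPhaseControl(entrained, scattered)
    expect_gt(pcS$p.value, 0.05)
    expect_error(assessPhaseControl(numeric(0), scattered), "non-empty")

    dup <- rep(19, 8)
    expect_lt(assessPhaseControl(entrained, dup)$p.value, 0.01)
})

test_that("4PL recovery from noisy data and exact interpolation", {
    true <- c(alpha_L = 23.9, delta = 3.4, eta = 0.15, phi_m = 30)
    dose <- rep(seq(0, 80, length.out = 15), each = 6)
    f <- function(x) true["alpha_L"] + true["delta"] /
        (1 + exp(-true["eta"] * (x - true["phi_m"])))
    # typical (median over fixed-seed replicates) recovery error
    errs <- vapply(1:10, function(s) {
        set.seed(s)
        y <- f(dose) + rnorm(length(dose), 0, 0.2)
        fit <- fitLogistic4(dose, y)
        expect_true(fit$converged)
        cf <- fit$coefficients
        c(abs(cf["alpha_L"] - true["alpha_L"]),
          abs(cf["delta"] - true["delta"]) / true["delta"],
          abs(cf["eta"] - true["eta"]) / true["eta"])
    }, numeric(3))
    med <- apply(errs, 1L, median)
    expect_lt(med[1], 0.1)   # alpha_L within 0.1 h
    expect_lt(med[2], 0.1)   # delta within 10%
    expect_lt(med[3], 0.1)   # eta within 10%

    # noiseless data are interpolated to numerical zero
    fit0 <- fitLogistic4(dose, f(dose))
    expect_lt(fit0$rss, 1e-10)

    # flat data: span collapses, RSS equals the flat-model RSS
    yf <- rep(24, 30) + rep(c(-0.01, 0.01), 15)
    doseF <- rep(c(10, 30, 50), each = 10)
    fitF <- fitLogistic4(doseF, yf)
    expect_lt(abs(fitF$rss - sum((yf - mean(yf))^2)), 1e-6)
})

test_that("flat-line ANOVA behaves at its boundary and under signal", {
    set.seed(56)
    dose <- rep(seq(5, 60, length.out = 15), each = 6)
    y <- 23.9 + 3.4 / (1 + exp(-0.15 * (dose - 30))) +
        rnorm(length(dose), 0, 0.2)
    fit <- fitLogistic4(dose, y)
    av <- anovaVsFlat(fit)
    expect_lt(av$p.value, 0.001)

    # RSS0 == RSS1 -> F = 0, p = 1
    fakeFit <- fit
    fakeFit$rss <- sum((y - mean(y))^2)
    avF <- anovaVsFlat(fakeFit)
    expect_equal(unname(avF$statistic), 0)
    expect_equal(avF$p.value, 1)

    expect_error(fitLogistic4(c(1, 2), c(1, 2)), "at least 4")
    expect_error(fitLogistic4(rep(c(1, 2), 4), rnorm(8)), "distinct doses")
})

test_that("Kruskal-Wallis H matches the direct rank-formula oracle", {
    groups <- list(a = c(3, 1, 4, 1, 5), b = c(9, 2, 6, 5, 3),
                   c = c(5, 8, 9, 7, 9))
    kw <- kruskalWithLetters(groups)
    expect_equal(kw$H, kwOracle(groups), tolerance = 1e-12)
    expect_equal(kw$H, unname(kruskal.test(groups)$statistic),
                 tolerance = 1e-12)
})

test_that("letter display separates disjoint groups and merges equals", {
    set.seed(2)
    same <- list(a = rnorm(12), b = rnorm(12))
    kwS <- kruskalWithLetters(same)
    expect_lt(kwS$H, 3)
    expect_equal(unname(kwS$letters["a"]), unname(kwS$letters["b"]))

    apart <- list(lo = 1:8, mid = 101:108, hi = 201:208)
    kwA <- kruskalWithLetters(apart)
    expect_lt(kwA$p, 0.01)
    expect_equal(length(unique(kwA$letters)), 3L)
    expect_error(kruskalWithLetters(list(a = 1:3)), "two groups")
})

test_that("rank-sum p matches full enumeration for small samples", {
    a <- c(1.2, 2.1, 2.3)
    b <- c(4.5, 5.1, 6.0, 7.2)
    w <- wilcoxonRankSum(a, b)
    expect_equal(w$p.value, wilcoxEnumOracle(a, b), tolerance = 1e-12)

    set.seed(91)
    a2 <- rnorm(6); b2 <- rnorm(5, 0.3)
    expect_equal(wilcoxonRankSum(a2, b2)$p.value,
                 wilcoxEnumOracle(a2, b2), tolerance = 1e-12)

    expect_equal(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
    expect_error(wilcoxonRankSum(numeric(0), 1:3), "non-empty")
})

test_that("a 3 h period shift is detected by the rank-sum test", {
    set.seed(10)
    dd <- 23.8 + rnorm(32, 0, 0.3)
    ll <- dd + 3 + rnorm(32, 0, 0.1)
    expect_lt(wilcoxonRankSum(dd, ll)$p.value, 1e-6)
})
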