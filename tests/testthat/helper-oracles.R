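# Independent brute-force oracles and cohort builders used across tests.

# windowed least-squares polynomial fit; returns the smoothed value at the
# centre of each full interior window
sgOracle <- function(x, order, frameLen) {
    n <- length(x)
    h <- (frameLen - 1L) %/% 2L
    out <- rep(NA_real_, n)
    for (i in (h + 1L):(n - h)) {
        idx <- (i - h):(i + h)
        tt <- idx - i
        fit <- lm(x[idx] ~ poly(tt, degree = order, raw = TRUE))
        out[i] <- unname(predict(fit)[h + 1L])
    }
    out
}

# direct fold implementation of the Sokolove-Bushell statistic for a trial
# period of K bins
qpOracle <- function(x, K) {
    n <- length(x)
    m <- mean(x)
    col <- ((seq_len(n) - 1L) %% K) + 1L
    Mh <- tapply(x, col, mean)
    nh <- tabulate(col, nbins = K)
    n * sum(nh * (Mh - m)^2) / sum((x - m)^2)
}

# exact two-sided rank-sum p-value by full enumeration (no ties)
wilcoxEnumOracle <- function(a, b) {
    na <- length(a)
    pooled <- c(a, b)
    r <- rank(pooled)
    wObs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    combs <- combn(length(pooled), na)
    ws <- apply(combs, 2L, function(idx) sum(r[idx]) - na * (na + 1) / 2)
    pLo <- mean(ws <= wObs)
    pHi <- mean(ws >= wObs)
    min(1, 2 * min(pLo, pHi))
}

# direct Kruskal-Wallis H with tie correction
kwOracle <- function(groups) {
    x <- unlist(groups, use.names = FALSE)
    g <- rep(seq_along(groups), lengths(groups))
    n <- length(x)
    r <- rank(x)
    H <- 12 / (n * (n + 1)) *
        sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
    ties <- table(x)
    H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# von Mises sampler (Best & Fisher rejection algorithm)
rvonmises <- function(n, mu, kappa) {
    out <- numeric(n)
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    i <- 0L
    while (i < n) {
        u <- runif(3)
        z <- cos(pi * u[1])
        f <- (1 + r * z) / (r + z)
        c0 <- kappa * (r - f)
        if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
            i <- i + 1L
            out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
        }
    }
    out
}

# closed-form phase of a light-blind free-runner after `days` cycles
freeRunPhaseAfter <- function(psi0, tauH, days) {
    (psi0 + days * 24 * (24 / tauH)) %% 24
}

# fly whose intrinsic period alternates between two values, built from
# phase-continuous free-running segments (counts concatenated)
simulateAlternatingFly <- function(tau1, tau2, blockDays, nBlocks, seed) {
    psi <- 0
    counts <- NULL
    for (k in seq_len(nBlocks)) {
        tau <- if (k %% 2L == 1L) tau1 else tau2
        sp <- flySpec("free_running", tauH = tau, psi0H = psi,
                      seed = seed + k)
        sim <- simulateFly(sp, buildRegime("DD"), blockDays)
        counts <- rbind(counts, activityCounts(sim$table))
        psi <- freeRunPhaseAfter(psi, tau, blockDays)
    }
    ActivityTable(counts)
}

# cohort of n specs of one mode with per-fly seeds and phase jitter
makeSpecs <- function(n, mode, seed0, tauH = 24, psi0H = 0, ...) {
    lapply(seq_len(n), function(i)
        flySpec(mode, tauH = tauH, psi0H = (psi0H + (i %% 5) * 0.1) %% 24,
                seed = seed0 + i, ...))
}
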