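## Period estimation: chi-square (Sokolove-Bushell) periodogram and Morlet
## continuous wavelet spectrum.

#' Chi-square (Sokolove-Bushell) periodogram
#'
#' Evaluates every trial period expressible as a whole number of bins inside
#' \code{periodRangeH}. For a trial period of K bins the series is folded
#' into K columns and
#' \deqn{Q_p = N \sum_h n_h (M_h - \bar M)^2 / \sum_i (x_i - \bar M)^2,}
#' with \eqn{N} the number of bins, \eqn{M_h} the column means over the
#' \eqn{n_h} samples falling in column \eqn{h}, and \eqn{\bar M} the grand
#' mean; under the null of no rhythm \eqn{Q_p \sim \chi^2_{K-1}}. The
#' significance line is the upper-\eqn{\alpha} chi-square quantile with
#' \eqn{K-1} degrees of freedom, by default Bonferroni-corrected across the
#' period grid. The peak is the largest Qp exceeding its significance line;
#' rhythmic power is peak Qp minus the line there (0 when no peak).
#'
#' @param x numeric series of (possibly smoothed) counts.
#' @param binMinutes bin width of \code{x} in minutes (default 20, which
#'   places 23.67, 24.00 and 24.33 h on the grid).
#' @param periodRangeH numeric length-2 period search range in hours.
#' @param alpha nominal significance level.
#' @param adjust \code{"bonferroni"} (default) corrects \code{alpha} across
#'   the tested-period grid; \code{"none"} leaves it uncorrected.
#' @return a [PeriodogramResult-class].
#' @examples
#' x <- rep(c(rep(5, 36), rep(0, 36)), 10)  # 24 h square wave, 20-min bins
#' pg <- chiSquarePeriodogram(x, binMinutes = 20)
#' peakPeriod(pg)
#' @export
chiSquarePeriodogram <- function(x, binMinutes = 20,
                                 periodRangeH = c(16, 32), alpha = 0.05,
                                 adjust = c("bonferroni", "none")) {
    adjust <- match.arg(adjust)
    x <- as.numeric(x)
    if (any(!is.finite(x))) stop("series must be finite")
    n <- length(x)
    kMin <- as.integer(ceiling(periodRangeH[1L] * 60 / binMinutes))
    kMax <- as.integer(floor(periodRangeH[2L] * 60 / binMinutes))
    if (kMax < kMin) stop("empty period grid for this bin width")
    if (n < 3L * kMax)
        stop("insufficient data: need >= 3 cycles of the longest tested ",
             "period (", 3L * kMax, " bins), got ", n)
    ks <- kMin:kMax
    periodsH <- ks * binMinutes / 60
    m <- mean(x)
    denom <- sum((x - m)^2)
    if (denom == 0) {
        qp <- rep(0, length(ks))
    } else {
        dev <- x - m
        qp <- vapply(ks, function(k) {
            col <- (seq_len(n) - 1L) %% k
            sums <- rowsum(dev, col, reorder = FALSE)
            nh <- tabulate(col + 1L, nbins = k)
            n * sum(sums^2 / nh) / denom
        }, numeric(1))
    }
    aAdj <- if (adjust == "bonferroni") alpha / length(ks) else alpha
    sig <- stats::qchisq(1 - aAdj, df = ks - 1L)
    isSig <- qp > sig & denom > 0
    if (any(isSig)) {
        peak <- which(isSig)[which.max(qp[isSig])]
        peakPeriodH <- periodsH[peak]
        power <- qp[peak] - sig[peak]
    } else {
        peakPeriodH <- NA_real_
        power <- 0
    }
    new("PeriodogramResult", periodsH = periodsH, qp = qp, sigLine = sig,
        alpha = alpha, adjusted = adjust == "bonferroni",
        peakPeriodH = peakPeriodH, rhythmicPower = power,
        binMinutes = binMinutes)
}

#' @describeIn chiSquarePeriodogram rhythmic power of a computed
#'   periodogram: peak Qp minus the significance line at the peak, 0 when no
#'   significant peak exists.
#' @param object a [PeriodogramResult-class].
#' @export
setMethod("rhythmicPower", "PeriodogramResult", function(object)
    object@rhythmicPower)

#' Significant local maxima of a periodogram
#'
#' Used to detect multiple competing periodicities (a relative-coordination
#' signature): local maxima of Qp that exceed the significance line,
#' separated by at least \code{minSepH} hours.
#'
#' @param result a [PeriodogramResult-class].
#' @param minSepH minimal separation between reported peaks in hours.
#' @return data.frame with columns \code{period_h}, \code{qp},
#'   \code{excess} (Qp minus significance line), ordered by decreasing Qp.
#' @export
periodogramPeaks <- function(result, minSepH = 1) {
    stopifnot(is(result, "PeriodogramResult"))
    qp <- result@qp
    sig <- result@sigLine
    p <- result@periodsH
    n <- length(qp)
    if (n < 3L) return(data.frame(period_h = numeric(0), qp = numeric(0),
                                  excess = numeric(0)))
    isMax <- c(FALSE, qp[2:(n - 1)] > qp[1:(n - 2)] &
                      qp[2:(n - 1)] >= qp[3:n], FALSE)
    ## grid ends count as maxima when rising toward them
    isMax[1L] <- qp[1L] > qp[2L]
    isMax[n] <- qp[n] > qp[n - 1L]
    cand <- which(isMax & qp > sig)
    cand <- cand[order(qp[cand], decreasing = TRUE)]
    keep <- integer(0)
    for (i in cand)
        if (!length(keep) || all(abs(p[i] - p[keep]) >= minSepH))
            keep <- c(keep, i)
    data.frame(period_h = p[keep], qp = qp[keep], excess = qp[keep] -
                   sig[keep])
}

#' Morlet continuous wavelet power spectrum
#'
#' FFT-based continuous wavelet transform with the analytic Morlet mother
#' wavelet (\eqn{\omega_0 = 6}), evaluated on a logarithmic period grid.
#' Power is normalized by the series variance, so white noise has expected
#' power of order 1. The cone of influence marks, for each time point, the
#' longest period free of edge effects (e-folding time \eqn{\sqrt{2} s}).
#'
#' @param x numeric series.
#' @param binMinutes bin width in minutes.
#' @param periodRangeH period range in hours (default 16-32).
#' @param voicesPerOctave scale resolution (default 50).
#' @param omega0 Morlet non-dimensional frequency (default 6).
#' @return a [WaveletSpectrum-class].
#' @export
morletWaveletSpectrum <- function(x, binMinutes = 15,
                                  periodRangeH = c(16, 32),
                                  voicesPerOctave = 50, omega0 = 6) {
    x <- as.numeric(x)
    n <- length(x)
    dtH <- binMinutes / 60
    if (n * dtH < 2 * periodRangeH[2L])
        stop("insufficient data: series must span at least twice the ",
             "longest analysed period")
    sd0 <- stats::sd(x)
    xn <- if (sd0 > 0) (x - mean(x)) / sd0 else rep(0, n)
    npad <- 2^ceiling(log2(n))
    fx <- stats::fft(c(xn, rep(0, npad - n)))
    ## angular frequencies of the padded grid
    k <- c(0:(npad %/% 2), -((npad - npad %/% 2 - 1):1)) * (2 * pi) /
        (npad * dtH)
    fourierFactor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
    nOct <- log2(periodRangeH[2L] / periodRangeH[1L])
    periodsH <- periodRangeH[1L] *
        2^(seq(0, nOct, by = 1 / voicesPerOctave))
    scales <- periodsH / fourierFactor
    power <- matrix(0, n, length(periodsH))
    pos <- k > 0
    norm0 <- pi^(-1 / 4) * sqrt(2 * pi / dtH)
    for (j in seq_along(scales)) {
        s <- scales[j]
        daughter <- numeric(npad)
        daughter[pos] <- norm0 * sqrt(s) * exp(-0.5 * (s * k[pos] - omega0)^2)
        w <- stats::fft(fx * daughter, inverse = TRUE) / npad
        power[, j] <- Mod(w[seq_len(n)])^2
    }
    timesH <- (seq_len(n) - 1L) * dtH
    edgeDist <- pmin(timesH, (n - seq_len(n)) * dtH)
    coi <- fourierFactor / sqrt(2) * edgeDist
    new("WaveletSpectrum", timesH = timesH, periodsH = periodsH,
        power = power, coi = coi)
}

#' Daily period estimates from a wavelet spectrum
#'
#' For each complete 24 h cycle covered by the spectrum, returns the ridge
#' period: the period of maximal time-averaged power within that cycle,
#' after masking every (time, period) cell lying outside the cone of
#' influence. A period only competes for the ridge when it is
#' edge-safe for at least \code{minCoverage} of the cycle's time points,
#' so edge cycles whose circadian band lies wholly inside the cone yield
#' \code{NA} instead of a short-period artifact.
#'
#' @param spectrum a [WaveletSpectrum-class].
#' @param minCoverage minimal fraction of a cycle's samples a period must
#'   have outside the cone of influence to be eligible (default 0.5).
#' @return data.frame with columns \code{cycle} (1-based index),
#'   \code{period_h} (NA when no estimate) and \code{ridge_power}.
#' @export
dailyPeriods <- function(spectrum, minCoverage = 0.5) {
    stopifnot(is(spectrum, "WaveletSpectrum"))
    nCyc <- floor((max(spectrum@timesH) + (spectrum@timesH[2L] -
                   spectrum@timesH[1L])) / 24)
    if (nCyc < 1L) stop("spectrum spans less than one complete cycle")
    res <- data.frame(cycle = seq_len(nCyc), period_h = NA_real_,
                      ridge_power = NA_real_)
    for (cc in seq_len(nCyc)) {
        idx <- which(spectrum@timesH >= (cc - 1) * 24 &
                     spectrum@timesH < cc * 24)
        pw <- spectrum@power[idx, , drop = FALSE]
        mask <- outer(spectrum@coi[idx], spectrum@periodsH,
                      function(coi, p) p > coi)
        pw[mask] <- NA_real_
        avg <- colMeans(pw, na.rm = TRUE)
        avg[!is.finite(avg)] <- NA_real_
        avg[colMeans(!mask) < minCoverage] <- NA_real_
        if (all(is.na(avg))) next
        j <- which.max(avg)
        res$period_h[cc] <- spectrum@periodsH[j]
        res$ridge_power[cc] <- avg[j]
    }
    res
}
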