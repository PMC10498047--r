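## Activity-profile averaging and peak-phase extraction.

#' Average daily activity profile across flies
#'
#' Computes each fly's mean day (across its complete ZT-aligned days) and
#' then averages across flies; the s.e.m. is the across-fly standard error
#' per bin.
#'
#' @param tables list of single- or multi-channel [ActivityTable-class]
#'   objects (one fly per entry; first channel used).
#' @param binMinutes profile bin width (default 30).
#' @param channel channel to take from each table.
#' @return an [ActivityProfile-class].
#' @export
averageProfile <- function(tables, binMinutes = 30, channel = 1L) {
    if (length(tables) == 0L) stop("need at least one fly")
    perFly <- vapply(tables, function(tb) {
        dm <- splitDays(binActivity(tb, binMinutes), channel = channel)
        if (nrow(dm) == 0L) stop("a fly has no complete day of data")
        colMeans(dm)
    }, numeric(1440 / binMinutes))
    perFly <- matrix(perFly, nrow = 1440 / binMinutes)
    mu <- rowMeans(perFly)
    nf <- ncol(perFly)
    sem <- if (nf > 1L) apply(perFly, 1L, stats::sd) / sqrt(nf)
           else rep(0, nrow(perFly))
    new("ActivityProfile", binMinutes = as.numeric(binMinutes), mean = mu,
        sem = sem, n = as.integer(nf))
}

#' Locate peaks in a smoothed series
#'
#' Smooths with the Savitzky-Golay filter, then returns local maxima whose
#' topographic prominence (height above the higher of the two flanking
#' bases) exceeds \code{prominenceFloor}, ordered by descending height.
#'
#' @param x numeric series (at least one cycle long for circadian use).
#' @param order,frameLen SG parameters (see [savitzkyGolay()]).
#' @param prominenceFloor minimal prominence; also the minimal absolute
#'   height (flat series yield no peaks).
#' @param smooth set \code{FALSE} if \code{x} is already smoothed.
#' @return data.frame with columns \code{index}, \code{height},
#'   \code{prominence} (possibly 0-row).
#' @export
findPeaks <- function(x, order = 2L, frameLen = 81L, prominenceFloor = 1e-8,
                      smooth = TRUE) {
    s <- if (smooth) savitzkyGolay(x, order, frameLen) else as.numeric(x)
    n <- length(s)
    if (n < 3L || max(s) - min(s) < prominenceFloor)
        return(data.frame(index = integer(0), height = numeric(0),
                          prominence = numeric(0)))
    isMax <- c(FALSE, s[2:(n - 1)] > s[1:(n - 2)] &
                      s[2:(n - 1)] >= s[3:n], FALSE)
    cand <- which(isMax)
    if (!length(cand))
        return(data.frame(index = integer(0), height = numeric(0),
                          prominence = numeric(0)))
    prom <- vapply(cand, function(i) {
        h <- s[i]
        left <- if (i > 1L) {
            higher <- which(s[1:(i - 1L)] > h)
            lo <- if (length(higher)) max(higher) + 1L else 1L
            min(s[lo:(i - 1L)])
        } else h
        right <- if (i < n) {
            higher <- which(s[(i + 1L):n] > h)
            hi <- if (length(higher)) i + min(higher) - 1L else n
            min(s[(i + 1L):hi])
        } else h
        h - max(left, right)
    }, numeric(1))
    keep <- prom >= prominenceFloor
    out <- data.frame(index = cand[keep], height = s[cand[keep]],
                      prominence = prom[keep])
    out[order(out$height, decreasing = TRUE), , drop = FALSE]
}

## circular mean of phases given in hours on a `periodH` cycle
circularMeanHours <- function(h, periodH = 24) {
    z <- mean(exp(1i * 2 * pi * h / periodH))
    (Arg(z) * periodH / (2 * pi)) %% periodH
}

#' Evening-peak phase of an entrained fly
#'
#' Applies the SG peak-finding filter to the raw 1-min data, then, for each
#' of the last \code{lastDays} complete days, takes the highest smoothed
#' peak inside the evening search window, excluding bins within
#' \code{guardMin} minutes after any discrete light transition (startle
#' guard). Per-day phases are combined by circular mean.
#'
#' @param table single-fly [ActivityTable-class] at 1-min cadence.
#' @param regime the entraining [LightRegime-class] (for the startle guard).
#' @param order,frameLen SG parameters (default preset: order 2, frame 81).
#' @param windowZt numeric length-2 evening search window in ZT hours
#'   (default ZT06-ZT15).
#' @param guardMin startle guard duration after each discrete transition.
#' @param lastDays number of trailing entrained days to pool (default 5).
#' @param channel channel index.
#' @return list with \code{zt_h} (circular-mean phase in [0, 24), NA when no
#'   qualifying peak on any day), \code{height}, \code{kind = "evening"} and
#'   \code{per_day} (the per-day phases).
#' @export
eveningPeakPhase <- function(table, regime, order = 2L, frameLen = 81L,
                             windowZt = c(6, 15), guardMin = 30,
                             lastDays = 5L, channel = 1L) {
    stopifnot(is(table, "ActivityTable"), table@binMinutes == 1)
    sm <- savitzkyGolay(table@counts[, channel], order, frameLen)
    smTab <- ActivityTable(pmax(sm, 0), binMinutes = 1,
                           zt0Offset = table@zt0Offset)
    dm <- splitDays(smTab, channel = 1L)
    if (nrow(dm) == 0L) stop("no complete day of data")
    useDays <- tail(seq_len(nrow(dm)), lastDays)
    tr <- transitions(regime)
    guard <- rep(FALSE, 1440)
    if (nrow(tr))
        for (z in tr$zt_min)
            guard[(seq(z, z + guardMin - 1) %% 1440) + 1] <- TRUE
    zt <- (seq_len(1440) - 1) / 60
    inWindow <- zt >= windowZt[1L] & zt < windowZt[2L] & !guard
    phases <- heights <- numeric(0)
    for (d in useDays) {
        day <- dm[d, ]
        pk <- findPeaks(day, smooth = FALSE)
        pk <- pk[inWindow[pk$index], , drop = FALSE]
        if (nrow(pk)) {
            phases <- c(phases, zt[pk$index[1L]])
            heights <- c(heights, pk$height[1L])
        }
    }
    if (!length(phases))
        return(list(zt_h = NA_real_, height = NA_real_, kind = "evening",
                    per_day = numeric(0)))
    list(zt_h = circularMeanHours(phases), height = mean(heights),
         kind = "evening", per_day = phases)
}

#' Dominant peak phase on the first day after release
#'
#' Bins the whole recording to 15 min, smooths with SG(order 1, frame 41)
#' over the full series (so the release day carries no filter edge
#' transient), and returns the dominant peak within the first complete
#' cycle after release into constant conditions.
#'
#' @param table single-fly [ActivityTable-class] at 1-min cadence covering
#'   at least one full day after \code{releaseStartMin}.
#' @param releaseStartMin minutes from recording start to the release into
#'   constant conditions.
#' @param channel channel index.
#' @return list with \code{zt_h} (phase of the dominant peak in ZT hours of
#'   the projected cycle, NA when no peak), \code{height} and
#'   \code{kind = "release_day"}.
#' @export
releaseDayPhase <- function(table, releaseStartMin, channel = 1L) {
    stopifnot(is(table, "ActivityTable"), table@binMinutes == 1)
    if (nBins(table) < releaseStartMin + 1440)
        stop("need at least one full day after release")
    b15 <- binActivity(table, 15)
    sm <- savitzkyGolay(b15@counts[, channel], 1L, 41L)
    pk <- findPeaks(sm, smooth = FALSE)
    dayBins <- (releaseStartMin %/% 15L) + seq_len(96L)
    pk <- pk[pk$index %in% dayBins, , drop = FALSE]
    if (!nrow(pk))
        return(list(zt_h = NA_real_, height = NA_real_,
                    kind = "release_day"))
    zt <- (((pk$index[1L] - 1L) * 15 - table@zt0Offset) %% 1440) / 60
    list(zt_h = zt, height = pk$height[1L], kind = "release_day")
}
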