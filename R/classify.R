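## Entrainment verdicts: the skeleton-photoperiod period-window gate and
## the four-way ramped-cycle classification.

.ENTRAIN_WINDOW_H <- c(23.67, 24.33)   # periodogram period window
.WAVELET_BAND_H <- c(23.5, 24.5)       # daily wavelet period band (wider:
                                       # the wavelet method varies more)

#' Classify a fly under a skeleton photoperiod (or any stepped LD cycle)
#'
#' The entrainment gate, in two strands:
#' \itemize{
#'   \item rhythmicity is assessed on the raw binned counts, whose
#'     chi-square periodogram null is calibrated (smoothing makes the
#'     series strongly autocorrelated and would wildly inflate the
#'     significance of spurious long-period peaks);
#'   \item the period value is read from the periodogram of the
#'     SG-smoothed series (entrainment preset: order 2, frame 251 min),
#'     which stops startle spikes at light transitions from dragging the
#'     peak to the startle period; when the smoothed periodogram shows no
#'     peak the raw peak is used.
#' }
#' Verdicts: \code{entrained} if rhythmic with period in [23.67, 24.33] h;
#' \code{free_running} if rhythmic with period outside that window;
#' \code{arrhythmic} if no significant raw peak.
#'
#' @param table single-fly 1-min [ActivityTable-class] with >= 6 days.
#' @param channel channel index.
#' @param binMinutes periodogram bin width (default 20 min, placing 23.67
#'   and 24.33 h on the grid).
#' @param periodRangeH,alpha,adjust periodogram settings (see
#'   [chiSquarePeriodogram()]).
#' @param sgOrder,sgFrame smoothing parameters in 1-min samples.
#' @return an [EntrainmentCall-class] (never \code{relative_coordination};
#'   that verdict needs the multi-cycle ramp evidence).
#' @export
classifySkeleton <- function(table, channel = 1L, binMinutes = 20,
                             periodRangeH = c(16, 32), alpha = 0.05,
                             adjust = "bonferroni", sgOrder = 2L,
                             sgFrame = 251L) {
    stopifnot(is(table, "ActivityTable"), table@binMinutes == 1)
    if (nDays(table) < 6L)
        stop("insufficient data: need >= 6 complete days")
    x <- table@counts[, channel]
    nb <- length(x) %/% binMinutes
    grp <- rep(seq_len(nb), each = binMinutes)
    bRaw <- as.vector(rowsum(x[seq_len(nb * binMinutes)], grp))
    pgRaw <- chiSquarePeriodogram(bRaw, binMinutes = binMinutes,
                                  periodRangeH = periodRangeH,
                                  alpha = alpha, adjust = adjust)
    sm <- savitzkyGolay(x, sgOrder, sgFrame)
    bSm <- as.vector(rowsum(sm[seq_len(nb * binMinutes)], grp))
    pgSm <- chiSquarePeriodogram(bSm, binMinutes = binMinutes,
                                 periodRangeH = periodRangeH,
                                 alpha = alpha, adjust = adjust)
    rhythmic <- !is.na(pgRaw@peakPeriodH)
    peak <- if (!rhythmic) NA_real_
        else if (!is.na(pgSm@peakPeriodH)) pgSm@peakPeriodH
        else pgRaw@peakPeriodH
    verdict <- if (!rhythmic) "arrhythmic"
        else if (peak >= .ENTRAIN_WINDOW_H[1L] &&
                 peak <= .ENTRAIN_WINDOW_H[2L]) "entrained"
        else "free_running"
    new("EntrainmentCall", verdict = verdict,
        evidence = list(peak_period_h = peak,
                        rhythmic_power = pgRaw@rhythmicPower,
                        significant = rhythmic,
                        window_h = .ENTRAIN_WINDOW_H,
                        periodogram = pgSm,
                        periodogram_raw = pgRaw))
}

## per-cycle dominant peak phases (15-min bins, SG(1,41)), in ZT hours
.cyclePeakPhases <- function(table, cycles, channel = 1L) {
    b15 <- binActivity(table, 15)
    sm <- savitzkyGolay(b15@counts[, channel], 1L, 41L)
    dm <- splitDays(ActivityTable(pmax(sm, 0), binMinutes = 15,
                                  zt0Offset = b15@zt0Offset))
    out <- rep(NA_real_, length(cycles))
    for (k in seq_along(cycles)) {
        d <- cycles[k]
        if (d > nrow(dm)) next
        pk <- findPeaks(dm[d, ], smooth = FALSE)
        if (nrow(pk)) out[k] <- (pk$index[1L] - 1L) * 15 / 60
    }
    out
}

## per-cycle circular centre of gravity of smoothed activity, in ZT hours;
## far less jittery than the argmax on flat-topped waveforms, so this is
## what the drift criterion uses
.cycleCogPhases <- function(table, cycles, channel = 1L) {
    b15 <- binActivity(table, 15)
    sm <- savitzkyGolay(b15@counts[, channel], 1L, 41L)
    dm <- splitDays(ActivityTable(pmax(sm, 0), binMinutes = 15,
                                  zt0Offset = b15@zt0Offset))
    ang <- 2 * pi * (seq_len(ncol(dm)) - 1L) / ncol(dm)
    out <- rep(NA_real_, length(cycles))
    for (k in seq_along(cycles)) {
        d <- cycles[k]
        if (d > nrow(dm)) next
        w <- dm[d, ] - min(dm[d, ])
        if (sum(w) <= 0) next
        out[k] <- (Arg(sum(w * exp(1i * ang))) * 24 / (2 * pi)) %% 24
    }
    out
}

## mean signed per-cycle drift (min/cycle) of phases in hours, using
## wrapped successive differences; NA when < 2 phases
.phaseDrift <- function(phases) {
    ph <- phases[!is.na(phases)]
    if (length(ph) < 2L) return(list(slope = NA_real_, diffs = numeric(0)))
    d <- diff(ph)
    d <- ((d + 12) %% 24) - 12
    list(slope = mean(d) * 60, diffs = d * 60)
}

#' Classify a fly under ramped light cycles
#'
#' Four-way classification from three strands of evidence over >= 9 ramp
#' cycles: the chi-square periodogram of the SG-smoothed series, daily
#' wavelet period estimates, and the drift of the per-cycle activity phase
#' (circular centre of gravity of the smoothed waveform; the per-cycle
#' dominant peak is reported as evidence alongside) after the
#' stabilization cycle. First matching rule wins:
#' \enumerate{
#'   \item \code{arrhythmic}: no significant periodogram peak and no
#'     detectable wavelet ridge;
#'   \item \code{entrained}: daily wavelet periods for cycles
#'     \code{stableFrom}+ all within [23.5, 24.5] h, absolute mean phase
#'     drift over the final cycles at most \code{driftMaxMin} min/cycle,
#'     and periodogram peak within [23.67, 24.33] h;
#'   \item \code{free_running}: phase drifting monotonically in one
#'     direction (all successive per-cycle shifts of one sign and mean
#'     drift beyond \code{driftMaxMin}) together with a significant
#'     periodogram peak outside the entrainment window;
#'   \item \code{relative_coordination}: everything else (multiple
#'     periodogram peaks, unstable daily periods, non-monotone or
#'     partially arrested drift).
#' }
#'
#' Because the smoothing filter's boundary region overlaps the final
#' cycle, phase drift is judged on cycles \code{stableFrom} to
#' \code{nCycles - 1}.
#'
#' @param table single-fly 1-min [ActivityTable-class] with >= 9 cycles.
#' @param channel channel index.
#' @param stableFrom cycle by which entrained timing must have stabilized
#'   (default 6).
#' @param driftMaxMin maximal absolute stable-phase drift, min/cycle
#'   (default 20).
#' @param ridgeThreshold minimal cycle-median wavelet ridge power (in
#'   variance units) for a detectable ridge (default 2; white noise is
#'   order 1).
#' @param nCycles number of ramp cycles to analyse (default 9; trailing
#'   release days beyond this are ignored here).
#' @param alpha significance level for the periodogram.
#' @return an [EntrainmentCall-class].
#' @export
classifyRamp <- function(table, channel = 1L, stableFrom = 6L,
                         driftMaxMin = 20, ridgeThreshold = 2,
                         nCycles = 9L, alpha = 0.05) {
    stopifnot(is(table, "ActivityTable"), table@binMinutes == 1)
    if (nDays(table) < nCycles)
        stop("insufficient data: need >= ", nCycles, " ramp cycles")
    x <- table@counts[seq_len(nCycles * 1440L), channel]
    rampTab <- ActivityTable(x, binMinutes = 1,
                             zt0Offset = table@zt0Offset)

    ## periodogram strand: significance from raw binned counts (calibrated
    ## null), period value from the SG-smoothed series as in the skeleton
    ## gate
    nb <- length(x) %/% 20L
    grp <- rep(seq_len(nb), each = 20L)
    pgRaw <- chiSquarePeriodogram(
        as.vector(rowsum(x[seq_len(nb * 20L)], grp)),
        binMinutes = 20, alpha = alpha)
    sm <- savitzkyGolay(x, 2L, 251L)
    pgSm <- chiSquarePeriodogram(
        as.vector(rowsum(sm[seq_len(nb * 20L)], grp)),
        binMinutes = 20, alpha = alpha)
    pks <- periodogramPeaks(pgRaw)
    peak <- if (is.na(pgRaw@peakPeriodH)) NA_real_
        else if (!is.na(pgSm@peakPeriodH)) pgSm@peakPeriodH
        else pgRaw@peakPeriodH
    peakInWindow <- !is.na(peak) && peak >= .ENTRAIN_WINDOW_H[1L] &&
        peak <= .ENTRAIN_WINDOW_H[2L]

    ## wavelet strand (15-min bins, raw counts)
    b15 <- binActivity(rampTab, 15)
    ws <- morletWaveletSpectrum(b15@counts[, 1L], binMinutes = 15)
    dp <- dailyPeriods(ws)
    stableCycles <- dp[dp$cycle >= stableFrom, , drop = FALSE]
    ridgeDetectable <- any(is.finite(dp$ridge_power)) &&
        stats::median(dp$ridge_power, na.rm = TRUE) >= ridgeThreshold
    ## edge cycles with no coi-safe circadian estimate are missing, not
    ## unstable; need >= 2 valid post-stabilization estimates
    validDailies <- stableCycles$period_h[!is.na(stableCycles$period_h)]
    dailiesStable <- length(validDailies) >= 2L &&
        all(validDailies >= .WAVELET_BAND_H[1L] &
            validDailies <= .WAVELET_BAND_H[2L])

    ## phase-drift strand; the last cycle sits in the filter's boundary
    ## region and is excluded
    driftCycles <- stableFrom:(nCycles - 1L)
    phases <- .cyclePeakPhases(rampTab, driftCycles, channel = 1L)
    cog <- .cycleCogPhases(rampTab, driftCycles, channel = 1L)
    drift <- .phaseDrift(cog)
    driftOk <- !is.na(drift$slope) && abs(drift$slope) <= driftMaxMin
    monotoneDrift <- length(drift$diffs) >= 2L &&
        (all(drift$diffs > 0) || all(drift$diffs < 0)) &&
        abs(drift$slope) > driftMaxMin

    verdict <- if (is.na(peak) && !ridgeDetectable) "arrhythmic"
        else if (dailiesStable && driftOk && peakInWindow) "entrained"
        else if (monotoneDrift && !is.na(peak) && !peakInWindow)
            "free_running"
        else "relative_coordination"

    new("EntrainmentCall", verdict = verdict,
        evidence = list(peak_period_h = peak,
                        rhythmic_power = pgRaw@rhythmicPower,
                        n_sig_peaks = nrow(pks),
                        daily_periods_h = dp$period_h,
                        dailies_stable = dailiesStable,
                        ridge_detectable = ridgeDetectable,
                        drift_min_per_cycle = drift$slope,
                        drift_ok = driftOk,
                        monotone_drift = monotoneDrift,
                        stable_phases_zt_h = phases,
                        stable_cog_zt_h = cog))
}

#' Rhythmicity call for loss-of-function clock mutants
#'
#' For clock mutants the question is not the verdict category but whether
#' any rhythm is detectable at all: rhythmic iff the periodogram shows a
#' significant peak or the wavelet spectrum a detectable ridge.
#'
#' @param call an [EntrainmentCall-class] from [classifyRamp()].
#' @return logical.
#' @export
isRhythmic <- function(call) {
    stopifnot(is(call, "EntrainmentCall"))
    ev <- call@evidence
    (!is.null(ev$peak_period_h) && !is.na(ev$peak_period_h)) ||
        isTRUE(ev$ridge_detectable)
}

#' Summarize a cohort of entrainment calls
#'
#' @param calls list of [EntrainmentCall-class] objects (>= 1).
#' @return data.frame with columns \code{verdict}, \code{n},
#'   \code{percent}; percentages sum to 100 within rounding.
#' @examples
#' calls <- replicate(4, new("EntrainmentCall", verdict = "entrained",
#'                           evidence = list()))
#' cohortSummary(calls)
#' @export
cohortSummary <- function(calls) {
    if (!length(calls)) stop("need at least one call")
    v <- vapply(calls, verdict, character(1))
    tab <- table(factor(v, levels = .VERDICTS))
    tab <- tab[tab > 0]
    data.frame(verdict = names(tab), n = as.integer(tab),
               percent = 100 * as.integer(tab) / length(v),
               row.names = NULL)
}
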