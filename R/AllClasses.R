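#' @import methods
NULL

#' ActivityTable: beam-crossing counts on a regular time grid
#'
#' Container for Drosophila Activity Monitor (DAM) style recordings: an
#' integer count matrix with one row per time bin (native cadence 1 min) and
#' one column per monitor channel (fly). The time axis is implicit and
#' strictly regular: bin \code{i} covers minutes
#' \code{[(i-1)*binMinutes, i*binMinutes)} since recording start.
#' \code{zt0Offset} gives the number of minutes from recording start to the
#' first Zeitgeber Time 00 (lights-on of the entraining cycle), so recordings
#' and light regimes stay independent records.
#'
#' @slot counts integer matrix, time bins x channels; non-negative.
#' @slot binMinutes single positive number of minutes per bin; must divide
#'   1440.
#' @slot zt0Offset minutes from recording start to the first ZT00, in
#'   \code{[0, 1440)}.
#' @slot flagged integer vector of 1-based row indices whose monitor status
#'   was not the OK code when read from disk (counts at those rows were
#'   zeroed, never silently dropped).
#'
#' @seealso [readMonitorFile()], [binActivity()], [splitDays()]
#' @exportClass ActivityTable
setClass("ActivityTable",
    representation(
        counts = "matrix",
        binMinutes = "numeric",
        zt0Offset = "numeric",
        flagged = "integer"
    ),
    prototype(
        counts = matrix(integer(0), 0, 0),
        binMinutes = 1,
        zt0Offset = 0,
        flagged = integer(0)
    )
)

setValidity("ActivityTable", function(object) {
    msg <- character(0)
    cts <- object@counts
    if (!is.numeric(cts))
        msg <- c(msg, "counts must be a numeric matrix")
    else {
        if (any(!is.finite(cts)))
            msg <- c(msg, "counts must be finite")
        else if (any(cts < 0))
            msg <- c(msg, "counts must be >= 0")
    }
    bm <- object@binMinutes
    if (length(bm) != 1L || !is.finite(bm) || bm <= 0 || bm != round(bm))
        msg <- c(msg, "binMinutes must be a single positive integer")
    else if (1440 %% bm != 0)
        msg <- c(msg, "binMinutes must divide 1440")
    z <- object@zt0Offset
    if (length(z) != 1L || !is.finite(z) || z < 0 || z >= 1440)
        msg <- c(msg, "zt0Offset must lie in [0, 1440)")
    if (length(object@flagged) &&
        (min(object@flagged) < 1L || max(object@flagged) > nrow(cts)))
        msg <- c(msg, "flagged indices out of range")
    if (length(msg)) msg else TRUE
})

#' Construct an ActivityTable
#'
#' @param counts numeric matrix (time bins x channels) or a vector for a
#'   single channel; values must be non-negative and finite.
#' @param binMinutes minutes per bin (default 1, the native DAM cadence).
#' @param zt0Offset minutes from recording start to the first ZT00.
#' @param flagged integer indices of rows flagged on read.
#' @return an [ActivityTable-class] object.
#' @examples
#' at <- ActivityTable(matrix(rpois(2880, 1), ncol = 2))
#' nBins(at)
#' @export
ActivityTable <- function(counts, binMinutes = 1, zt0Offset = 0,
                          flagged = integer(0)) {
    if (is.vector(counts)) counts <- matrix(counts, ncol = 1L)
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("ch", seq_len(ncol(counts)))
    new("ActivityTable", counts = counts, binMinutes = as.numeric(binMinutes),
        zt0Offset = as.numeric(zt0Offset), flagged = as.integer(flagged))
}

#' LightRegime: piecewise light intensity over one Zeitgeber cycle
#'
#' A light schedule represented as ordered segments tiling \code{[0, 1440)}
#' ZT minutes, each with a start and end intensity (constant when equal,
#' linear in between). Supported kinds: \code{LD} (12 h light : 12 h dark),
#' \code{SPP} (symmetric skeleton photoperiod: two 30 min pulses, one
#' starting at dawn and one ending at dusk), \code{aSPP1} (6 h dawn light
#' plus a 30 min pulse ending at dusk), \code{aSPP2} (a 30 min pulse starting
#' at dawn plus 6 h of light ending at dusk), \code{RAMP} (linear rise from
#' \code{I_min} at ZT00 to \code{I_max} at ZT12, then linear fall back;
#' never dark), \code{LL} and \code{DD}.
#'
#' @slot kind character, one of LD, SPP, aSPP1, aSPP2, RAMP, LL, DD.
#' @slot segments data.frame with columns \code{start}, \code{end} (ZT
#'   minutes) and \code{i0}, \code{i1} (intensity at segment start/end).
#' @slot periodH cycle length in hours (24).
#' @slot units intensity unit label (display only; no conversion applied).
#' @seealso [buildRegime()], [intensityAt()], [transitions()]
#' @exportClass LightRegime
setClass("LightRegime",
    representation(kind = "character", segments = "data.frame",
                   periodH = "numeric", units = "character"))

setValidity("LightRegime", function(object) {
    seg <- object@segments
    msg <- character(0)
    if (!all(c("start", "end", "i0", "i1") %in% names(seg)))
        return("segments must have columns start, end, i0, i1")
    if (nrow(seg) == 0L) return("segments must be non-empty")
    if (seg$start[1L] != 0 || seg$end[nrow(seg)] != 1440)
        msg <- c(msg, "segments must tile [0, 1440)")
    if (nrow(seg) > 1L && any(seg$start[-1L] != seg$end[-nrow(seg)]))
        msg <- c(msg, "segments must be contiguous and non-overlapping")
    if (any(seg$i0 < 0 | seg$i1 < 0))
        msg <- c(msg, "intensities must be >= 0")
    if (object@kind == "RAMP" && any(c(seg$i0, seg$i1) <= 0))
        msg <- c(msg, "RAMP must have no zero-intensity point")
    if (length(msg)) msg else TRUE
})

#' PeriodogramResult: chi-square periodogram over a period grid
#'
#' Result of [chiSquarePeriodogram()]: the Qp statistic evaluated at every
#' period expressible as a whole number of bins inside the search range,
#' the per-period significance line (upper-alpha chi-square quantile with
#' K-1 degrees of freedom, optionally Bonferroni-corrected across the grid),
#' the peak period among significant periods (NA when none), and the
#' rhythmic power (peak Qp minus its significance line, 0 when no peak).
#'
#' @slot periodsH numeric, evaluated periods in hours.
#' @slot qp numeric, Qp statistic per period (>= 0).
#' @slot sigLine numeric, significance threshold per period.
#' @slot alpha nominal significance level before any correction.
#' @slot adjusted logical, whether the grid-wide Bonferroni correction was
#'   applied to the significance line.
#' @slot peakPeriodH peak period in hours, NA_real_ when no significant peak.
#' @slot rhythmicPower peak Qp minus significance line at the peak, else 0.
#' @slot binMinutes bin width of the analysed series.
#' @exportClass PeriodogramResult
setClass("PeriodogramResult",
    representation(periodsH = "numeric", qp = "numeric", sigLine = "numeric",
                   alpha = "numeric", adjusted = "logical",
                   peakPeriodH = "numeric", rhythmicPower = "numeric",
                   binMinutes = "numeric"))

setValidity("PeriodogramResult", function(object) {
    msg <- character(0)
    if (length(object@qp) != length(object@periodsH) ||
        length(object@sigLine) != length(object@periodsH))
        msg <- c(msg, "qp, sigLine and periodsH must have equal length")
    if (any(object@qp < 0)) msg <- c(msg, "qp must be >= 0")
    if (object@rhythmicPower < 0) msg <- c(msg, "rhythmicPower must be >= 0")
    if (!is.na(object@peakPeriodH) &&
        !any(abs(object@periodsH - object@peakPeriodH) < 1e-9))
        msg <- c(msg, "peakPeriodH must be on the period grid")
    if (length(msg)) msg else TRUE
})

#' WaveletSpectrum: Morlet continuous wavelet power over time and period
#'
#' Result of [morletWaveletSpectrum()]: a time x period matrix of wavelet
#' power (normalized by series variance) with the cone-of-influence boundary,
#' i.e. for each time point the longest period whose estimate is free of
#' edge effects.
#'
#' @slot timesH sample times in hours since series start.
#' @slot periodsH analysed periods in hours.
#' @slot power numeric matrix, length(timesH) x length(periodsH), >= 0.
#' @slot coi numeric, per-time maximal edge-safe period in hours.
#' @exportClass WaveletSpectrum
setClass("WaveletSpectrum",
    representation(timesH = "numeric", periodsH = "numeric",
                   power = "matrix", coi = "numeric"))

setValidity("WaveletSpectrum", function(object) {
    msg <- character(0)
    if (nrow(object@power) != length(object@timesH) ||
        ncol(object@power) != length(object@periodsH))
        msg <- c(msg, "power dimensions must match timesH x periodsH")
    if (length(object@coi) != length(object@timesH))
        msg <- c(msg, "coi must have one value per time point")
    if (any(object@power < 0)) msg <- c(msg, "power must be >= 0")
    if (length(msg)) msg else TRUE
})

.VERDICTS <- c("entrained", "relative_coordination", "free_running",
               "arrhythmic")

#' EntrainmentCall: categorical entrainment verdict with evidence
#'
#' Verdict for one fly: \code{entrained}, \code{relative_coordination}
#' (transient/unstable entrainment), \code{free_running} or
#' \code{arrhythmic}, together with the numeric evidence each criterion was
#' judged on (periodogram peak period and power, daily wavelet period band
#' compliance, phase-drift slope, peak multiplicity).
#'
#' @slot verdict character, one of the four categories.
#' @slot evidence named list of supporting numbers and pass/fail flags.
#' @seealso [classifySkeleton()], [classifyRamp()]
#' @exportClass EntrainmentCall
setClass("EntrainmentCall",
    representation(verdict = "character", evidence = "list"))

setValidity("EntrainmentCall", function(object) {
    if (length(object@verdict) != 1L || !object@verdict %in% .VERDICTS)
        paste("verdict must be one of:", paste(.VERDICTS, collapse = ", "))
    else TRUE
})

#' ActivityProfile: mean daily activity waveform across flies
#'
#' Per-bin mean and standard error of the day-averaged activity of a group
#' of flies, spanning exactly one 24 h cycle in ZT.
#'
#' @slot binMinutes minutes per bin.
#' @slot mean per-bin mean count (first per fly across days, then across
#'   flies).
#' @slot sem per-bin standard error of the across-fly mean.
#' @slot n number of flies contributing.
#' @seealso [averageProfile()]
#' @exportClass ActivityProfile
setClass("ActivityProfile",
    representation(binMinutes = "numeric", mean = "numeric", sem = "numeric",
                   n = "integer"))

setValidity("ActivityProfile", function(object) {
    msg <- character(0)
    if (length(object@mean) * object@binMinutes != 1440)
        msg <- c(msg, "profile bins must span exactly 24 h")
    if (length(object@sem) != length(object@mean))
        msg <- c(msg, "mean and sem must have equal length")
    if (any(object@mean < 0) || any(object@sem < 0))
        msg <- c(msg, "mean and sem must be >= 0")
    if (object@n < 1L) msg <- c(msg, "n must be >= 1")
    if (length(msg)) msg else TRUE
})

.FLY_MODES <- c("entrained_locked", "oscillator", "free_running",
                "relative_coordination", "arrhythmic", "masker")

#' FlySpec: ground-truth parameters for one simulated fly
#'
#' Parameter record for the phase-oscillator fly model used by
#' [simulateFly()]. The oscillator advances with angular velocity
#' \code{24/tauH} modulated continuously by light (parametric action, gain
#' \code{epsP}) and jumps at discrete light transitions (non-parametric
#' action, amplitude \code{prcAmpH}). Activity is emitted as an
#' inhomogeneous Poisson process whose rate follows a bimodal circadian
#' waveform, suppressed by light (masking, \code{maskCoeff}) and boosted
#' transiently after discrete transitions (startle).
#'
#' @slot mode behavioural category the simulated fly emulates.
#' @slot tauH intrinsic free-running period in hours.
#' @slot psi0H initial circadian phase in hours.
#' @slot epsP dimensionless parametric light gain.
#' @slot prcAmpH phase-jump amplitude in hours at a full-intensity discrete
#'   transition.
#' @slot waveform list(centers, kappas, weights, baseline): two-bump von
#'   Mises mixture defining the circadian activity waveform (normalized to
#'   mean 1 over the cycle).
#' @slot startleAmp startle transient amplitude, counts/min.
#' @slot startleDecayMin startle exponential decay constant, minutes.
#' @slot maskCoeff masking coefficient kappa >= 0 (rate multiplied by
#'   \code{exp(-kappa * I_norm)}).
#' @slot baseRate baseline emission rate, counts/min.
#' @slot seed RNG seed recorded into every simulated output.
#' @seealso [flySpec()], [simulateFly()]
#' @exportClass FlySpec
setClass("FlySpec",
    representation(mode = "character", tauH = "numeric", psi0H = "numeric",
                   epsP = "numeric", prcAmpH = "numeric", waveform = "list",
                   startleAmp = "numeric", startleDecayMin = "numeric",
                   maskCoeff = "numeric", baseRate = "numeric",
                   seed = "integer"))

setValidity("FlySpec", function(object) {
    msg <- character(0)
    if (!object@mode %in% .FLY_MODES)
        msg <- c(msg, paste("mode must be one of:",
                            paste(.FLY_MODES, collapse = ", ")))
    if (object@tauH <= 0) msg <- c(msg, "tauH must be > 0")
    if (object@baseRate < 0) msg <- c(msg, "baseRate must be >= 0")
    if (object@maskCoeff < 0) msg <- c(msg, "maskCoeff must be >= 0")
    wf <- object@waveform
    if (!all(c("centers", "kappas", "weights", "baseline") %in% names(wf)))
        msg <- c(msg, "waveform needs centers, kappas, weights, baseline")
    else if (any(wf$weights < 0) || wf$baseline < 0)
        msg <- c(msg, "waveform weights and baseline must be >= 0")
    if (length(msg)) msg else TRUE
})
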