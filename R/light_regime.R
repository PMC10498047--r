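## Light schedules as piecewise intensity-vs-ZT functions.

## 1 lux of the broad-spectrum white source corresponds to roughly
## 0.57 uW/cm2 (400-500 lux ~ 228-285 uW/cm2); display-only constant,
## never applied to data.
#' @export
LUX_TO_UW_CM2 <- 0.57

.seg <- function(start, end, i0, i1 = i0)
    data.frame(start = start, end = end, i0 = i0, i1 = i1)

#' Build a light regime
#'
#' Constructs one of the light schedules used for fly entrainment
#' experiments. Skeleton photoperiods place their pulses at fixed ZT
#' positions: \code{SPP} has 30 min pulses starting at dawn (ZT00:00-00:30)
#' and ending at dusk (ZT11:30-12:00); \code{aSPP1} has a 6 h dawn light
#' block (ZT00-06) plus the 30 min pulse ending at dusk; \code{aSPP2} has
#' the 30 min dawn pulse plus a 6 h light block ending at dusk (ZT06-12).
#' \code{RAMP} rises linearly from \code{iMin} at ZT00 to \code{iMax} at
#' ZT12 and falls linearly back, never reaching darkness.
#'
#' @param kind one of \code{"LD"}, \code{"SPP"}, \code{"aSPP1"},
#'   \code{"aSPP2"}, \code{"RAMP"}, \code{"LL"}, \code{"DD"}.
#' @param intensity light intensity for the lit phases of LD/SPP/aSPP/LL.
#' @param iMin,iMax ramp endpoints (RAMP only); \code{iMin} must be > 0.
#' @param units unit label (display only).
#' @return a [LightRegime-class].
#' @examples
#' spp <- buildRegime("SPP", intensity = 450)
#' intensityAt(spp, c(10, 100, 700, 1000))
#' @export
buildRegime <- function(kind, intensity = 450, iMin = 10, iMax = 45,
                        units = NULL) {
    kind <- match.arg(kind, c("LD", "SPP", "aSPP1", "aSPP2", "RAMP", "LL",
                              "DD"))
    if (is.null(units))
        units <- if (kind %in% c("RAMP", "LL")) "uW/cm2" else "lux"
    seg <- switch(kind,
        LD = rbind(.seg(0, 720, intensity), .seg(720, 1440, 0)),
        SPP = rbind(.seg(0, 30, intensity), .seg(30, 690, 0),
                    .seg(690, 720, intensity), .seg(720, 1440, 0)),
        aSPP1 = rbind(.seg(0, 360, intensity), .seg(360, 690, 0),
                      .seg(690, 720, intensity), .seg(720, 1440, 0)),
        aSPP2 = rbind(.seg(0, 30, intensity), .seg(30, 360, 0),
                      .seg(360, 720, intensity), .seg(720, 1440, 0)),
        RAMP = {
            if (iMin <= 0) stop("RAMP requires iMin > 0 (never dark)")
            if (iMax <= iMin) stop("RAMP requires iMax > iMin")
            rbind(.seg(0, 720, iMin, iMax), .seg(720, 1440, iMax, iMin))
        },
        LL = .seg(0, 1440, intensity),
        DD = .seg(0, 1440, 0))
    new("LightRegime", kind = kind, segments = seg, periodH = 24,
        units = units)
}

#' Light intensity at given ZT minutes
#'
#' Piecewise evaluation of the regime; linear within ramp segments,
#' vectorized, with input wrapped modulo the 24 h cycle.
#'
#' @param regime a [LightRegime-class].
#' @param ztMin ZT minutes (any real values; wrapped mod 1440).
#' @return numeric intensities.
#' @export
intensityAt <- function(regime, ztMin) {
    stopifnot(is(regime, "LightRegime"))
    zt <- ztMin %% 1440
    seg <- regime@segments
    idx <- findInterval(zt, seg$start, rightmost.closed = FALSE)
    frac <- (zt - seg$start[idx]) / (seg$end[idx] - seg$start[idx])
    seg$i0[idx] + frac * (seg$i1[idx] - seg$i0[idx])
}

#' Discrete light transitions of a regime
#'
#' Lists every intensity discontinuity once per cycle with its signed jump.
#' Ramped and constant regimes have none.
#'
#' @param regime a [LightRegime-class].
#' @return data.frame with columns \code{zt_min} and \code{dI} (possibly
#'   0-row).
#' @examples
#' nrow(transitions(buildRegime("SPP")))  # 4
#' @export
transitions <- function(regime) {
    stopifnot(is(regime, "LightRegime"))
    seg <- regime@segments
    bounds <- seg$start  # cycle boundaries incl. wrap at ZT0
    before <- c(seg$i1[nrow(seg)], seg$i1[-nrow(seg)])
    after <- seg$i0
    jump <- after - before
    keep <- abs(jump) > 1e-12
    data.frame(zt_min = bounds[keep], dI = jump[keep])
}

#' Intensity trace of a regime at 1-min resolution
#'
#' @param regime a [LightRegime-class].
#' @return data.frame with columns \code{zt_min} (0..1439) and
#'   \code{intensity}.
#' @export
regimeTrace <- function(regime) {
    zt <- 0:1439
    data.frame(zt_min = zt, intensity = intensityAt(regime, zt))
}
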