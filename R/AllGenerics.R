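#' Accessors for entrainR classes
#'
#' Small accessor generics: \code{activityCounts} returns the count matrix,
#' \code{binMinutes} the bin width in minutes, \code{zt0Offset} the minutes
#' from recording start to the first ZT00, \code{nBins}/\code{nChannels} the
#' matrix dimensions, \code{nDays} the number of complete 24 h cycles after
#' ZT alignment, \code{flaggedRows} the indices flagged on read, and
#' \code{verdict}/\code{evidence} the components of an
#' [EntrainmentCall-class].
#'
#' @param object an entrainR S4 object.
#' @return the accessed component.
#' @name accessors
#' @examples
#' at <- ActivityTable(matrix(0:9, ncol = 1))
#' nBins(at)
NULL

#' @rdname accessors
#' @export
setGeneric("activityCounts", function(object) standardGeneric("activityCounts"))
#' @rdname accessors
#' @export
setGeneric("binMinutes", function(object) standardGeneric("binMinutes"))
#' @rdname accessors
#' @export
setGeneric("zt0Offset", function(object) standardGeneric("zt0Offset"))
#' @rdname accessors
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nDays", function(object) standardGeneric("nDays"))
#' @rdname accessors
#' @export
setGeneric("flaggedRows", function(object) standardGeneric("flaggedRows"))
#' @rdname accessors
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))
#' @rdname accessors
#' @export
setGeneric("evidence", function(object) standardGeneric("evidence"))
#' @rdname accessors
#' @export
setGeneric("peakPeriod", function(object) standardGeneric("peakPeriod"))
#' @rdname accessors
#' @export
setGeneric("rhythmicPower", function(object) standardGeneric("rhythmicPower"))

#' @rdname accessors
#' @export
setMethod("activityCounts", "ActivityTable", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("binMinutes", "ActivityTable", function(object) object@binMinutes)
#' @rdname accessors
#' @export
setMethod("binMinutes", "ActivityProfile", function(object) object@binMinutes)
#' @rdname accessors
#' @export
setMethod("zt0Offset", "ActivityTable", function(object) object@zt0Offset)
#' @rdname accessors
#' @export
setMethod("nBins", "ActivityTable", function(object) nrow(object@counts))
#' @rdname accessors
#' @export
setMethod("nChannels", "ActivityTable", function(object) ncol(object@counts))
#' @rdname accessors
#' @export
setMethod("nDays", "ActivityTable", function(object) {
    lead <- leadBins(object)
    max(0L, (nrow(object@counts) - lead) %/% (1440L / object@binMinutes))
})
#' @rdname accessors
#' @export
setMethod("flaggedRows", "ActivityTable", function(object) object@flagged)
#' @rdname accessors
#' @export
setMethod("verdict", "EntrainmentCall", function(object) object@verdict)
#' @rdname accessors
#' @export
setMethod("evidence", "EntrainmentCall", function(object) object@evidence)
#' @rdname accessors
#' @export
setMethod("peakPeriod", "PeriodogramResult", function(object)
    object@peakPeriodH)

setMethod("show", "ActivityTable", function(object) {
    cat(sprintf(
        "ActivityTable: %d bins x %d channel(s), %g min/bin (%.2f days)\n",
        nrow(object@counts), ncol(object@counts), object@binMinutes,
        nrow(object@counts) * object@binMinutes / 1440))
    cat(sprintf("  ZT00 offset: %g min; flagged rows: %d\n",
                object@zt0Offset, length(object@flagged)))
})

setMethod("show", "LightRegime", function(object) {
    cat(sprintf("LightRegime %s (%s), %d segment(s), %g h cycle\n",
                object@kind, object@units, nrow(object@segments),
                object@periodH))
})

setMethod("show", "PeriodogramResult", function(object) {
    cat(sprintf("Chi-square periodogram: %d periods in [%.2f, %.2f] h\n",
                length(object@periodsH), min(object@periodsH),
                max(object@periodsH)))
    if (is.na(object@peakPeriodH))
        cat("  no significant peak\n")
    else
        cat(sprintf("  peak: %.2f h, rhythmic power %.1f\n",
                    object@peakPeriodH, object@rhythmicPower))
})

setMethod("show", "WaveletSpectrum", function(object) {
    cat(sprintf("Morlet wavelet spectrum: %d times x %d periods [%.1f, %.1f] h\n",
                length(object@timesH), length(object@periodsH),
                min(object@periodsH), max(object@periodsH)))
})

setMethod("show", "EntrainmentCall", function(object) {
    cat(sprintf("EntrainmentCall: %s\n", object@verdict))
    ev <- object@evidence
    num <- ev[vapply(ev, function(x) is.numeric(x) && length(x) == 1L,
                     logical(1))]
    if (length(num))
        cat(paste0("  ", names(num), " = ",
                   vapply(num, function(x) format(x, digits = 4),
                          character(1)), collapse = "\n"), "\n")
})

setMethod("show", "ActivityProfile", function(object) {
    cat(sprintf("ActivityProfile: %d bins of %g min, n = %d flies\n",
                length(object@mean), object@binMinutes, object@n))
})

setMethod("show", "FlySpec", function(object) {
    cat(sprintf("FlySpec[%s]: tau = %g h, eps_p = %g, prc = %g h, seed = %d\n",
                object@mode, object@tauH, object@epsP, object@prcAmpH,
                object@seed))
})
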