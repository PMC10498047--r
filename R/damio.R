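## DAM monitor I/O, binning and day-splitting.
##
## Dialect: classic 42-column Trikinetics text. Tab-delimited, one row per
## minute: reading index, date (dd Mon yy), time (HH:MM:SS), monitor status
## (1 = OK), six auxiliary fields, then 32 channel counts.

.DAM_OK_STATUS <- 1L
.DAM_NCOL <- 42L

## bins before the first ZT00 (complete-day alignment support);
## zt0Offset is itself the lead in minutes
leadBins <- function(table) {
    as.integer(ceiling((table@zt0Offset %% 1440) / table@binMinutes))
}

#' Read a Trikinetics-style DAM monitor file
#'
#' Parses the classic 42-column tab-delimited monitor dialect at 1-min
#' cadence. Rows whose status field is not the OK code (1) are flagged: their
#' counts are set to zero with a warning and their indices recorded on the
#' returned object, never silently dropped.
#'
#' @param path path to the monitor text file.
#' @param channels optional integer subset of the 32 channels to keep.
#' @param zt0Offset minutes from recording start to the first ZT00 (supplied
#'   as metadata from the experiment's light schedule, not inferred from the
#'   data).
#' @return an [ActivityTable-class] with \code{binMinutes = 1}.
#' @examples
#' tf <- tempfile()
#' writeMonitorFile(ActivityTable(matrix(0:9, ncol = 1)), tf)
#' at <- readMonitorFile(tf, channels = 1)
#' activityCounts(at)[, 1]
#' @export
readMonitorFile <- function(path, channels = NULL, zt0Offset = 0) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("parse error: empty monitor file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf != .DAM_NCOL)
    if (length(bad))
        stop(sprintf("parse error at line %d: expected %d fields, got %d",
                     bad[1L], .DAM_NCOL, nf[bad[1L]]))
    m <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
    timestamps <- strptime(paste(m[, 2L], m[, 3L]), "%d %b %y %H:%M:%S",
                           tz = "UTC")
    if (anyNA(timestamps))
        stop(sprintf("parse error at line %d: unparseable date/time",
                     which(is.na(timestamps))[1L]))
    tmin <- as.numeric(timestamps) / 60
    if (length(tmin) > 1L && any(diff(tmin) <= 0))
        stop("integrity error: non-monotone timestamps at line ",
             which(diff(tmin) <= 0)[1L] + 1L)
    status <- suppressWarnings(as.integer(m[, 4L]))
    cts <- suppressWarnings(matrix(as.numeric(m[, 11L:42L]),
                                   nrow = nrow(m)))
    if (anyNA(cts))
        stop(sprintf("parse error at line %d: non-numeric count",
                     which(rowSums(is.na(cts)) > 0)[1L]))
    colnames(cts) <- paste0("ch", seq_len(32L))
    if (!is.null(channels)) cts <- cts[, channels, drop = FALSE]
    flagged <- which(is.na(status) | status != .DAM_OK_STATUS)
    if (length(flagged)) {
        warning(length(flagged),
                " row(s) with non-OK monitor status flagged; counts zeroed")
        cts[flagged, ] <- 0
    }
    ActivityTable(cts, binMinutes = 1, zt0Offset = zt0Offset,
                  flagged = flagged)
}

#' Write an ActivityTable as a Trikinetics-style monitor file
#'
#' Inverse of [readMonitorFile()] for 1-min tables; channels beyond the
#' table's are padded with zero counts up to the 32-channel monitor layout.
#'
#' @param table an [ActivityTable-class] at \code{binMinutes = 1}.
#' @param path output path.
#' @param startDate POSIXct timestamp of the first reading.
#' @return \code{path}, invisibly.
#' @export
writeMonitorFile <- function(table, path,
                             startDate = as.POSIXct("2023-01-02 00:00:00",
                                                    tz = "UTC")) {
    stopifnot(is(table, "ActivityTable"))
    if (table@binMinutes != 1)
        stop("monitor files are written at native 1-min cadence")
    cts <- table@counts
    n <- nrow(cts)
    if (ncol(cts) > 32L) stop("at most 32 channels per monitor file")
    full <- matrix(0L, n, 32L)
    full[, seq_len(ncol(cts))] <- as.integer(round(cts))
    tt <- startDate + 60 * (seq_len(n) - 1L)
    lt <- as.POSIXlt(tt)
    status <- rep(.DAM_OK_STATUS, n)
    status[table@flagged] <- 51L  # conventional non-OK code
    meta <- cbind(seq_len(n),
                  format(tt, "%d %b %y"),
                  format(tt, "%H:%M:%S"),
                  status,
                  matrix(0L, n, 6L))
    out <- cbind(meta, full)
    writeLines(apply(out, 1L, paste, collapse = "\t"), path)
    invisible(path)
}

#' Re-bin an activity table by summing counts
#'
#' @param table an [ActivityTable-class].
#' @param binMinutes target bin width; must be a multiple of the table's
#'   current bin width and divide 1440. Counts are summed within bins, so the
#'   grand total is conserved exactly. A trailing partial bin is dropped.
#' @return an [ActivityTable-class] at the new cadence.
#' @examples
#' at <- ActivityTable(matrix(rep(1, 1440), ncol = 1))
#' sum(activityCounts(binActivity(at, 15))) == 1440
#' @export
binActivity <- function(table, binMinutes) {
    stopifnot(is(table, "ActivityTable"))
    if (binMinutes %% table@binMinutes != 0)
        stop("binMinutes must be a multiple of the table's bin width (",
             table@binMinutes, " min)")
    if (1440 %% binMinutes != 0)
        stop("binMinutes must divide 1440")
    k <- as.integer(binMinutes / table@binMinutes)
    if (k == 1L) return(table)
    n <- nrow(table@counts)
    nOut <- n %/% k
    if (nOut == 0L) stop("series shorter than one output bin")
    idx <- seq_len(nOut * k)
    grp <- rep(seq_len(nOut), each = k)
    cts <- rowsum(table@counts[idx, , drop = FALSE], grp, reorder = TRUE)
    rownames(cts) <- NULL
    ActivityTable(cts, binMinutes = binMinutes, zt0Offset = table@zt0Offset)
}

#' Split an aligned activity channel into a day-by-bin matrix
#'
#' Rows are complete 24 h cycles beginning at ZT00 (partial leading and
#' trailing days are excluded); columns are within-day bins.
#'
#' @param table an [ActivityTable-class].
#' @param channel channel index or name (default first).
#' @return numeric matrix, days x (1440 / binMinutes); 0-row matrix with a
#'   warning when less than one complete day is available.
#' @export
splitDays <- function(table, channel = 1L) {
    stopifnot(is(table, "ActivityTable"))
    x <- table@counts[, channel]
    perDay <- as.integer(1440 / table@binMinutes)
    lead <- leadBins(table)
    nd <- max(0L, (length(x) - lead) %/% perDay)
    if (nd == 0L) {
        warning("fewer than one complete ZT-aligned day; empty matrix")
        return(matrix(numeric(0), 0L, perDay))
    }
    matrix(x[lead + seq_len(nd * perDay)], nrow = nd, ncol = perDay,
           byrow = TRUE)
}

#' Export a (binned) activity table as tidy CSV
#'
#' Columns: \code{zt_min} (ZT minutes of bin start, wrapped to the 24 h
#' cycle), \code{channel}, \code{count}.
#'
#' @param table an [ActivityTable-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
exportActivityCSV <- function(table, path) {
    stopifnot(is(table, "ActivityTable"))
    cts <- table@counts
    n <- nrow(cts)
    zt <- ((seq_len(n) - 1L) * table@binMinutes - table@zt0Offset) %% 1440
    df <- data.frame(
        zt_min = rep(zt, times = ncol(cts)),
        channel = rep(colnames(cts), each = n),
        count = as.vector(cts))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
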