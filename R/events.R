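#' Zero-phase band-pass filter for multichannel signals
#'
#' Demeans each channel and applies a Butterworth band-pass realized as a
#' cascade of a 2nd-order high-pass and a 2nd-order low-pass, each run
#' forward-backward (`signal::filtfilt`). Zero-phase filtering keeps event
#' timestamps unshifted; the cascade keeps the design numerically stable
#' with the upper edge close to Nyquist. The default band 0.1-200 Hz
#' mirrors common hardware filters of LFP recordings; after filtering the
#' channel mean is virtually zero.
#'
#' @param x numeric matrix (channels x time) or vector.
#' @param fs sampling rate, Hz.
#' @param low,high band edges, Hz; must satisfy 0 < low < high < fs/2.
#' @return filtered signal, same shape as `x`.
#' @export
bandpassFilter <- function(x, fs, low = 0.1, high = 200) {
    stopifnot(fs > 0)
    if (!(low > 0 && low < high && high < fs / 2))
        stop("band edges must satisfy 0 < low < high < fs/2")
    hp <- signal::butter(2, low / (fs / 2), type = "high")
    lp <- signal::butter(2, high / (fs / 2), type = "low")
    filt1 <- function(v) {
        v <- v - mean(v)
        signal::filtfilt(lp, signal::filtfilt(hp, v))
    }
    if (is.matrix(x)) t(apply(x, 1L, filt1)) else filt1(x)
}

# Event indices of one filtered, demeaned channel: one candidate per
# positive excursion (maximal run with x > 0, strictly), placed at the
# excursion's largest maximum; kept if that maximum exceeds the threshold.
# Excursions truncated at the record edge are dropped when their maximum
# sits on the edge sample (ambiguous maximum).
excursionEventIdx <- function(x, threshold) {
    pos <- x > 0
    if (!any(pos)) return(integer(0))
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    out <- integer(0)
    for (k in which(keep)) {
        seg <- x[starts[k]:ends[k]]
        imax <- which.max(seg)
        idx <- starts[k] + imax - 1L
        if ((starts[k] == 1L && imax == 1L) ||
            (ends[k] == length(x) && idx == length(x)))
            next  # edge-truncated with edge maximum
        if (seg[imax] > threshold) out <- c(out, idx)
    }
    out
}

#' Extract discrete events from a coarse-sampled record
#'
#' The stage that converts continuous electrode signals into the same
#' event-timestamp representation as spike sub-sampling: each channel is
#' band-pass filtered (see [bandpassFilter()]), its threshold is set to
#' `thresholdSD` standard deviations above the (virtually zero) mean of the
#' full filtered series, and every positive excursion whose largest
#' maximum exceeds the threshold contributes exactly one event at the
#' timestamp of that maximum. Crossings of the mean delimit excursions, so
#' an excursion never yields more than one event regardless of how many
#' local maxima or threshold passages it contains.
#'
#' @param record a \linkS4class{CoarseRecord}, or a numeric matrix
#'   (channels x time) with `dt` supplied.
#' @param thresholdSD threshold multiplier in units of per-channel SD
#'   (default 3).
#' @param band band edges in Hz (default `c(0.1, 200)`); `NULL` skips
#'   filtering (input must already be demeaned).
#' @param dt sampling interval in ms (taken from the record if omitted).
#' @return an \linkS4class{EventSeries}.
#' @export
extractEvents <- function(record, thresholdSD = 3, band = c(0.1, 200),
                          dt = NULL) {
    if (is(record, "CoarseRecord")) {
        if (is.null(dt)) dt <- record@dt
        x <- record@signal
    } else {
        x <- record
        stopifnot(is.matrix(x), !is.null(dt))
    }
    stopifnot(thresholdSD > 0, dt > 0)
    fs <- 1000 / dt
    if (!is.null(band)) x <- bandpassFilter(x, fs, band[1], band[2])
    else x <- x - rowMeans(x)
    chan <- integer(0)
    tms <- numeric(0)
    for (ch in seq_len(nrow(x))) {
        v <- x[ch, ]
        s <- sd(v)
        if (s == 0) next
        idx <- excursionEventIdx(v - mean(v), thresholdSD * s)
        chan <- c(chan, rep.int(ch, length(idx)))
        tms <- c(tms, (idx - 1) * dt)
    }
    new("EventSeries", channel = chan, time = tms,
        nChannels = nrow(x), duration = ncol(x) * dt,
        meta = list(thresholdSD = thresholdSD, band = band,
                    sampling = "coarse"))
}
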