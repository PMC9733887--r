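# Synthetic fixtures with known ground truth, used by the test-suite
# oracles and exported so analysis behaviour can be validated on data
# whose parameters are known exactly.

#' Synthetic AR(1) population-activity trace with known timescale
#'
#' Generates `A(t+1) = exp(-dt/tau) A(t) + Poisson(drive)`, the same
#' autoregressive structure the timescale estimator assumes, so the
#' generator is its own oracle: [estimateTimescale()] applied to the
#' output should recover `tau`. Values are left continuous; rounding to
#' counts would add measurement noise and attenuate the fitted slope.
#'
#' @param nSteps series length.
#' @param tau intrinsic timescale, ms (`tau = 0` gives white Poisson
#'   noise).
#' @param dt sampling step, ms.
#' @param drive mean of the Poisson innovations per step (plays the role
#'   of the population drive N*h).
#' @param seed RNG seed (R stream, restored).
#' @return integer activity series of length `nSteps`.
#' @export
synthAR1Activity <- function(nSteps, tau, dt = 2, drive = 2,
                             seed = NULL) {
    stopifnot(nSteps > 1, tau >= 0, dt > 0, drive >= 0)
    b <- if (tau > 0) exp(-dt / tau) else 0
    withLocalSeed(seed, function() {
        A <- numeric(nSteps)
        innov <- rpois(nSteps, drive)
        A[1] <- if (b < 1) drive / (1 - b) else drive
        for (t in seq_len(nSteps - 1L))
            A[t + 1L] <- b * A[t] + innov[t]
        A
    })
}

#' Hand-checkable per-bin event-count sequence
#'
#' Builds a \linkS4class{BinnedActivity} directly from a count vector so
#' avalanche decomposition and the branching estimator can be exercised on
#' fixtures whose answer is computed by hand.
#'
#' @param counts nonnegative integer vector of per-bin event counts.
#' @param binSize bin size, ms.
#' @return a \linkS4class{BinnedActivity}.
#' @export
binnedFromCounts <- function(counts, binSize = 1) {
    new("BinnedActivity", counts = as.integer(counts), binSize = binSize)
}

#' Event series from explicit channel/time pairs
#'
#' Convenience constructor for tests and for feeding externally recorded
#' spike timestamps (e.g. spike-sorted data) into the avalanche pipeline.
#'
#' @param channel integer channel ids.
#' @param time timestamps, ms.
#' @param nChannels number of channels (default `max(channel)`).
#' @param duration recording length, ms (default just past the last
#'   event).
#' @return an \linkS4class{EventSeries}.
#' @export
eventSeries <- function(channel, time, nChannels = NULL,
                        duration = NULL) {
    stopifnot(length(channel) == length(time))
    o <- order(channel, time)
    channel <- as.integer(channel[o])
    time <- as.numeric(time[o])
    if (is.null(nChannels))
        nChannels <- if (length(channel)) max(channel) else 0L
    if (is.null(duration))
        duration <- if (length(time)) max(time) + 1 else 1
    new("EventSeries", channel = channel, time = time,
        nChannels = as.integer(nChannels), duration = duration,
        meta = list(sampling = "external"))
}
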