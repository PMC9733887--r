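#' Analytic intrinsic timescale of a branching process
#'
#' `tau = -dt / ln(m)` for `0 < m < 1`; the uncorrelated limit `m = 0`
#' has `tau = 0`.
#'
#' @param m branching parameter in \[0, 1).
#' @param dt simulation step, ms.
#' @return intrinsic timescale in ms.
#' @export
analyticTimescale <- function(m, dt = 2) {
    stopifnot(dt > 0)
    if (any(m < 0) || any(m >= 1))
        stop("m must lie in [0, 1): tau diverges at m = 1")
    ifelse(m == 0, 0, -dt / log(m))
}

#' Spontaneous drive needed for a target stationary rate
#'
#' Inverts the stationary-rate relation `r = h / (dt * (1 - m))` (with dt
#' converted to seconds): `h = r * dt * (1 - m)`.
#'
#' @param rate target per-neuron rate, Hz.
#' @param m branching parameter in \[0, 1).
#' @param dt simulation step, ms.
#' @return per-neuron per-step spontaneous spike probability.
#' @export
driveForRate <- function(rate, m, dt = 2) {
    stopifnot(rate >= 0, dt > 0)
    if (any(m < 0) || any(m >= 1)) stop("m must lie in [0, 1)")
    h <- rate * (dt / 1000) * (1 - m)
    if (any(h > 1)) stop("requested rate implies h > 1")
    h
}

#' Named dynamic states
#'
#' The four canonical states (branching parameter, with drive set for a
#' stationary rate of 1 Hz at dt = 2 ms): poisson (m = 0), subcritical
#' (m = 0.9), reverberating (m = 0.98, typical of in vivo cortex) and
#' critical (m = 0.999). Pass `m` explicitly for a custom state.
#'
#' @param name one of "poisson", "subcritical", "reverberating",
#'   "critical"; ignored when `m` is given.
#' @param m custom branching parameter.
#' @param rate target stationary rate, Hz.
#' @param dt simulation step, ms.
#' @return a \linkS4class{DynamicState}.
#' @export
dynamicState <- function(name = c("poisson", "subcritical", "reverberating",
                                  "critical"),
                         m = NULL, rate = 1, dt = 2) {
    if (is.null(m)) {
        name <- match.arg(name)
        m <- c(poisson = 0, subcritical = 0.9, reverberating = 0.98,
               critical = 0.999)[[name]]
    } else {
        name <- "custom"
    }
    new("DynamicState", m = m, h = driveForRate(rate, m, dt), dt = dt,
        rate = rate, name = name)
}

#' Default burn-in for a dynamic state
#'
#' `max(1000, ceiling(10 * tau / dt))` steps, discarded before analysis so
#' the record starts from (approximate) stationarity.
#'
#' @param state a \linkS4class{DynamicState}.
#' @return burn-in length in steps.
#' @export
defaultBurnIn <- function(state) {
    tau <- analyticTimescale(state@m, state@dt)
    max(1000L, as.integer(ceiling(10 * tau / state@dt)))
}

#' Simulate the driven branching process on a network
#'
#' At every step each active neuron attempts to activate each of its
#' targets with probability `m * w_ij`; when a successful activation hits a
#' target already marked for the next step, coalescence compensation
#' redirects it to the next quiescent neuron in the source's
#' distance-sorted target list (wrapping to the head; dropped if no
#' quiescent target remains). Independently, every neuron spikes
#' spontaneously with probability `h`. Activations are iterated in neuron
#' index order and targets in distance order, so rasters are bit-identical
#' under a fixed seed.
#'
#' @param topology a \linkS4class{NetworkTopology}.
#' @param state a \linkS4class{DynamicState}.
#' @param nSteps number of simulated steps.
#' @param seed dynamics RNG seed (internal generator, independent of R's).
#' @param compensate apply coalescence compensation (default TRUE).
#' @param method "skip" (geometric-skip thinning, default) or "naive"
#'   (per-target Bernoulli loop); identical in law.
#' @param initActive integer vector of initially active neurons (default
#'   all-quiescent start).
#' @return a \linkS4class{SpikeRaster}; sustained saturation is flagged via
#'   its `saturatedSteps` slot, not an error.
#' @export
simulateBranching <- function(topology, state, nSteps, seed = 1,
                              compensate = TRUE,
                              method = c("skip", "naive"),
                              initActive = integer(0)) {
    stopifnot(is(topology, "NetworkTopology"), is(state, "DynamicState"),
              nSteps >= 1)
    method <- match.arg(method)
    n <- nrow(topology@geometry@positions)
    res <- simulateBranchingCpp(topology@ptr, topology@targets,
                                topology@weights, n, state@m, state@h,
                                as.integer(nSteps), as.numeric(seed),
                                compensate, method,
                                as.integer(initActive))
    new("SpikeRaster", step = res$step, neuron = res$neuron,
        activity = res$activity, nSteps = as.integer(nSteps),
        nNeurons = as.integer(n), dt = state@dt, seed = as.numeric(seed),
        saturatedSteps = res$saturatedSteps,
        droppedActivations = res$droppedActivations, state = state)
}

#' Discard an initial burn-in window from a raster
#'
#' Drops the first `nBurn` steps and renumbers the remainder from step 1,
#' so downstream timestamps again start at 0.
#'
#' @param raster a \linkS4class{SpikeRaster}.
#' @param nBurn steps to discard (e.g. [defaultBurnIn()]).
#' @return the trimmed \linkS4class{SpikeRaster}.
#' @export
discardBurnIn <- function(raster, nBurn) {
    stopifnot(is(raster, "SpikeRaster"), nBurn >= 0,
              nBurn < raster@nSteps)
    if (nBurn == 0) return(raster)
    keep <- raster@step > nBurn
    new("SpikeRaster", step = raster@step[keep] - as.integer(nBurn),
        neuron = raster@neuron[keep],
        activity = raster@activity[-seq_len(nBurn)],
        nSteps = raster@nSteps - as.integer(nBurn),
        nNeurons = raster@nNeurons, dt = raster@dt, seed = raster@seed,
        saturatedSteps = raster@saturatedSteps,
        droppedActivations = raster@droppedActivations,
        state = raster@state)
}

#' Mean per-neuron rate of a raster
#'
#' @param raster a \linkS4class{SpikeRaster}.
#' @return rate in Hz.
#' @export
meanRate <- function(raster) {
    stopifnot(is(raster, "SpikeRaster"))
    mean(raster@activity) / raster@nNeurons / (raster@dt / 1000)
}

#' Estimate the intrinsic timescale from population activity
#'
#' Linear least-squares fit of the autoregressive relation
#' `A(t+1) = b A(t) + c`; the slope maps to the timescale via
#' `tau_hat = -dt / ln(b)`. A non-positive slope yields `tau_hat = 0` with
#' a warning (no resolvable timescale at this sampling step).
#'
#' @param A population-activity series (counts per step), or a
#'   \linkS4class{SpikeRaster}.
#' @param dt sampling step in ms (taken from the raster if omitted).
#' @return estimated timescale in ms, with the fitted slope and intercept
#'   attached as attributes "slope" and "intercept".
#' @export
estimateTimescale <- function(A, dt = NULL) {
    if (is(A, "SpikeRaster")) {
        if (is.null(dt)) dt <- A@dt
        A <- A@activity
    }
    stopifnot(!is.null(dt), dt > 0, length(A) > 2)
    if (sd(A) == 0) stop("constant activity series: timescale undefined")
    x <- A[-length(A)]
    y <- A[-1L]
    b <- cov(x, y) / var(x)
    c0 <- mean(y) - b * mean(x)
    if (b <= 0) {
        warning("non-positive AR(1) slope; returning tau = 0")
        tau <- 0
    } else {
        tau <- -dt / log(b)
    }
    structure(tau, slope = b, intercept = c0)
}
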