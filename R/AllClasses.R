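#' Virtual electrode array
#'
#' A square grid of point-like virtual electrodes centered in the periodic
#' simulation plane. Each electrode carries a dead zone (an exclusion radius
#' inside which no neuron may be placed, which bounds the 1/d^gamma signal
#' contribution) and the decay exponent gamma describing its field of view
#' (gamma = 1 wide, gamma = 2 narrow).
#'
#' @slot positions numeric matrix (nElectrodes x 2), micrometres.
#' @slot dE inter-electrode distance, micrometres.
#' @slot gridDim integer c(rows, cols).
#' @slot deadZone exclusion radius around each electrode, micrometres.
#' @slot gamma decay exponent of the coarse signal contribution.
#' @exportClass ElectrodeArray
setClass("ElectrodeArray",
    representation(positions = "matrix", dE = "numeric",
                   gridDim = "integer", deadZone = "numeric",
                   gamma = "numeric"))

setValidity("ElectrodeArray", function(object) {
    if (ncol(object@positions) != 2L)
        return("positions must have two columns")
    if (nrow(object@positions) != prod(object@gridDim))
        return("number of positions must equal prod(gridDim)")
    if (object@deadZone < 0 || object@gamma <= 0)
        return("deadZone must be >= 0 and gamma > 0")
    TRUE
})

#' Neuron placement on the periodic plane
#'
#' Uniformly random neuron positions on the periodic square \[0, L)^2,
#' excluding electrode dead zones. The linear size L follows the ideal-gas
#' relation L = 2*sqrt(nNeurons)*dN, so that the mean nearest-neighbour
#' spacing equals dN and the density is 1/(4*dN^2).
#'
#' @slot positions numeric matrix (nNeurons x 2), micrometres.
#' @slot L linear system size, micrometres.
#' @slot dN mean nearest-neighbour distance, micrometres.
#' @slot seed placement RNG seed.
#' @slot electrodes the \linkS4class{ElectrodeArray} whose dead zones were
#'   respected, or NULL.
#' @exportClass NeuronGeometry
setClass("NeuronGeometry",
    representation(positions = "matrix", L = "numeric", dN = "numeric",
                   seed = "numeric", electrodes = "ANY"))

setValidity("NeuronGeometry", function(object) {
    p <- object@positions
    if (ncol(p) != 2L) return("positions must have two columns")
    if (any(p < 0) || any(p >= object@L))
        return("positions must lie in [0, L)")
    TRUE
})

#' Distance-thresholded network topology
#'
#' Directed connectivity in which every neuron connects to all neighbours
#' within dMax (periodic minimum-image distance). Per-source target lists
#' are stored in compressed form (ptr/targets/weights), sorted ascending by
#' distance with ties broken by neuron index; weights are Gaussian in
#' distance, exp(-d^2/(2 sigma^2)), normalized to sum to one per source.
#'
#' @slot geometry the \linkS4class{NeuronGeometry}.
#' @slot ptr integer offsets, length nNeurons + 1 (0-based, CSR style).
#' @slot targets integer neuron indices (1-based), concatenated lists.
#' @slot weights numeric weights aligned with targets.
#' @slot dMax connection cutoff radius, micrometres.
#' @slot sigma effective connection length, micrometres.
#' @slot k requested mean out-degree.
#' @exportClass NetworkTopology
setClass("NetworkTopology",
    representation(geometry = "NeuronGeometry", ptr = "integer",
                   targets = "integer", weights = "numeric",
                   dMax = "numeric", sigma = "numeric", k = "numeric"))

setValidity("NetworkTopology", function(object) {
    n <- nrow(object@geometry@positions)
    if (length(object@ptr) != n + 1L) return("ptr must have length N + 1")
    if (length(object@targets) != length(object@weights))
        return("targets and weights must be aligned")
    if (utils::tail(object@ptr, 1L) != length(object@targets))
        return("ptr must index into targets")
    TRUE
})

#' Dynamic state of the branching process
#'
#' The pair (m, h) controls the distance to criticality and the stationary
#' per-neuron rate r = h / (dt * (1 - m)) (dt in seconds when r is in Hz).
#' The analytic intrinsic timescale is tau = -dt / ln(m).
#'
#' @slot m branching parameter in \[0, 1).
#' @slot h per-neuron per-step spontaneous spike probability.
#' @slot dt simulation step, milliseconds.
#' @slot rate target stationary per-neuron rate, Hz.
#' @slot name one of "poisson", "subcritical", "reverberating", "critical",
#'   or "custom".
#' @exportClass DynamicState
setClass("DynamicState",
    representation(m = "numeric", h = "numeric", dt = "numeric",
                   rate = "numeric", name = "character"))

setValidity("DynamicState", function(object) {
    if (object@m < 0 || object@m >= 1)
        return("m must lie in [0, 1)")
    if (object@h < 0 || object@h > 1)
        return("h must be a probability")
    if (object@dt <= 0) return("dt must be positive")
    TRUE
})

#' Sparse spike raster of a simulation
#'
#' Activations stored as (step, neuron) pairs; steps run 1..nSteps and the
#' timestamp of step t is (t - 1) * dt so times span \[0, nSteps * dt).
#' activity holds A(t), the number of active neurons per step.
#'
#' @slot step integer activation steps (1-based).
#' @slot neuron integer neuron ids aligned with step.
#' @slot activity integer vector of length nSteps.
#' @slot nSteps,nNeurons record dimensions.
#' @slot dt simulation step, ms.
#' @slot seed dynamics RNG seed.
#' @slot saturatedSteps number of steps with all neurons active (flagged,
#'   not fatal).
#' @slot droppedActivations activations lost because coalescence
#'   compensation found no quiescent target.
#' @slot state the \linkS4class{DynamicState} that generated the record.
#' @exportClass SpikeRaster
setClass("SpikeRaster",
    representation(step = "integer", neuron = "integer",
                   activity = "integer", nSteps = "integer",
                   nNeurons = "integer", dt = "numeric", seed = "numeric",
                   saturatedSteps = "integer",
                   droppedActivations = "integer", state = "DynamicState"))

setValidity("SpikeRaster", function(object) {
    if (length(object@step) != length(object@neuron))
        return("step and neuron must be aligned")
    if (length(object@activity) != object@nSteps)
        return("activity must have one entry per step")
    if (length(object@step) &&
        (min(object@step) < 1L || max(object@step) > object@nSteps))
        return("steps out of range")
    if (any(object@activity < 0L) ||
        any(object@activity > object@nNeurons))
        return("activity must lie in [0, nNeurons]")
    TRUE
})

#' Coarse-sampled (LFP-like) multichannel record
#'
#' Per-electrode continuous signal V_k(t) = sum_i s_i(t) / d_ik^gamma over
#' all neurons, using periodic minimum-image neuron-to-electrode distances.
#'
#' @slot signal numeric matrix, channels x time steps; all entries >= 0.
#' @slot dt sampling interval (simulation step), ms.
#' @slot gamma decay exponent used.
#' @slot array the \linkS4class{ElectrodeArray}.
#' @exportClass CoarseRecord
setClass("CoarseRecord",
    representation(signal = "matrix", dt = "numeric", gamma = "numeric",
                   array = "ElectrodeArray"))

setValidity("CoarseRecord", function(object) {
    if (min(object@signal) < 0) return("coarse signal must be nonnegative")
    if (nrow(object@signal) != nrow(object@array@positions))
        return("one signal row per electrode required")
    TRUE
})

#' Discrete per-channel event timestamps
#'
#' The common currency of both sampling paths: sub-sampled spikes are events
#' directly, coarse signals become events after filtering and thresholding.
#' Timestamps are in milliseconds, strictly increasing within a channel and
#' contained in \[0, duration).
#'
#' @slot channel integer channel ids.
#' @slot time numeric timestamps, ms (aligned with channel).
#' @slot nChannels number of channels.
#' @slot duration recording length, ms.
#' @slot meta provenance list (threshold multiplier, band, neuron map, ...).
#' @exportClass EventSeries
setClass("EventSeries",
    representation(channel = "integer", time = "numeric",
                   nChannels = "integer", duration = "numeric",
                   meta = "list"))

setValidity("EventSeries", function(object) {
    if (length(object@channel) != length(object@time))
        return("channel and time must be aligned")
    if (length(object@time) &&
        (min(object@time) < 0 || max(object@time) >= object@duration))
        return("timestamps must lie in [0, duration)")
    for (ch in unique(object@channel)) {
        tt <- object@time[object@channel == ch]
        if (any(diff(tt) <= 0))
            return("timestamps must be strictly increasing per channel")
    }
    TRUE
})

#' Binned multichannel event counts
#'
#' Events from all channels binned at bin size binSize and summed; bin b
#' (1-based) covers times [(b-1)*binSize, b*binSize).
#'
#' @slot counts integer per-bin total event counts.
#' @slot binSize bin size, ms.
#' @exportClass BinnedActivity
setClass("BinnedActivity",
    representation(counts = "integer", binSize = "numeric"))

setValidity("BinnedActivity", function(object) {
    if (any(object@counts < 0L)) return("counts must be nonnegative")
    if (object@binSize <= 0) return("binSize must be positive")
    TRUE
})

#' Avalanche decomposition of binned activity
#'
#' Maximal runs of consecutive non-empty bins; size S is the total event
#' count of a run and duration D its bin count. Runs that touch the start
#' or end of the record are truncated cascades and may be discarded; the
#' events lost that way are counted in nDiscardedEvents.
#'
#' @slot size integer avalanche sizes S.
#' @slot duration integer avalanche durations D (bins).
#' @slot start integer first bin (1-based) of each avalanche.
#' @slot counts the per-bin counts the set was cut from.
#' @slot binSize bin size, ms.
#' @slot nDiscardedEvents events in discarded edge-truncated runs.
#' @exportClass AvalancheSet
setClass("AvalancheSet",
    representation(size = "integer", duration = "integer",
                   start = "integer", counts = "integer",
                   binSize = "numeric", nDiscardedEvents = "integer"))

setValidity("AvalancheSet", function(object) {
    if (length(object@size) != length(object@duration) ||
        length(object@size) != length(object@start))
        return("size, duration and start must be aligned")
    if (length(object@size) && any(object@size < object@duration))
        return("every bin of an avalanche holds at least one event")
    if (sum(object@size) + object@nDiscardedEvents != sum(object@counts))
        return("avalanche sizes plus discarded events must conserve the total")
    TRUE
})

#' Discrete power-law fit of avalanche sizes
#'
#' Maximum-likelihood fit of p(S) proportional to S^-alpha on integer
#' support \[sMin, sMax\], with a discrete-exponential alternative fitted on
#' the same support and the log-likelihood ratio as a diagnostic (positive
#' values favour the power law).
#'
#' @slot alpha fitted exponent.
#' @slot sMin,sMax fit range.
#' @slot n number of observations in range.
#' @slot logLik power-law log-likelihood at the optimum.
#' @slot llrExponential log-likelihood ratio power law vs exponential.
#' @slot expRate rate of the fitted discrete exponential.
#' @slot ksModel Kolmogorov-Smirnov distance between the empirical CDF of
#'   the in-range sizes and the fitted power-law CDF (goodness of fit; a
#'   pronounced decay shows up as a large value).
#' @exportClass PowerLawFit
setClass("PowerLawFit",
    representation(alpha = "numeric", sMin = "numeric", sMax = "numeric",
                   n = "integer", logLik = "numeric",
                   llrExponential = "numeric", expRate = "numeric",
                   ksModel = "numeric"))

#' Bin-size scaling of the fitted exponent
#'
#' Least-squares fit of ln(alpha) against ln(binSize); beta is minus the
#' slope, describing alpha ~ binSize^-beta.
#'
#' @slot table data.frame with columns binSize and alpha.
#' @slot beta scaling exponent.
#' @slot intercept intercept of the log-log fit.
#' @exportClass BinScalingFit
setClass("BinScalingFit",
    representation(table = "data.frame", beta = "numeric",
                   intercept = "numeric"))
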