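#' Accessors for critsample classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the documented classes.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("positions", function(x, ...) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("systemLength", function(x, ...) standardGeneric("systemLength"))

#' @rdname accessors
#' @export
setGeneric("activity", function(x, ...) standardGeneric("activity"))

#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x, ...) standardGeneric("signalMatrix"))

#' @rdname accessors
#' @export
setGeneric("eventTable", function(x, ...) standardGeneric("eventTable"))

#' @rdname accessors
#' @export
setGeneric("binCounts", function(x, ...) standardGeneric("binCounts"))

#' @rdname accessors
#' @export
setGeneric("avalancheSizes",
           function(x, ...) standardGeneric("avalancheSizes"))

#' @rdname accessors
#' @export
setGeneric("avalancheDurations",
           function(x, ...) standardGeneric("avalancheDurations"))

#' @rdname accessors
#' @export
setGeneric("plExponent", function(x, ...) standardGeneric("plExponent"))

#' @rdname accessors
#' @export
setMethod("positions", "NeuronGeometry", function(x, ...) x@positions)

#' @rdname accessors
#' @export
setMethod("positions", "ElectrodeArray", function(x, ...) x@positions)

#' @rdname accessors
#' @export
setMethod("positions", "NetworkTopology",
          function(x, ...) x@geometry@positions)

#' @rdname accessors
#' @export
setMethod("systemLength", "NeuronGeometry", function(x, ...) x@L)

#' @rdname accessors
#' @export
setMethod("systemLength", "NetworkTopology", function(x, ...) x@geometry@L)

#' @rdname accessors
#' @export
setMethod("activity", "SpikeRaster", function(x, ...) x@activity)

#' @rdname accessors
#' @export
setMethod("signalMatrix", "CoarseRecord", function(x, ...) x@signal)

#' @rdname accessors
#' @export
setMethod("eventTable", "EventSeries", function(x, ...)
    data.frame(channel_id = x@channel, time_ms = x@time))

#' @rdname accessors
#' @export
setMethod("binCounts", "BinnedActivity", function(x, ...) x@counts)

#' @rdname accessors
#' @export
setMethod("binCounts", "AvalancheSet", function(x, ...) x@counts)

#' @rdname accessors
#' @export
setMethod("avalancheSizes", "AvalancheSet", function(x, ...) x@size)

#' @rdname accessors
#' @export
setMethod("avalancheDurations", "AvalancheSet", function(x, ...) x@duration)

#' @rdname accessors
#' @export
setMethod("plExponent", "PowerLawFit", function(x, ...) x@alpha)

#' @rdname accessors
#' @export
setMethod("plExponent", "BinScalingFit", function(x, ...) x@table$alpha)

setMethod("show", "NeuronGeometry", function(object) {
    cat(sprintf(
        "NeuronGeometry: %d neurons on a periodic %.3g x %.3g mm plane (dN = %g um)\n",
        nrow(object@positions), object@L / 1000, object@L / 1000,
        object@dN))
    if (!is.null(object@electrodes))
        cat(sprintf("  dead zones of %g um around %d electrodes respected\n",
                    object@electrodes@deadZone,
                    nrow(object@electrodes@positions)))
})

setMethod("show", "ElectrodeArray", function(object) {
    cat(sprintf(
        "ElectrodeArray: %d x %d grid, dE = %g um, gamma = %g, dead zone %g um\n",
        object@gridDim[1], object@gridDim[2], object@dE, object@gamma,
        object@deadZone))
})

setMethod("show", "NetworkTopology", function(object) {
    deg <- diff(object@ptr)
    cat(sprintf(
        "NetworkTopology: %d neurons, mean out-degree %.1f (dMax = %.3g um, sigma = %g um)\n",
        nrow(object@geometry@positions), mean(deg), object@dMax,
        object@sigma))
})

setMethod("show", "DynamicState", function(object) {
    tau <- analyticTimescale(object@m, object@dt)
    cat(sprintf(
        "DynamicState '%s': m = %g, h = %g, dt = %g ms (tau = %.3g ms, target rate %g Hz)\n",
        object@name, object@m, object@h, object@dt, tau, object@rate))
})

setMethod("show", "SpikeRaster", function(object) {
    cat(sprintf(
        "SpikeRaster: %d spikes over %d steps (%.1f s), %d neurons, state '%s'\n",
        length(object@step), object@nSteps,
        object@nSteps * object@dt / 1000, object@nNeurons,
        object@state@name))
    if (object@saturatedSteps > 0L)
        cat(sprintf("  flag: %d saturated steps (all neurons active)\n",
                    object@saturatedSteps))
})

setMethod("show", "CoarseRecord", function(object) {
    cat(sprintf(
        "CoarseRecord: %d channels x %d steps (dt = %g ms, gamma = %g)\n",
        nrow(object@signal), ncol(object@signal), object@dt,
        object@gamma))
})

setMethod("show", "EventSeries", function(object) {
    cat(sprintf(
        "EventSeries: %d events on %d channels over %.1f s\n",
        length(object@time), object@nChannels, object@duration / 1000))
})

setMethod("show", "AvalancheSet", function(object) {
    cat(sprintf(
        "AvalancheSet: %d avalanches at binSize = %g ms (max S = %s, %d edge-discarded events)\n",
        length(object@size), object@binSize,
        if (length(object@size)) max(object@size) else "-",
        object@nDiscardedEvents))
})

setMethod("show", "PowerLawFit", function(object) {
    cat(sprintf(
        "PowerLawFit: alpha = %.3f on S in [%g, %g], n = %d, LLR vs exponential = %.1f\n",
        object@alpha, object@sMin, object@sMax, object@n,
        object@llrExponential))
})

setMethod("show", "BinScalingFit", function(object) {
    cat(sprintf("BinScalingFit: beta = %.3f over %d bin sizes\n",
                object@beta, nrow(object@table)))
})
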