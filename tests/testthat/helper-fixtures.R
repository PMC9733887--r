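# Shared fixtures, all built in code at test time.

# Geometry wrapped around externally chosen positions (hand fixtures).
geometryFromPositions <- function(pos, L, dN = 50) {
    methods::new("NeuronGeometry", positions = pos, L = L, dN = dN,
                 seed = NA_real_, electrodes = NULL)
}

# Hand-built topology from explicit target lists (list of integer vectors)
# and weights (list of numeric vectors); positions only nominal.
topologyFromLists <- function(targetList, weightList, L = 1000) {
    n <- length(targetList)
    pos <- cbind(runif(n, 0, L), runif(n, 0, L))
    ptr <- c(0L, cumsum(lengths(targetList)))
    methods::new("NetworkTopology",
                 geometry = geometryFromPositions(pos, L),
                 ptr = as.integer(ptr),
                 targets = as.integer(unlist(targetList)),
                 weights = as.numeric(unlist(weightList)),
                 dMax = L / 4, sigma = 300, k = mean(lengths(targetList)))
}

# Small connected geometry + topology reused across dynamics tests.
smallNetwork <- local({
    cache <- NULL
    function(n = 2000, seed = 101) {
        if (is.null(cache)) {
            geom <- placeNeurons(n, 50, seed = seed)
            top <- buildConnectivity(geom, k = min(1000, n / 10),
                                     sigma = 300)
            cache <<- list(geom = geom, top = top)
        }
        cache
    }
})

# Raster with explicit spikes: steps/neurons vectors (1-based steps; the
# timestamp of step t is (t-1)*dt).
rasterFromSpikes <- function(step, neuron, nSteps, nNeurons, dt = 2) {
    step <- as.integer(step)
    neuron <- as.integer(neuron)
    act <- tabulate(step, nSteps)
    methods::new("SpikeRaster", step = step, neuron = neuron,
                 activity = as.integer(act), nSteps = as.integer(nSteps),
                 nNeurons = as.integer(nNeurons), dt = dt, seed = NA_real_,
                 saturatedSteps = 0L, droppedActivations = 0L,
                 state = dynamicState("poisson", dt = dt))
}
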