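#' Linear system size from neuron count and spacing
#'
#' For uniformly random (ideal-gas) placement, a mean nearest-neighbour
#' spacing of `dN` corresponds to a linear size `L = 2 * sqrt(nNeurons) * dN`
#' and a density `nNeurons / L^2 = 1 / (4 * dN^2)`.
#'
#' @param nNeurons number of neurons.
#' @param dN mean nearest-neighbour distance, micrometres.
#' @return linear system size in micrometres.
#' @export
systemSize <- function(nNeurons, dN) {
    stopifnot(nNeurons >= 1, dN > 0)
    2 * sqrt(nNeurons) * dN
}

#' Neuron density of the ideal-gas placement
#'
#' @inheritParams systemSize
#' @return density in neurons per square micrometre.
#' @export
neuronDensity <- function(nNeurons, dN) {
    nNeurons / systemSize(nNeurons, dN)^2
}

#' Connection radius containing a given mean number of neighbours
#'
#' Radius of the disk that contains on average `k` neurons at density
#' `rho`: `sqrt(k / (pi * rho))`.
#'
#' @param k target mean out-degree.
#' @param rho neuron density, per square micrometre.
#' @return radius in micrometres.
#' @export
connectionRadius <- function(k, rho) {
    stopifnot(k > 0, rho > 0)
    sqrt(k / (pi * rho))
}

#' Place a centered grid of virtual electrodes
#'
#' The grid is centered in the periodic square of side `L`; electrode
#' positions are deterministic. The array must fit inside the system.
#'
#' @param rows,cols grid dimensions (default 8 x 8).
#' @param dE inter-electrode distance, micrometres.
#' @param L linear system size, micrometres.
#' @param deadZone exclusion radius around each electrode, micrometres.
#' @param gamma decay exponent of coarse-signal contributions
#'   (1 = wide field of view, 2 = narrow).
#' @return an \linkS4class{ElectrodeArray}.
#' @export
placeElectrodes <- function(rows = 8L, cols = 8L, dE, L, deadZone = 10,
                            gamma = 1) {
    stopifnot(rows >= 1, cols >= 1, dE > 0, L > 0)
    if ((max(rows, cols) - 1) * dE >= L)
        stop("electrode array does not fit inside the system")
    xo <- (seq_len(cols) - (cols + 1) / 2) * dE + L / 2
    yo <- (seq_len(rows) - (rows + 1) / 2) * dE + L / 2
    pos <- cbind(rep(xo, times = rows), rep(yo, each = cols))
    colnames(pos) <- c("x", "y")
    new("ElectrodeArray", positions = pos, dE = dE,
        gridDim = c(as.integer(rows), as.integer(cols)),
        deadZone = deadZone, gamma = gamma)
}

# Run fn with a locally seeded R RNG, restoring the caller's stream.
withLocalSeed <- function(seed, fn) {
    if (is.null(seed)) return(fn())
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
            else suppressWarnings(rm(".Random.seed",
                                     envir = globalenv())), add = TRUE)
    set.seed(seed)
    fn()
}

#' Place neurons uniformly at random outside electrode dead zones
#'
#' Uniform rejection sampling on the periodic square \[0, L)^2: electrodes
#' are placed first, and any neuron draw closer than the dead-zone radius
#' to an electrode (periodic minimum-image distance) is resampled. The
#' linear size is derived from `nNeurons` and `dN` via [systemSize()].
#'
#' @param nNeurons number of neurons.
#' @param dN mean nearest-neighbour distance, micrometres.
#' @param electrodes an \linkS4class{ElectrodeArray} or NULL.
#' @param seed placement RNG seed (R stream; restored afterwards).
#' @param maxAttempts cap on total draws before giving up (guards against
#'   dead zones covering the whole plane).
#' @return a \linkS4class{NeuronGeometry}.
#' @export
placeNeurons <- function(nNeurons, dN = 50, electrodes = NULL, seed = NULL,
                         maxAttempts = 1e6) {
    stopifnot(nNeurons >= 1, dN > 0)
    L <- systemSize(nNeurons, dN)
    pos <- withLocalSeed(seed, function() {
        out <- matrix(NA_real_, nNeurons, 2L)
        filled <- 0L
        attempts <- 0
        while (filled < nNeurons) {
            want <- nNeurons - filled
            draw <- ceiling(want * 1.1) + 16L
            attempts <- attempts + draw
            if (attempts > maxAttempts)
                stop("placement attempt cap exceeded; dead zones too large")
            cand <- cbind(runif(draw, 0, L), runif(draw, 0, L))
            if (!is.null(electrodes)) {
                d <- periodicDistanceCpp(cand, electrodes@positions, L)
                keep <- apply(d, 1L, min) >= electrodes@deadZone
                cand <- cand[keep, , drop = FALSE]
            }
            take <- min(nrow(cand), want)
            if (take > 0L)
                out[filled + seq_len(take), ] <- cand[seq_len(take), ,
                                                      drop = FALSE]
            filled <- filled + take
        }
        out
    })
    colnames(pos) <- c("x", "y")
    new("NeuronGeometry", positions = pos, L = L, dN = dN,
        seed = if (is.null(seed)) NA_real_ else seed,
        electrodes = electrodes)
}

#' Build distance-thresholded Gaussian-weight connectivity
#'
#' Every neuron is connected to all neighbours within `dMax` (periodic
#' minimum-image distance); by default `dMax` is chosen so a disk of that
#' radius contains on average `k` neurons. Connection weights decay as
#' `exp(-d^2 / (2 sigma^2))` and are normalized to sum to one per source
#' over the surviving (within-cutoff) targets. Target lists are sorted
#' ascending by distance, ties broken by neuron index.
#'
#' @param geometry a \linkS4class{NeuronGeometry}.
#' @param k target mean out-degree (used to derive `dMax` when not given).
#' @param sigma effective connection length, micrometres.
#' @param dMax connection cutoff, micrometres; must be < L/2.
#' @return a \linkS4class{NetworkTopology}.
#' @export
buildConnectivity <- function(geometry, k = 1000, sigma = 300,
                              dMax = NULL) {
    stopifnot(is(geometry, "NeuronGeometry"), sigma > 0)
    n <- nrow(geometry@positions)
    rho <- n / geometry@L^2
    if (is.null(dMax)) dMax <- connectionRadius(k, rho)
    if (dMax >= geometry@L / 2)
        stop("dMax must be < L/2 (minimum-image convention)")
    con <- buildConnectivityCpp(geometry@positions, geometry@L, dMax, sigma)
    new("NetworkTopology", geometry = geometry, ptr = con$ptr,
        targets = con$targets, weights = con$weights, dMax = dMax,
        sigma = sigma, k = k)
}

#' Target list of one neuron
#'
#' @param topology a \linkS4class{NetworkTopology}.
#' @param i source neuron index.
#' @return data.frame with columns target, weight, distance (sorted
#'   ascending by distance).
#' @export
targetsOf <- function(topology, i) {
    stopifnot(is(topology, "NetworkTopology"))
    idx <- seq.int(topology@ptr[i] + 1L, length.out = diff(topology@ptr)[i])
    tgt <- topology@targets[idx]
    p <- topology@geometry@positions
    d <- periodicDistanceCpp(p[tgt, , drop = FALSE],
                             p[i, , drop = FALSE], topology@geometry@L)
    data.frame(target = tgt, weight = topology@weights[idx],
               distance = as.numeric(d))
}
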