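#' Coarse-sampled (LFP-like) electrode signals
#'
#' Every spike contributes to every electrode with weight `1/d^gamma`,
#' where d is the periodic minimum-image neuron-to-electrode distance:
#' `V_k(t) = sum_i s_i(t) / d_ik^gamma`. Contributions are instantaneous
#' and strictly positive; divergence is prevented by the electrode dead
#' zones enforced at neuron placement.
#'
#' @param raster a \linkS4class{SpikeRaster}.
#' @param geometry the \linkS4class{NeuronGeometry} the raster was
#'   simulated on.
#' @param array an \linkS4class{ElectrodeArray}.
#' @param gamma decay exponent; defaults to the array's setting
#'   (1 = wide field of view, 2 = narrow).
#' @param cutoff optional contribution cutoff: neurons farther than this
#'   from an electrode contribute nothing to it (default `Inf`, every
#'   neuron contributes to every channel).
#' @return a \linkS4class{CoarseRecord} (channels x steps).
#' @export
coarseSignal <- function(raster, geometry, array, gamma = NULL,
                         cutoff = Inf) {
    stopifnot(is(raster, "SpikeRaster"), is(geometry, "NeuronGeometry"),
              is(array, "ElectrodeArray"))
    if (is.null(gamma)) gamma <- array@gamma
    stopifnot(gamma > 0, cutoff > 0)
    d <- periodicDistanceCpp(geometry@positions, array@positions,
                             geometry@L)
    contrib <- 1 / d^gamma  # nNeurons x nElectrodes
    if (is.finite(cutoff)) contrib[d > cutoff] <- 0
    s <- Matrix::sparseMatrix(i = raster@neuron, j = raster@step, x = 1,
                              dims = c(raster@nNeurons, raster@nSteps))
    v <- as.matrix(Matrix::crossprod(contrib, s))
    dimnames(v) <- NULL
    new("CoarseRecord", signal = v, dt = raster@dt, gamma = gamma,
        array = array)
}

#' Spike sub-sampling: each electrode observes its closest neuron
#'
#' Deterministic nearest-neuron assignment (periodic minimum-image
#' distance; equidistant ties broken by lowest neuron index). Whenever the
#' observed neuron spikes, the timestamp is recorded; all other neurons are
#' neglected.
#'
#' @inheritParams coarseSignal
#' @return an \linkS4class{EventSeries}; the electrode-to-neuron map is in
#'   `meta$neuronMap`.
#' @export
subsampleSpikes <- function(raster, geometry, array) {
    stopifnot(is(raster, "SpikeRaster"), is(geometry, "NeuronGeometry"),
              is(array, "ElectrodeArray"))
    d <- periodicDistanceCpp(array@positions, geometry@positions,
                             geometry@L)
    nearest <- apply(d, 1L, which.min)
    sel <- raster@neuron %in% nearest
    step <- raster@step[sel]
    neuron <- raster@neuron[sel]
    chan <- integer(0)
    tms <- numeric(0)
    for (k in seq_along(nearest)) {
        s <- sort(step[neuron == nearest[k]])
        chan <- c(chan, rep.int(k, length(s)))
        tms <- c(tms, (s - 1) * raster@dt)
    }
    new("EventSeries", channel = chan, time = tms,
        nChannels = nrow(array@positions),
        duration = raster@nSteps * raster@dt,
        meta = list(neuronMap = nearest, sampling = "spikes"))
}

#' Pearson correlation between two channel series
#'
#' @param a,b equal-length numeric series (e.g. binned event counts or
#'   processed signals of two electrodes).
#' @return Pearson correlation coefficient.
#' @export
channelCorrelation <- function(a, b) {
    stopifnot(length(a) == length(b), length(a) > 1)
    if (sd(a) == 0 || sd(b) == 0)
        stop("zero-variance input: correlation undefined")
    cor(a, b)
}

#' Grid-adjacent electrode pairs
#'
#' Horizontally and vertically adjacent channel pairs of the array's grid
#' (channel index runs column-fastest along x).
#'
#' @param array an \linkS4class{ElectrodeArray}.
#' @return two-column integer matrix of channel index pairs.
#' @export
adjacentPairs <- function(array) {
    r <- array@gridDim[1]
    cc <- array@gridDim[2]
    idx <- function(row, col) (row - 1L) * cc + col
    out <- matrix(0L, 0L, 2L)
    for (row in seq_len(r)) for (col in seq_len(cc)) {
        if (col < cc) out <- rbind(out, c(idx(row, col), idx(row, col + 1L)))
        if (row < r) out <- rbind(out, c(idx(row, col), idx(row + 1L, col)))
    }
    out
}

#' Per-channel binned event counts
#'
#' @param events an \linkS4class{EventSeries}.
#' @param binSize bin size, ms.
#' @return integer matrix channels x bins.
#' @export
binEventsByChannel <- function(events, binSize) {
    stopifnot(is(events, "EventSeries"), binSize > 0)
    nBins <- max(1L, as.integer(ceiling(events@duration / binSize)))
    out <- matrix(0L, events@nChannels, nBins)
    if (length(events@time)) {
        b <- pmin(as.integer(floor(events@time / binSize)) + 1L, nBins)
        for (i in seq_along(b))
            out[events@channel[i], b[i]] <- out[events@channel[i], b[i]] + 1L
    }
    out
}

#' Mean correlation between adjacent electrodes, with bootstrap CI
#'
#' Pearson correlation of binned per-channel event counts for every
#' grid-adjacent electrode pair, averaged over pairs (pairs with a
#' zero-variance channel are skipped). The confidence interval is a
#' percentile bootstrap over time bins, resampled jointly across channels
#' so the spatial structure is preserved.
#'
#' @param events an \linkS4class{EventSeries}.
#' @param array the \linkS4class{ElectrodeArray}.
#' @param binSize bin size, ms.
#' @param nBoot bootstrap replicates (0 to skip the CI).
#' @param level confidence level.
#' @param seed RNG seed for the bootstrap (R stream, restored).
#' @return list with elements `r` (mean adjacent correlation), `perPair`
#'   (data.frame i, j, r) and `ci` (bootstrap interval or NULL).
#' @export
adjacentCorrelation <- function(events, array, binSize, nBoot = 0,
                                level = 0.95, seed = NULL) {
    counts <- binEventsByChannel(events, binSize)
    pairs <- adjacentPairs(array)
    meanAdjacent <- function(m) {
        rs <- rep(NA_real_, nrow(pairs))
        for (p in seq_len(nrow(pairs))) {
            a <- m[pairs[p, 1L], ]
            b <- m[pairs[p, 2L], ]
            if (sd(a) > 0 && sd(b) > 0) rs[p] <- cor(a, b)
        }
        rs
    }
    rs <- meanAdjacent(counts)
    out <- list(r = mean(rs, na.rm = TRUE),
                perPair = data.frame(i = pairs[, 1L], j = pairs[, 2L],
                                     r = rs),
                ci = NULL)
    if (nBoot > 0) {
        nb <- ncol(counts)
        out$ci <- withLocalSeed(seed, function() {
            reps <- vapply(seq_len(nBoot), function(i) {
                m <- counts[, sample.int(nb, nb, replace = TRUE),
                            drop = FALSE]
                mean(meanAdjacent(m), na.rm = TRUE)
            }, numeric(1))
            quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                     na.rm = TRUE, names = FALSE)
        })
    }
    out
}
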