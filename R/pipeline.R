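#' Derive independent per-network seeds from a master seed
#'
#' Deterministic splitting rule (multiplicative hash mod 2^31) so ensemble
#' members use unrelated streams and a single master seed reproduces the
#' whole experiment.
#'
#' @param master master seed (integer-valued).
#' @param n number of seeds.
#' @return numeric vector of `n` seeds in \[1, 2^31).
#' @export
splitSeeds <- function(master, n) {
    stopifnot(n >= 1)
    s <- (as.numeric(master) %% 2^31) + 1
    out <- ((s * 48271 + seq_len(n) * 2654435761) %% (2^31 - 1)) + 1
    out
}

#' Experiment configuration
#'
#' Bundles geometry, dynamic state, electrode settings and analysis
#' settings into one serializable list; a configuration plus the package
#' version determines every output. Defaults are the desk-scale study
#' conditions: 10 000 neurons at the full model's density, out-degree
#' `min(1000, nNeurons/10)`, 8 x 8 electrodes.
#'
#' @param state a \linkS4class{DynamicState} or a preset name for
#'   [dynamicState()].
#' @param nNeurons,dN,sigma geometry parameters (counts, um, um).
#' @param k mean out-degree; default `min(1000, nNeurons / 10)`.
#' @param nSteps simulated steps per network (after burn-in).
#' @param nNetworks ensemble size.
#' @param grid electrode grid c(rows, cols).
#' @param dE inter-electrode distance, um.
#' @param gamma electrode decay exponent.
#' @param deadZone electrode dead-zone radius, um.
#' @param binSizes analysis bin sizes, ms.
#' @param thresholdSD threshold multiplier for event extraction.
#' @param band band-pass edges, Hz.
#' @param fitRange power-law fit range c(sMin, sMax).
#' @param burnIn steps discarded before analysis; default
#'   [defaultBurnIn()] of the state.
#' @param seed master seed.
#' @return a named list of class "ExperimentConfig".
#' @export
experimentConfig <- function(state = "reverberating", nNeurons = 10000,
                             dN = 50, k = min(1000, nNeurons / 10),
                             sigma = 300, nSteps = 1e5, nNetworks = 5,
                             grid = c(8, 8), dE = 400, gamma = 1,
                             deadZone = 10, binSizes = 8,
                             thresholdSD = 3, band = c(0.1, 200),
                             fitRange = c(1, 50), burnIn = NULL,
                             seed = 1) {
    if (is.character(state)) state <- dynamicState(state)
    stopifnot(is(state, "DynamicState"))
    if (is.null(burnIn)) burnIn <- defaultBurnIn(state)
    cfg <- list(state = state, nNeurons = nNeurons, dN = dN, k = k,
                sigma = sigma, nSteps = nSteps, nNetworks = nNetworks,
                grid = grid, dE = dE, gamma = gamma, deadZone = deadZone,
                binSizes = binSizes, thresholdSD = thresholdSD,
                band = band, fitRange = fitRange, burnIn = burnIn,
                seed = seed)
    class(cfg) <- "ExperimentConfig"
    cfg
}

#' Named presets of the study conditions
#'
#' One preset per dynamic state. The plain names use the desk-scale
#' defaults of [experimentConfig()]; `"*_desk"` aliases are accepted for
#' clarity.
#'
#' @param name "poisson", "subcritical", "reverberating" or "critical"
#'   (optionally suffixed "_desk").
#' @param ... overrides passed to [experimentConfig()].
#' @return an ExperimentConfig.
#' @export
preset <- function(name, ...) {
    base <- sub("_desk$", "", name)
    experimentConfig(state = dynamicState(base), ...)
}

# One network realization: simulate, trim burn-in, sample both ways and
# run the avalanche analysis for every requested bin size.
runNetwork <- function(cfg, topoSeed, dynSeed) {
    L <- systemSize(cfg$nNeurons, cfg$dN)
    arr <- placeElectrodes(cfg$grid[1], cfg$grid[2], cfg$dE, L,
                           deadZone = cfg$deadZone, gamma = cfg$gamma)
    geom <- placeNeurons(cfg$nNeurons, cfg$dN, electrodes = arr,
                         seed = topoSeed)
    top <- buildConnectivity(geom, k = cfg$k, sigma = cfg$sigma)
    sim <- simulateBranching(top, cfg$state, cfg$nSteps + cfg$burnIn,
                             seed = dynSeed)
    sim <- discardBurnIn(sim, cfg$burnIn)
    # near m = 0 the AR(1) slope can dip below zero; tau = 0 is the answer
    tauHat <- suppressWarnings(estimateTimescale(sim))

    coarse <- coarseSignal(sim, geom, arr)
    evCoarse <- extractEvents(coarse, thresholdSD = cfg$thresholdSD,
                              band = cfg$band)
    evSub <- subsampleSpikes(sim, geom, arr)

    analyse <- function(ev) lapply(cfg$binSizes, function(bs)
        cutAvalanches(binEvents(ev, bs)))
    list(tauHat = as.numeric(tauHat), rate = meanRate(sim),
         saturatedSteps = sim@saturatedSteps,
         coarse = analyse(evCoarse), sub = analyse(evSub),
         events = list(coarse = evCoarse, sub = evSub),
         array = arr)
}

#' Run an ensemble experiment end to end
#'
#' Simulates `nNetworks` independent networks (seeds derived from the
#' master seed by [splitSeeds()]), applies both sampling paths, and pools
#' avalanches across networks before computing distributions, power-law
#' fits and the avalanche-based branching estimate for every bin size.
#' A failed network run is recorded and excluded rather than aborting the
#' ensemble.
#'
#' @param cfg an ExperimentConfig from [experimentConfig()] or [preset()].
#' @param keepEvents retain per-network event series in the result
#'   (default FALSE to save memory).
#' @return list with elements `perNetwork` (tauHat, rate per network),
#'   `pooled` (per path and bin size: sizes, fit or fit error, mAv),
#'   `failures`, and `config`.
#' @export
runExperiment <- function(cfg, keepEvents = FALSE) {
    stopifnot(inherits(cfg, "ExperimentConfig"))
    seeds <- matrix(splitSeeds(cfg$seed, 2 * cfg$nNetworks), ncol = 2)
    nets <- vector("list", cfg$nNetworks)
    failures <- list()
    for (i in seq_len(cfg$nNetworks)) {
        nets[[i]] <- tryCatch(
            runNetwork(cfg, seeds[i, 1], seeds[i, 2]),
            error = function(e) e)
        if (inherits(nets[[i]], "error")) {
            failures[[length(failures) + 1L]] <-
                list(network = i, message = conditionMessage(nets[[i]]))
            nets[[i]] <- NULL
        } else if (!keepEvents) {
            nets[[i]]$events <- NULL
        }
    }
    ok <- !vapply(nets, is.null, logical(1))
    nets <- nets[ok]
    if (!length(nets)) stop("all network runs failed")

    poolPath <- function(path) {
        lapply(seq_along(cfg$binSizes), function(bi) {
            avsList <- lapply(nets, function(nw) path(nw)[[bi]])
            sizes <- unlist(lapply(avsList, avalancheSizes))
            fit <- tryCatch(
                fitPowerLaw(sizes, cfg$fitRange[1], cfg$fitRange[2]),
                error = function(e) e)
            mavs <- lapply(avsList, function(a)
                tryCatch(branchingFromAvalanches(a),
                         error = function(e) NULL))
            np <- vapply(mavs, function(m)
                if (is.null(m)) 0 else attr(m, "nPairs"), numeric(1))
            mAv <- if (sum(np) > 0)
                sum(vapply(mavs, function(m)
                    if (is.null(m)) 0 else as.numeric(m), numeric(1)) *
                    np) / sum(np)
            else NA_real_
            list(binSize = cfg$binSizes[bi], sizes = sizes, fit = fit,
                 mAv = mAv)
        })
    }

    list(perNetwork = data.frame(
             tauHat = vapply(nets, `[[`, numeric(1), "tauHat"),
             rate = vapply(nets, `[[`, numeric(1), "rate"),
             saturatedSteps = vapply(nets, `[[`, integer(1),
                                     "saturatedSteps")),
         pooled = list(coarse = poolPath(function(nw) nw$coarse),
                       sub = poolPath(function(nw) nw$sub)),
         networks = if (keepEvents) nets else NULL,
         failures = failures, config = cfg)
}
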