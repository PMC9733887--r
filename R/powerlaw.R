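# Discrete power-law machinery on a finite integer support [sMin, sMax].
# Count data (avalanche sizes) call for the discrete likelihood; the
# truncated support mirrors the conventional fit range S <= 50.

plLogZ <- function(alpha, support) log(sum(support^(-alpha)))

plNegLogLik <- function(alpha, sizes, support) {
    length(sizes) * plLogZ(alpha, support) + alpha * sum(log(sizes))
}

expNegLogLik <- function(rate, sizes, support) {
    length(sizes) * log(sum(exp(-rate * support))) + rate * sum(sizes)
}

#' Discrete power-law fit of avalanche sizes
#'
#' Maximum-likelihood fit of `p(S) = S^-alpha / Z` on integer support
#' `[sMin, sMax]` (default `[1, 50]`, the conventional fit range). Sizes
#' outside the range are excluded before fitting. A discrete exponential
#' `p(S) = exp(-lambda S) / Z` is fitted on the same support and compared
#' via the log-likelihood ratio: positive values favour the power law,
#' clearly negative values indicate a pronounced (faster-than-power-law)
#' decay.
#'
#' @param sizes integer avalanche sizes, or an \linkS4class{AvalancheSet}.
#' @param sMin,sMax fit range (inclusive).
#' @param minCount minimum number of in-range sizes required (default 100).
#' @return a \linkS4class{PowerLawFit}.
#' @export
fitPowerLaw <- function(sizes, sMin = 1, sMax = 50, minCount = 100) {
    if (is(sizes, "AvalancheSet")) sizes <- sizes@size
    stopifnot(sMin >= 1, sMax > sMin)
    sizes <- sizes[sizes >= sMin & sizes <= sMax]
    n <- length(sizes)
    if (n < minCount)
        stop(sprintf("only %d avalanches in fit range (need >= %d)", n,
                     minCount))
    if (length(unique(sizes)) < 2L)
        stop("degenerate sample: all sizes equal")
    support <- seq.int(sMin, sMax)
    opt <- optimize(plNegLogLik, c(1e-3, 10), sizes = sizes,
                    support = support, tol = 1e-8)
    optE <- optimize(expNegLogLik, c(1e-8, 10), sizes = sizes,
                     support = support, tol = 1e-8)
    modelCdf <- cumsum(support^(-opt$minimum))
    modelCdf <- modelCdf / modelCdf[length(modelCdf)]
    empCdf <- cumsum(tabulate(as.integer(sizes - sMin + 1),
                              length(support))) / n
    new("PowerLawFit", alpha = opt$minimum, sMin = sMin, sMax = sMax,
        n = n, logLik = -opt$objective,
        llrExponential = optE$objective - opt$objective,
        expRate = optE$minimum,
        ksModel = max(abs(empCdf - modelCdf)))
}

#' Sample from a discrete power law on a finite support
#'
#' Inversion sampling of `p(S) = S^-alpha / Z` on integers
#' `[sMin, sMax]`; the generator used as the independent oracle for the
#' fitting routines and as a synthetic-data fixture.
#'
#' @param n number of draws.
#' @param alpha exponent (> 0).
#' @param sMin,sMax support (inclusive).
#' @param seed RNG seed (R stream, restored afterwards).
#' @return integer vector of draws.
#' @export
rPowerLawInt <- function(n, alpha, sMin = 1, sMax = 50, seed = NULL) {
    stopifnot(n >= 0, alpha > 0, sMin >= 1, sMax > sMin)
    support <- seq.int(sMin, sMax)
    p <- support^(-alpha)
    withLocalSeed(seed, function()
        sample(support, n, replace = TRUE, prob = p))
}
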