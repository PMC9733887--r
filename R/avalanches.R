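#' Bin events from all channels and sum
#'
#' Bin b (1-based) counts events with `(b-1)*binSize <= t < b*binSize`,
#' summed over channels. The total count is conserved.
#'
#' @param events an \linkS4class{EventSeries}.
#' @param binSize bin size, ms (a positive multiple of the sampling step).
#' @return a \linkS4class{BinnedActivity}.
#' @export
binEvents <- function(events, binSize) {
    stopifnot(is(events, "EventSeries"), binSize > 0)
    nBins <- max(1L, as.integer(ceiling(events@duration / binSize)))
    counts <- if (length(events@time))
        tabulate(as.integer(floor(events@time / binSize)) + 1L, nBins)
    else integer(nBins)
    new("BinnedActivity", counts = as.integer(counts), binSize = binSize)
}

#' Cut binned activity into avalanches
#'
#' An avalanche is a maximal run of consecutive non-empty bins: it starts
#' at a non-empty bin preceded by an empty one and ends when an empty bin
#' is observed. Size S is the total event count of the run and duration D
#' its length in bins. Runs still open at the record edges are truncated
#' cascades whose S and D are undefined; by default they are discarded and
#' their events counted in `nDiscardedEvents`.
#'
#' @param binned a \linkS4class{BinnedActivity}.
#' @param dropEdges discard runs touching the first or last bin (default
#'   TRUE).
#' @return an \linkS4class{AvalancheSet}.
#' @export
cutAvalanches <- function(binned, dropEdges = TRUE) {
    stopifnot(is(binned, "BinnedActivity"))
    counts <- binned@counts
    occ <- counts > 0L
    discarded <- 0L
    if (!any(occ))
        return(new("AvalancheSet", size = integer(0),
                   duration = integer(0), start = integer(0),
                   counts = counts, binSize = binned@binSize,
                   nDiscardedEvents = 0L))
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    cs <- c(0L, cumsum(counts))
    size <- cs[ends[runs] + 1L] - cs[starts[runs]]
    keep <- rep(TRUE, length(runs))
    if (dropEdges && length(runs)) {
        open <- starts[runs] == 1L | ends[runs] == length(counts)
        discarded <- as.integer(sum(size[open]))
        keep <- !open
    }
    new("AvalancheSet", size = as.integer(size[keep]),
        duration = as.integer(r$lengths[runs][keep]),
        start = as.integer(starts[runs][keep]), counts = counts,
        binSize = binned@binSize, nDiscardedEvents = discarded)
}

#' Empirical avalanche-size distribution
#'
#' Normalized occurrence counts: `p(S)` sums to one over observed sizes.
#'
#' @param avs an \linkS4class{AvalancheSet} or integer vector of sizes.
#' @return data.frame with columns size, count, p.
#' @export
sizeDistribution <- function(avs) {
    s <- if (is(avs, "AvalancheSet")) avs@size else as.integer(avs)
    if (!length(s)) return(data.frame(size = integer(0), count = integer(0),
                                      p = numeric(0)))
    tb <- table(s)
    data.frame(size = as.integer(names(tb)), count = as.integer(tb),
               p = as.numeric(tb) / length(s))
}

#' Avalanche-based branching-parameter estimate
#'
#' The classical estimator from avalanche data: the average ratio of event
#' counts between subsequent time bins within an avalanche (during
#' non-zero activity). By default all consecutive-bin pairs are pooled
#' across avalanches before averaging; `perAvalanche = TRUE` first averages
#' ratios within each avalanche and then across avalanches.
#'
#' @param avs an \linkS4class{AvalancheSet}.
#' @param perAvalanche average per avalanche first (default FALSE: pool
#'   all pairs).
#' @return the estimate, with the number of ratio pairs attached as
#'   attribute "nPairs".
#' @export
branchingFromAvalanches <- function(avs, perAvalanche = FALSE) {
    stopifnot(is(avs, "AvalancheSet"))
    long <- which(avs@duration >= 2L)
    if (!length(long))
        stop("no avalanche with duration >= 2: estimator undefined")
    perAv <- vector("list", length(long))
    for (i in seq_along(long)) {
        a <- long[i]
        b <- avs@counts[avs@start[a]:(avs@start[a] + avs@duration[a] - 1L)]
        perAv[[i]] <- b[-1L] / b[-length(b)]
    }
    nPairs <- sum(lengths(perAv))
    est <- if (perAvalanche) mean(vapply(perAv, mean, numeric(1)))
           else mean(unlist(perAv))
    structure(est, nPairs = nPairs)
}

#' Scaling of the fitted exponent with bin size
#'
#' Least-squares fit of `ln(alpha)` on `ln(binSize)`, describing
#' `alpha ~ binSize^-beta`.
#'
#' @param binSize numeric vector of bin sizes, ms (>= 3 distinct values).
#' @param alpha fitted exponents aligned with `binSize`.
#' @return a \linkS4class{BinScalingFit}.
#' @export
fitBinScaling <- function(binSize, alpha) {
    stopifnot(length(binSize) == length(alpha),
              length(unique(binSize)) >= 3, all(alpha > 0),
              all(binSize > 0))
    fit <- lm(log(alpha) ~ log(binSize))
    new("BinScalingFit",
        table = data.frame(binSize = binSize, alpha = alpha),
        beta = -unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]))
}

#' Kolmogorov-Smirnov distance between two size samples
#'
#' Maximum absolute difference of the empirical CDFs; used to quantify how
#' close or separated two avalanche-size distributions are.
#'
#' @param a,b integer vectors of avalanche sizes (or
#'   \linkS4class{AvalancheSet}s).
#' @return the KS distance in \[0, 1\].
#' @export
ksDistance <- function(a, b) {
    if (is(a, "AvalancheSet")) a <- a@size
    if (is(b, "AvalancheSet")) b <- b@size
    stopifnot(length(a) > 0, length(b) > 0)
    g <- sort(unique(c(a, b)))
    fa <- vapply(g, function(s) mean(a <= s), numeric(1))
    fb <- vapply(g, function(s) mean(b <= s), numeric(1))
    max(abs(fa - fb))
}
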