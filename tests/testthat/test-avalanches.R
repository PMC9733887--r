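test_that("binning sums events from all channels and conserves totals", {
    ev <- eventSeries(channel = c(1, 2, 1), time = c(1, 3, 9),
                      nChannels = 2, duration = 12)
    b <- binEvents(ev, 4)
    expect_identical(binCounts(b), c(2L, 0L, 1L))

    e0 <- eventSeries(integer(0), numeric(0), nChannels = 3, duration = 12)
    expect_identical(binCounts(binEvents(e0, 4)), c(0L, 0L, 0L))

    set.seed(1)
    evR <- eventSeries(channel = sample(1:5, 300, TRUE),
                       time = sort(runif(300, 0, 999)) + (1:300) * 1e-6,
                       nChannels = 5, duration = 1000)
    for (bs in c(1, 7, 40))
        expect_equal(sum(binCounts(binEvents(evR, bs))), 300)
})

test_that("avalanche cutting matches the definition and conserves events", {
    b <- binnedFromCounts(c(3, 1, 0, 2, 0, 0, 5))
    avs <- cutAvalanches(b, dropEdges = FALSE)
    expect_identical(avalancheSizes(avs), c(4L, 2L, 5L))
    expect_identical(avalancheDurations(avs), c(2L, 1L, 1L))

    # edge-open runs (first and last here) are truncated cascades
    avsE <- cutAvalanches(b)
    expect_identical(avalancheSizes(avsE), 2L)
    expect_identical(avsE@nDiscardedEvents, 9L)

    expect_length(avalancheSizes(cutAvalanches(binnedFromCounts(rep(0, 6)))),
                  0)
    allOn <- cutAvalanches(binnedFromCounts(c(2, 1, 3)), dropEdges = FALSE)
    expect_identical(avalancheSizes(allOn), 6L)
    expect_identical(avalancheDurations(allOn), 3L)
})

test_that("avalanche cutting agrees with a naive reference on random input", {
    naiveCut <- function(counts) {
        sizes <- integer(0); durs <- integer(0)
        s <- 0L; d <- 0L
        for (c in counts) {
            if (c > 0) { s <- s + c; d <- d + 1L }
            else if (d > 0) { sizes <- c(sizes, s); durs <- c(durs, d)
                              s <- 0L; d <- 0L }
        }
        if (d > 0) { sizes <- c(sizes, s); durs <- c(durs, d) }
        list(sizes = sizes, durs = durs)
    }
    set.seed(99)
    for (i in 1:200) {
        counts <- rpois(sample(5:80, 1), lambda = runif(1, 0.2, 3))
        avs <- cutAvalanches(binnedFromCounts(counts), dropEdges = FALSE)
        ref <- naiveCut(counts)
        expect_identical(avalancheSizes(avs), ref$sizes)
        expect_identical(avalancheDurations(avs), ref$durs)
        expect_equal(sum(avalancheSizes(avs)), sum(counts))
        # with edge dropping, conservation includes the discarded events
        avsE <- cutAvalanches(binnedFromCounts(counts))
        expect_equal(sum(avalancheSizes(avsE)) + avsE@nDiscardedEvents,
                     sum(counts))
    }
})

test_that("coarser bins never increase the avalanche count", {
    set.seed(7)
    for (i in 1:20) {
        ev <- eventSeries(channel = rep(1, 400),
                          time = sort(runif(400, 0, 4000)),
                          nChannels = 1, duration = 4000)
        nAv <- vapply(c(2, 4, 8, 16), function(bs)
            length(avalancheSizes(cutAvalanches(binEvents(ev, bs),
                                                dropEdges = FALSE))),
            numeric(1))
        expect_true(all(diff(nAv) <= 0))
    }
})

test_that("size distributions are normalized occurrence counts", {
    d <- sizeDistribution(c(4L, 2L, 5L))
    expect_equal(d$size, c(2L, 4L, 5L))
    expect_equal(d$p, rep(1 / 3, 3))
    expect_equal(sizeDistribution(7L)$p, 1)

    draws <- rPowerLawInt(1e4, 1.5, seed = 2)
    emp <- sizeDistribution(draws)
    theo <- (1:50)^-1.5 / sum((1:50)^-1.5)
    # multinomial error: compare within 4 SE per size
    se <- sqrt(theo * (1 - theo) / 1e4)
    obs <- theo * 0
    obs[emp$size] <- emp$p
    expect_true(all(abs(obs - theo) < 4 * se + 2e-4))
})

test_that("the avalanche branching estimator averages in-avalanche ratios", {
    expect_equal(as.numeric(branchingFromAvalanches(
        cutAvalanches(binnedFromCounts(c(0, 2, 4, 0)), dropEdges = FALSE))),
        2)
    avs <- cutAvalanches(binnedFromCounts(c(0, 1, 1, 1, 0, 2, 2, 0)),
                         dropEdges = FALSE)
    expect_equal(as.numeric(branchingFromAvalanches(avs)), 1)
    avs2 <- cutAvalanches(binnedFromCounts(c(0, 1, 2, 0, 4, 2, 0)),
                          dropEdges = FALSE)
    expect_equal(as.numeric(branchingFromAvalanches(avs2)), 1.25)
    expect_equal(attr(branchingFromAvalanches(avs2), "nPairs"), 2)

    # pooled pairs vs per-avalanche averaging differ when durations differ
    avs3 <- cutAvalanches(binnedFromCounts(c(0, 1, 2, 4, 0, 2, 1, 0)),
                          dropEdges = FALSE)
    expect_equal(as.numeric(branchingFromAvalanches(avs3)), (2 + 2 + 0.5) / 3)
    expect_equal(as.numeric(branchingFromAvalanches(avs3,
                                                    perAvalanche = TRUE)),
                 mean(c(2, 0.5)))

    expect_error(branchingFromAvalanches(
        cutAvalanches(binnedFromCounts(c(0, 3, 0, 1, 0)),
                      dropEdges = FALSE)),
        "duration >= 2")
})

test_that("discrete power-law MLE recovers known exponents", {
    draws <- rPowerLawInt(1e5, 1.5, seed = 31)
    fit <- fitPowerLaw(draws)
    expect_equal(fit@alpha, 1.5, tolerance = 0.02 / 1.5)
    expect_equal(fit@n, 1e5L)
    expect_gt(fit@llrExponential, 0)
    expect_lt(fit@ksModel, 0.01)

    draws2 <- rPowerLawInt(5e4, 2.4, seed = 32)
    expect_equal(fitPowerLaw(draws2)@alpha, 2.4, tolerance = 0.02)

    # out-of-range sizes are excluded before fitting
    fit3 <- fitPowerLaw(c(draws, rep(500L, 1000)))
    expect_equal(fit3@n, 1e5L)

    expect_error(fitPowerLaw(rep(3L, 500)), "degenerate")
    expect_error(fitPowerLaw(rPowerLawInt(50, 1.5, seed = 1)), "50")
})

test_that("exponential data are flagged against the power law", {
    set.seed(12)
    geo <- pmin(rgeom(2e4, 0.4) + 1L, 50L)
    fit <- fitPowerLaw(geo)
    expect_lt(fit@llrExponential, 0)   # exponential wins
    expect_gt(fit@ksModel, 0.05)       # and the power law misfits
})

test_that("bin-size scaling recovers exact and degenerate exponents", {
    dts <- c(2, 4, 8, 16)
    sc <- fitBinScaling(dts, 2 * dts^-0.16)
    expect_equal(sc@beta, 0.16, tolerance = 1e-10)
    expect_equal(sc@intercept, log(2), tolerance = 1e-10)
    expect_equal(fitBinScaling(dts, rep(1.3, 4))@beta, 0)
    expect_error(fitBinScaling(c(2, 4), c(1, 2)))
})

test_that("KS distance separates unlike distributions and vanishes for like", {
    a <- rPowerLawInt(5000, 1.5, seed = 1)
    expect_equal(ksDistance(a, a), 0)
    b <- rPowerLawInt(5000, 3.0, seed = 2)
    expect_gt(ksDistance(a, b), 0.2)
    c1 <- rPowerLawInt(5000, 1.5, seed = 3)
    expect_lt(ksDistance(a, c1), 0.05)
})
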