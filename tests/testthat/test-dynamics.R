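test_that("analytic timescale matches the branching-process relation", {
    expect_equal(analyticTimescale(0.9, 2), -2 / log(0.9))
    expect_equal(analyticTimescale(0.9, 2), 18.98, tolerance = 1e-3)
    expect_equal(analyticTimescale(0.999, 2), 1999.0, tolerance = 1e-3)
    expect_equal(analyticTimescale(0, 2), 0)
    expect_error(analyticTimescale(1, 2), "diverges")
    expect_error(analyticTimescale(1.2, 2))
})

test_that("drive inverts the stationary-rate relation for all named states", {
    expect_equal(driveForRate(1, 0.0, 2), 2e-3)
    expect_equal(driveForRate(1, 0.9, 2), 2e-4)
    expect_equal(driveForRate(1, 0.98, 2), 4e-5)
    expect_equal(driveForRate(1, 0.999, 2), 2e-6)
    expect_error(driveForRate(1e6, 0, 2), "h > 1")
    # round trip: r = h / (dt_s * (1 - m))
    h <- driveForRate(3, 0.7, 2)
    expect_equal(h / ((2 / 1000) * (1 - 0.7)), 3)
})

test_that("named states carry the canonical parametrization", {
    st <- dynamicState("critical")
    expect_equal(st@m, 0.999)
    expect_equal(st@h, 2e-6)
    expect_equal(st@dt, 2)
    expect_equal(dynamicState("reverberating")@m, 0.98)
    expect_equal(dynamicState(m = 0.5)@name, "custom")
})

test_that("m = 0 dynamics are pure spontaneous spiking with binomial counts", {
    net <- smallNetwork()
    n <- nrow(positions(net$top))
    st <- dynamicState("poisson")  # h = 2e-3
    sim <- simulateBranching(net$top, st, 5000, seed = 3)
    A <- activity(sim)
    expect_equal(mean(A), n * st@h, tolerance = 0.05)
    expect_equal(var(A), n * st@h * (1 - st@h), tolerance = 0.1)
    expect_equal(meanRate(sim), 1, tolerance = 0.05)
})

test_that("zero drive from an empty start stays absorbing", {
    net <- smallNetwork()
    st <- methods::new("DynamicState", m = 0.9, h = 0, dt = 2,
                       rate = 0, name = "custom")
    sim <- simulateBranching(net$top, st, 100, seed = 1)
    expect_identical(activity(sim), rep(0L, 100))
    expect_length(sim@step, 0)
})

test_that("single-spike offspring count averages to m for both samplers", {
    net <- smallNetwork()
    st <- methods::new("DynamicState", m = 0.97, h = 0, dt = 2,
                       rate = 0, name = "custom")
    for (method in c("skip", "naive")) {
        off <- vapply(1:600, function(i) {
            sim <- simulateBranching(net$top, st, 1, seed = 1000 + i,
                                     compensate = FALSE, method = method,
                                     initActive = 7L)
            activity(sim)[1]
        }, integer(1))
        se <- stats::sd(off) / sqrt(length(off))
        expect_lt(abs(mean(off) - st@m), 3.5 * se + 1e-9)
    }
})

test_that("skip and naive samplers activate targets with the same law", {
    # one source with a steeply decaying weight profile; compare per-target
    # activation frequencies between the two samplers
    w <- c(0.4, 0.3, 0.15, 0.1, 0.05)
    top <- topologyFromLists(list(2:6, integer(0), integer(0), integer(0),
                                  integer(0), integer(0)),
                             list(w, numeric(0), numeric(0), numeric(0),
                                  numeric(0), numeric(0)))
    st <- methods::new("DynamicState", m = 0.8, h = 0, dt = 2,
                       rate = 0, name = "custom")
    freq <- function(method) {
        hits <- matrix(0, 800, 5)
        for (i in 1:800) {
            sim <- simulateBranching(top, st, 1, seed = i,
                                     compensate = FALSE, method = method,
                                     initActive = 1L)
            hits[i, ] <- tabulate(sim@neuron - 1L, 5)
        }
        colMeans(hits)
    }
    fSkip <- freq("skip")
    fNaive <- freq("naive")
    expect_equal(fSkip, 0.8 * w, tolerance = 0.15)
    expect_equal(fNaive, 0.8 * w, tolerance = 0.15)
})

test_that("coalescence compensation redirects to the next quiescent target", {
    # neuron 1 hits 3 first (index order); neuron 2 also aims at 3 and can
    # fall back to 4. With compensation the double hit lands on 4, never
    # lost.
    top <- topologyFromLists(
        list(3L, c(3L, 4L), integer(0), integer(0)),
        list(1, c(1 - 1e-12, 1e-12), numeric(0), numeric(0)))
    st <- methods::new("DynamicState", m = 1 - 1e-9, h = 0, dt = 2,
                       rate = 0, name = "custom")
    both <- 0L
    for (i in 1:50) {
        sim <- simulateBranching(top, st, 1, seed = i, compensate = TRUE,
                                 initActive = c(1L, 2L))
        act <- sort(sim@neuron)
        expect_false(any(duplicated(act)))
        if (identical(act, c(3L, 4L))) both <- both + 1L
    }
    expect_equal(both, 50L)  # both activations survive via redirection

    # without a quiescent alternative the colliding activation is dropped
    top2 <- topologyFromLists(list(3L, 3L, integer(0)),
                              list(1, 1, numeric(0)))
    sim2 <- simulateBranching(top2, st, 1, seed = 1, compensate = TRUE,
                              initActive = c(1L, 2L))
    expect_identical(sim2@neuron, 3L)
    expect_gte(sim2@droppedActivations, 1L)
})

test_that("compensation preserves the offspring budget under collisions", {
    net <- smallNetwork()
    st <- methods::new("DynamicState", m = 0.95, h = 0, dt = 2,
                       rate = 0, name = "custom")
    seedNeurons <- as.integer(round(seq(1, 2000, length.out = 200)))
    offspring <- function(compensate) {
        vapply(1:150, function(i) {
            sim <- simulateBranching(net$top, st, 1, seed = 5000 + i,
                                     compensate = compensate,
                                     initActive = seedNeurons)
            activity(sim)[1]
        }, integer(1))
    }
    on <- offspring(TRUE)
    offv <- offspring(FALSE)
    expected <- st@m * length(seedNeurons)
    expect_lt(abs(mean(on) - expected), 0.03 * expected)
    expect_lt(mean(offv), mean(on))  # collisions lose activations
})

test_that("simulation is deterministic under fixed seeds", {
    net <- smallNetwork()
    st <- dynamicState("subcritical")
    a <- simulateBranching(net$top, st, 500, seed = 9)
    b <- simulateBranching(net$top, st, 500, seed = 9)
    expect_identical(a@step, b@step)
    expect_identical(a@neuron, b@neuron)
    d <- simulateBranching(net$top, st, 500, seed = 10)
    expect_false(identical(a@neuron, d@neuron))
})

test_that("all named states hold the 1 Hz stationary rate", {
    net <- smallNetwork()
    n <- nrow(positions(net$top))
    for (name in c("poisson", "subcritical", "reverberating")) {
        st <- dynamicState(name)
        sim <- simulateBranching(net$top, st, 2e4 + 1000, seed = 21)
        sim <- discardBurnIn(sim, 1000)
        A <- activity(sim)
        tauSteps <- max(1, analyticTimescale(st@m, st@dt) / st@dt)
        nEff <- length(A) / (2 * tauSteps)  # effective independent samples
        se <- stats::sd(A) / sqrt(nEff) / (n * st@dt / 1000)
        expect_lt(abs(meanRate(sim) - 1), 3 * se + 0.02)
    }
})

test_that("AR(1) timescale estimator recovers its generator", {
    # generator slope e^(-2/19) -> tau = 19 ms
    A <- synthAR1Activity(2e5, tau = 19, dt = 2, drive = 5, seed = 4)
    tau <- estimateTimescale(A, dt = 2)
    expect_equal(as.numeric(tau), 19, tolerance = 0.02)
    expect_equal(attr(tau, "slope"), exp(-2 / 19), tolerance = 0.005)

    # white noise: no resolvable timescale
    B <- synthAR1Activity(1e5, tau = 0, dt = 2, drive = 5, seed = 5)
    tauB <- suppressWarnings(estimateTimescale(B, dt = 2))
    expect_lt(as.numeric(tauB), 1)

    expect_error(estimateTimescale(rep(3L, 100), dt = 2), "constant")
})

test_that("burn-in removal renumbers steps and conserves the tail", {
    r <- rasterFromSpikes(step = c(2, 5, 9), neuron = c(1, 2, 3),
                          nSteps = 10, nNeurons = 5)
    r2 <- discardBurnIn(r, 4)
    expect_equal(r2@nSteps, 6L)
    expect_identical(r2@step, c(1L, 5L))
    expect_identical(r2@neuron, c(2L, 3L))
    expect_identical(activity(r2), tabulate(c(1L, 5L), 6))
})

test_that("estimated timescale improves with compensation near criticality", {
    net <- smallNetwork()
    st <- dynamicState("reverberating")
    tauRef <- analyticTimescale(st@m, st@dt)
    sims <- lapply(c(TRUE, FALSE), function(comp) {
        sim <- simulateBranching(net$top, st, 3e4 + 1000, seed = 33,
                                 compensate = comp)
        estimateTimescale(discardBurnIn(sim, 1000))
    })
    errOn <- abs(as.numeric(sims[[1]]) - tauRef)
    errOff <- abs(as.numeric(sims[[2]]) - tauRef)
    expect_lt(errOn, errOff)
})
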