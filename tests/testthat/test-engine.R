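smallScenario <- function(seed = 1L) {
    referenceParams(latticeSide = 48L, ATarget = 25, pdeSubsteps = 64L,
                    seed = as.integer(seed))
}

test_that("a zero-length run returns the initial configuration only", {
    p <- smallScenario()
    run <- runSimulation(p, 4L, "regular", totalMcs = 0L, snapshotEvery = 10L)
    expect_equal(length(run@snapshots), 1L)
    expect_equal(run@state@mcs, 0L)
    expect_equal(sum(run@fields@s), 0)
})

test_that("identical seeds give bitwise-identical trajectories", {
    a <- runSimulation(smallScenario(7L), 4L, "semi_random", totalMcs = 15L)
    b <- runSimulation(smallScenario(7L), 4L, "semi_random", totalMcs = 15L)
    expect_identical(a@state@sigma, b@state@sigma)
    expect_identical(a@fields@b, b@fields@b)
})

test_that("a resumed run continues the uninterrupted trajectory exactly", {
    p <- smallScenario(3L)
    whole <- runSimulation(p, 4L, "regular", totalMcs = 20L)
    part <- runSimulation(p, 4L, "regular", totalMcs = 12L)
    part2 <- runSimulation(p, 4L, "regular", totalMcs = 8L,
                           state = part@state, fields = part@fields)
    expect_identical(part2@state@sigma, whole@state@sigma)
    expect_equal(part2@fields@s, whole@fields@s)
    expect_equal(part2@state@mcs, 20L)
})

test_that("replicate runs summarize reproducibly", {
    p <- smallScenario()
    one <- runRepetitions(p, 4L, "regular", totalMcs = 5L, seeds = 11L)
    expect_equal(nrow(one$records), 1L)
    expect_true(all(one$summary$sd == 0))
    three <- runRepetitions(p, 4L, "regular", totalMcs = 5L, seeds = 1:3)
    threeAgain <- runRepetitions(p, 4L, "regular", totalMcs = 5L, seeds = 1:3)
    expect_equal(three$summary, threeAgain$summary)
    expect_equal(nrow(three$records), 3L)
    expect_true(all(c("nLacunae", "coverage", "seed") %in%
                    names(three$records)))
})

test_that("dynamics tracking reports the coalescence observables", {
    p <- smallScenario(5L)
    run <- runSimulation(p, 4L, "regular", totalMcs = 30L,
                         snapshotEvery = 10L)
    dyn <- trackDynamics(run, cellLengthsAt = 30L)
    expect_equal(dyn$series$mcs, c(0L, 10L, 20L, 30L))
    # at MCS 0 every cell is its own isolated structure
    expect_equal(dyn$series$nComponents[1], 4L)
    expect_equal(length(dyn$cellLengths[["30"]]), 4L)
    expect_true(all(dyn$occupancy >= 0 & dyn$occupancy <= 1))
    # the occupancy map of a static trajectory is the mask itself
    frozen <- runSimulation(referenceParams(latticeSide = 48L, ATarget = 25,
                                            TFluct = 1e-9, Jcc = 0, Jcm = 0,
                                            muB = 0, muS = 0, muTotal = 0,
                                            lambdaArea = 1e6, seed = 1L),
                            4L, "regular", totalMcs = 4L, snapshotEvery = 2L)
    occ <- trackDynamics(frozen)$occupancy
    expect_equal(occ, (frozen@state@sigma > 0L) + 0)
})

test_that("closure detection reports the first closed checkpoint", {
    # a single cell driven to fill a tiny lattice closes within a few MCS
    p <- referenceParams(latticeSide = 8L, ATarget = 64, lambdaArea = 1e6,
                         TFluct = 1e-9, muB = 0, muS = 0, muTotal = 0,
                         seed = 1L)
    t <- networkClosureTime(p, 1L, maxMcs = 20L, checkEvery = 2L)
    expect_false(is.na(t))
    expect_true(t %% 2L == 0L && t <= 20L)
    # an empty lattice never closes
    expect_true(is.na(networkClosureTime(p, 0L, maxMcs = 4L,
                                         checkEvery = 2L)))
})
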