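test_that("component and lacuna counts match flood-fill and Euler oracles", {
    expect_equal(countComponents(matrix(0L, 10, 10)), 0L)
    two <- matrix(0L, 20, 20)
    two[2:5, 2:5] <- 1L; two[10:14, 10:14] <- 1L
    expect_equal(countComponents(two), 2L)
    expect_equal(countLacunae(matrix(1L, 10, 10)), 0L)
    ring <- primitivePattern("ring", side = 31L, radius = 10, thickness = 3)
    expect_equal(countComponents(ring), 1L)
    expect_equal(countLacunae(ring), 1L)
    # random masks: flood fill and Euler-characteristic equivalence
    set.seed(31)
    for (i in 1:30) {
        pat <- randomMask(40L, runif(1, 0.2, 0.8), smoothing = runif(1, 0, 2))
        m <- pat@mask
        expect_equal(countComponents(pat), max(floodLabelOracle(m, 8)))
        expect_equal(countComponents(pat) - countLacunae(pat),
                     eulerQuadOracle(m))
    }
})

test_that("border-touching background is not a lacuna unless requested", {
    m <- matrix(1L, 10, 10)
    m[1:3, 4:6] <- 0L       # bay open to the top border
    m[6:7, 6:7] <- 0L       # enclosed hole
    expect_equal(countLacunae(m), 1L)
    expect_equal(countLacunae(m, includeBorder = TRUE), 2L)
})

test_that("lacuna geometry follows the stated perimeter convention", {
    # square hole of side n: traced-contour roundness is exactly pi/4
    for (n in c(4L, 9L, 16L)) {
        m <- matrix(1L, n + 8L, n + 8L)
        m[5:(4 + n), 5:(4 + n)] <- 0L
        st <- lacunaStats(m)
        expect_equal(st$area, n^2)
        expect_equal(st$perimeter, 4 * (n - 1))
        expect_equal(st$roundness, pi / 4)
    }
    # a large disk-shaped lacuna is nearly round; the traced-contour
    # convention overestimates smooth perimeters by ~5% (chain-code bias),
    # so the oracle-derived value sits near 0.87, not at 1
    side <- 61L
    disk <- rasterDiskOracle(side, 22)
    st <- lacunaStats(1L - disk)
    expect_equal(st$area, sum(disk))
    expect_gt(st$roundness, 0.85)
    expect_lte(st$roundness, 1)
    # degenerate one-pixel lacuna keeps roundness in (0, 1]
    m1 <- matrix(1L, 7, 7); m1[4, 4] <- 0L
    st1 <- lacunaStats(m1)
    expect_equal(st1$roundness, pi / 4)
    expect_equal(lacunaStats(matrix(1L, 5, 5)),
                 data.frame(area = numeric(), perimeter = numeric(),
                            roundness = numeric()))
})

test_that("coverage is the foreground fraction", {
    expect_equal(coverage(matrix(0L, 8, 8)), 0)
    expect_equal(coverage(matrix(1L, 8, 8)), 1)
    half <- matrix(0L, 10, 10); half[, 1:5] <- 1L
    expect_equal(coverage(half), 0.5)
})

test_that("percolation needs one structure spanning both directions", {
    m <- matrix(0L, 20, 20)
    m[10, ] <- 1L                       # full-width horizontal bar only
    expect_false(isPercolative(m))
    m[, 10] <- 1L                       # cross it: now spans both
    expect_true(isPercolative(m))
    # disjoint structures that each span only one direction do not count
    m2 <- matrix(0L, 20, 20)
    m2[5, ] <- 1L                       # spans horizontally only
    m2[8:20, 15] <- 1L                  # vertical bar, does not reach the top
    expect_false(isPercolative(m2))
})

test_that("interface length counts 4-adjacent opposite pairs", {
    expect_equal(interfaceLength(matrix(1L, 9, 9)), 0)
    expect_equal(interfaceLength(matrix(0L, 9, 9)), 0)
    m <- matrix(0L, 20, 20)
    m[6:10, 6:10] <- 1L                 # interior 5x5 square: 4n = 20
    expect_equal(interfaceLength(m), 20)
    # brute-force pair scan on random masks
    set.seed(8)
    for (i in 1:10) {
        pat <- randomMask(25L, runif(1, 0.2, 0.8))
        m <- pat@mask
        cnt <- 0
        for (r in 1:25) for (cc in 1:25) {
            if (r < 25 && m[r, cc] != m[r + 1, cc]) cnt <- cnt + 1
            if (cc < 25 && m[r, cc] != m[r, cc + 1]) cnt <- cnt + 1
        }
        expect_equal(interfaceLength(pat), cnt)
    }
})

test_that("thinning preserves both Betti numbers and collapses bars", {
    bar <- primitivePattern("bar", side = 64L, width = 3L, length = 50L)
    sk <- skeletonize(bar)
    expect_true(abs(spanningLength(sk) - 50) <= 2)
    # a single pixel is its own skeleton
    px <- matrix(0L, 9, 9); px[5, 5] <- 1L
    expect_equal(skeletonize(px)@mask, px)
    fixtures <- list(
        gridNetwork(3L, 8L, 3L),
        gridNetwork(2L, 5L, 2L, margin = 4L),
        primitivePattern("ring", side = 41L, radius = 15, thickness = 5),
        primitivePattern("cross", side = 31L, arm = 5L),
        primitivePattern("disk", side = 41L, radius = 12))
    for (f in fixtures) {
        sk <- skeletonize(f)
        expect_equal(countComponents(sk), countComponents(f))
        expect_equal(countLacunae(sk), countLacunae(f))
    }
    set.seed(77)
    for (i in 1:20) {
        pat <- randomMask(50L, runif(1, 0.3, 0.7), smoothing = 1.5)
        sk <- skeletonize(pat)
        expect_equal(countComponents(sk), countComponents(pat))
        expect_equal(countLacunae(sk), countLacunae(pat))
    }
})

test_that("cord widths are the distance to the nearest avascular pixel", {
    bar7 <- primitivePattern("bar", side = 40L, width = 7L, length = 30L)
    w <- cordWidths(bar7)
    interior <- w[w == max(w)]
    expect_true(all(abs(interior - 3.5) <= 0.5))
    thin <- primitivePattern("bar", side = 20L, width = 1L, length = 10L)
    expect_true(all(cordWidths(thin) == 1))
    set.seed(3)
    expect_true(all(cordWidths(randomMask(40L, 0.5)) >= 1))
})

test_that("node graphs find and merge branch points correctly", {
    cross <- primitivePattern("cross", side = 31L, arm = 1L)
    g <- buildNodeGraph(skeletonize(cross), cross)
    expect_equal(nrow(g@nodes), 1L)
    expect_equal(g@nodes$degree, 4L)
    # Y junction: one degree-3 node
    y <- matrix(0L, 21, 21)
    y[11:20, 11] <- 1L                      # stem
    for (k in 0:9) {
        y[10 - k, 11 - k] <- 1L             # left arm
        y[10 - k, 11 + k] <- 1L             # right arm
    }
    gy <- buildNodeGraph(new("BinaryPattern", mask = y, pixelSize = 1))
    expect_equal(nrow(gy@nodes), 1L)
    expect_equal(gy@nodes$degree, 3L)
    # thick T junction: raw thinning yields adjacent branch pixels that the
    # width-aware merge must collapse to a single corrected node
    tt <- matrix(0L, 40, 40)
    tt[16:22, 4:36] <- 1L                   # thick horizontal bar
    tt[22:36, 17:23] <- 1L                  # thick vertical stem
    skt <- skeletonize(tt)
    gt <- buildNodeGraph(skt, new("BinaryPattern", mask = tt, pixelSize = 1))
    expect_equal(nrow(gt@nodes), 1L)
    # merging never yields more nodes than raw branch pixels
    expect_lte(nrow(gt@nodes), sum(gt@nodes$nRaw))
})

test_that("box-counting dimension hits the analytic limits", {
    line <- primitivePattern("bar", side = 64L, width = 1L, length = 64L)
    expect_lt(abs(fractalDimension(line) - 1), 0.1)
    expect_lt(abs(fractalDimension(matrix(1L, 64, 64)) - 2), 0.1)
    expect_error(fractalDimension(matrix(0L, 64, 64)), "occupied")
})

test_that("gliding-box lacunarity measures gappiness", {
    expect_equal(lacunarity(matrix(1L, 40, 40))$value, 1)
    spike <- matrix(0L, 100, 100); spike[50, 50] <- 1L
    lc <- lacunarity(spike)
    expect_gt(lc$curve$lambda[lc$curve$boxSize == 2], 10)
    set.seed(12)
    for (d in c(0.2, 0.5, 0.9)) {
        expect_gte(min(lacunarity(randomMask(50L, d))$curve$lambda,
                       na.rm = TRUE), 1)
    }
})

test_that("cell lengths follow the moment-equivalent ellipse", {
    p <- referenceParams(latticeSide = 64L, ATarget = 100)
    dIso <- isotropicDiameter(p)
    # 1 x n rod: L = 4 sqrt((n^2 - 1)/12), strictly increasing in n
    lens <- sapply(c(3L, 5L, 9L, 15L), function(n) {
        sig <- matrix(0L, 64, 64)
        sig[30, 10:(9 + n)] <- 1L
        st <- new("SimulationState", sigma = sig,
                  cells = data.frame(index = 1L, type = "angioblast",
                                     area = n),
                  mcs = 0L, pixelSize = 2)
        L <- cellLengths(st, p)[["1"]]
        expect_equal(L * dIso, 4 * sqrt((n^2 - 1) / 12), tolerance = 1e-10)
        L
    })
    expect_true(all(diff(lens) > 0))
    # a disk of the target area has normalized length ~ 1
    disk <- rasterDiskOracle(41L, sqrt(p@ATarget / pi))
    sig <- matrix(0L, 64, 64)
    sig[1:41, 1:41] <- disk
    st <- new("SimulationState", sigma = sig,
              cells = data.frame(index = 1L, type = "angioblast",
                                 area = sum(disk)),
              mcs = 0L, pixelSize = 2)
    expect_lt(abs(cellLengths(st, p)[["1"]] - 1), 0.05)
    # rotation by 90 degrees leaves the length unchanged
    sig2 <- matrix(0L, 64, 64)
    sig2[10:(9 + 7), 30] <- 1L
    st2 <- new("SimulationState", sigma = sig2,
               cells = data.frame(index = 1L, type = "angioblast", area = 7L),
               mcs = 0L, pixelSize = 2)
    sig3 <- t(sig2)
    st3 <- new("SimulationState", sigma = sig3,
               cells = data.frame(index = 1L, type = "angioblast", area = 7L),
               mcs = 0L, pixelSize = 2)
    expect_equal(cellLengths(st2, p), cellLengths(st3, p))
    # single-pixel cell has length one pixel
    sig4 <- matrix(0L, 64, 64); sig4[5, 5] <- 1L
    st4 <- new("SimulationState", sigma = sig4,
               cells = data.frame(index = 1L, type = "angioblast", area = 1L),
               mcs = 0L, pixelSize = 2)
    expect_equal(cellLengths(st4, p)[["1"]], 1 / dIso)
})

test_that("analyzePattern composes a consistent record", {
    pat <- gridNetwork(3L, 8L, 3L)
    rec <- analyzePattern(pat)
    expect_s4_class(rec, "MorphometricRecord")
    expect_equal(rec@nComponents, 1)
    expect_equal(rec@nLacunae, 9)
    expect_true(rec@percolative)
    expect_gte(rec@coverage, 0); expect_lte(rec@coverage, 1)
    expect_true(all(as.data.frame(rec)[
        c("nComponents", "nLacunae", "spanningLength", "nNodes",
          "interfaceLength")] >= 0))
    # idempotent on identical input
    rec2 <- analyzePattern(pat)
    expect_equal(as.data.frame(rec), as.data.frame(rec2))
})
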