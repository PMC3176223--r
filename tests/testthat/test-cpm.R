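test_that("Hamiltonian matches closed forms and the brute-force oracle", {
    p <- tinyParams()
    L <- p@latticeSide
    empty <- initializeCells(0L, "regular", p)
    expect_equal(cpmHamiltonian(empty, p), 0)
    # one 3x3 cell at exactly target area: only cell-medium interfaces
    st <- initializeCells(1L, "regular", p)     # ATarget = 9 -> 3x3 patch
    expect_equal(st@cells$area, 9L)
    expect_equal(cpmHamiltonian(st, p), bruteHamiltonian(st, p))
    # the area term is zero, so H is Jcm times the interface pair count
    expect_equal(cpmHamiltonian(st, p) %% p@Jcm, 0)
    # roughened multi-cell states against exhaustive enumeration
    for (sd in 1:3) {
        rs <- roughState(seed = sd, mcs = 10L)
        expect_equal(cpmHamiltonian(rs$state, rs$params),
                     bruteHamiltonian(rs$state, rs$params))
    }
})

test_that("local energy change equals the full Hamiltonian difference", {
    rs <- roughState(seed = 2, mcs = 10L)
    st <- rs$state; f <- rs$fields; p <- rs$params
    L <- p@latticeSide
    offs <- vasculogen:::cpm_neighborhood(p@copyOrder)
    set.seed(99)
    tested <- 0
    worst <- 0
    while (tested < 1000) {
        tg <- c(sample.int(L, 1), sample.int(L, 1))
        k <- sample.int(nrow(offs), 1)
        src <- tg + offs[k, ]
        if (any(src < 1 | src > L)) next
        if (st@sigma[tg[1], tg[2]] == st@sigma[src[1], src[2]]) next
        att <- copyAttempt(src, tg, st, p)
        dh <- cpmDeltaH(st, f, att, p)
        st2 <- st
        from <- att$targetIndex; to <- att$sourceIndex
        st2@sigma[tg[1], tg[2]] <- to
        cells <- st2@cells
        if (from > 0) cells$area[cells$index == from] <-
            cells$area[cells$index == from] - 1L
        if (to > 0) cells$area[cells$index == to] <-
            cells$area[cells$index == to] + 1L
        st2@cells <- cells
        chem <- -p@muB * (f@b[tg[1], tg[2]] - f@b[src[1], src[2]]) -
            p@muS * (f@s[tg[1], tg[2]] - f@s[src[1], src[2]])
        ref <- bruteHamiltonian(st2, p) - bruteHamiltonian(st, p) + chem
        worst <- max(worst, abs(dh - ref))
        tested <- tested + 1
    }
    expect_lt(worst, 1e-9)
})

test_that("uniform fields contribute no chemotaxis and the formula is exact", {
    rs <- roughState(seed = 4)
    p <- rs$params; st <- rs$state
    L <- p@latticeSide
    fUnif <- new("FieldState", s = matrix(2, L, L), e = matrix(0, L, L),
                 b = matrix(7, L, L))
    fZero <- emptyFields(p)
    att <- NULL
    offs <- vasculogen:::cpm_neighborhood(p@copyOrder)
    set.seed(1)
    repeat {
        tg <- c(sample.int(L, 1), sample.int(L, 1))
        src <- tg + offs[sample.int(nrow(offs), 1), ]
        if (all(src >= 1 & src <= L) &&
            st@sigma[tg[1], tg[2]] != st@sigma[src[1], src[2]]) {
            att <- copyAttempt(src, tg, st, p)
            break
        }
    }
    expect_equal(cpmDeltaH(st, fUnif, att, p), cpmDeltaH(st, fZero, att, p))
    # direct formula: muS = 0, b(target) - b(source) = 2, muB = 5 -> -10
    p2 <- referenceParams(latticeSide = L, ATarget = 9, muB = 5, muS = 0,
                          muTotal = 5)
    fb <- emptyFields(p2)
    fb@b[att$target[1], att$target[2]] <- 2.5
    fb@b[att$source[1], att$source[2]] <- 0.5
    expect_equal(cpmDeltaH(st, fb, att, p2) - cpmDeltaH(st, fZero, att, p2),
                 -10)
})

test_that("acceptance probability follows the Metropolis closed form", {
    expect_equal(acceptanceProbability(-5, 25), 1)
    expect_equal(acceptanceProbability(0, 25), 1)
    expect_equal(acceptanceProbability(25, 25), exp(-1))
    expect_equal(acceptanceProbability(c(-1, 0, 10), 5),
                 c(1, 1, exp(-2)))
    # zero-temperature limit: accept iff dH <= 0
    expect_equal(acceptanceProbability(c(-1, 0, 1e-9), 0), c(1, 1, 0))
    expect_error(acceptanceProbability(1, -1), ">= 0")
    # monotone in T for energy-raising moves
    Ts <- c(1, 5, 25, 125)
    expect_true(all(diff(acceptanceProbability(10, Ts)) > 0))
})

test_that("areas stay exact under Monte Carlo dynamics", {
    p <- referenceParams(latticeSide = 40L, ATarget = 25, seed = 8L)
    set.seed(p@seed)
    st <- initializeCells(6L, "regular", p)
    f <- emptyFields(p)
    f@b <- matrix(runif(1600), 40)
    st2 <- monteCarloStep(st, f, p, 50L)
    recount <- tabulate(st2@sigma[st2@sigma > 0L], nbins = 6L)
    expect_identical(as.integer(st2@cells$area), as.integer(recount))
    expect_equal(st2@mcs, 50L)
    # cell count is conserved: every index retains at least one pixel
    expect_true(all(recount >= 1L))
})

test_that("dynamics are deterministic given the seed", {
    p <- referenceParams(latticeSide = 32L, ATarget = 16, seed = 5L)
    runTwice <- function() {
        set.seed(p@seed)
        st <- initializeCells(4L, "regular", p)
        f <- emptyFields(p)
        monteCarloStep(st, f, p, 20L)@sigma
    }
    expect_identical(runTwice(), runTwice())
})

test_that("a stiff area constraint pins areas near target", {
    # no adhesion, no chemotaxis, huge lambda: area-changing flips are rare
    p <- referenceParams(latticeSide = 32L, ATarget = 16, Jcc = 0, Jcm = 0,
                         muB = 0, muS = 0, muTotal = 0, lambdaArea = 1e4,
                         seed = 2L)
    set.seed(p@seed)
    st <- initializeCells(4L, "regular", p)
    f <- emptyFields(p)
    st <- monteCarloStep(st, f, p, 100L)
    expect_true(all(abs(st@cells$area - p@ATarget) <= 2))
})

test_that("cells remain connected subdomains under dynamics", {
    p <- referenceParams(latticeSide = 40L, ATarget = 25, seed = 3L)
    set.seed(p@seed)
    st <- initializeCells(6L, "semi_random", p)
    f <- emptyFields(p)
    f@b <- matrix(runif(1600), 40)     # strong random chemotaxis noise
    st <- monteCarloStep(st, f, p, 60L)
    for (i in st@cells$index) {
        m <- matrix(as.integer(st@sigma == i), 40)
        expect_equal(max(floodLabelOracle(m, 8)), 1L)
    }
})
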