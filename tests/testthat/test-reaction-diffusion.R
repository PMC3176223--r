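test_that("reaction step reproduces the forced limits", {
    p <- tinyParams(alphaE = 0)
    f <- emptyFields(p)
    mask <- matrix(0L, 24, 24)
    out <- reactionStep(f, mask, p, dt = 0.01)
    # from zero fields with no matrix production: s = alphaV*dt uniformly
    expect_equal(out@s, matrix(p@alphaV * 0.01, 24, 24))
    expect_true(all(out@e == 0) && all(out@b == 0))
    expect_error(reactionStep(f, mask, p, dt = 0), "> 0")
})

test_that("binding conserves s + b when production and decay are off", {
    p <- tinyParams(alphaV = 0, alphaE = 0, gammaS = 0, kBind = 1)
    f <- new("FieldState", s = matrix(1, 24, 24), e = matrix(1, 24, 24),
             b = matrix(0, 24, 24))
    out <- reactionStep(f, matrix(1L, 24, 24), p, dt = 0.01)
    expect_equal(sum(out@s) + sum(out@b), sum(f@s) + sum(f@b))
    # and over many full MCS through the integrator, with diffusion on
    set.seed(5)
    f2 <- new("FieldState", s = matrix(runif(576), 24),
              e = matrix(runif(576), 24), b = matrix(0, 24, 24))
    tot0 <- sum(f2@s) + sum(f2@b)
    mask <- matrix(as.integer(runif(576) < 0.3), 24)
    for (t in 1:100) f2 <- integrateFields(f2, mask, p, 1, "normal")
    expect_lt(abs(sum(f2@s) + sum(f2@b) - tot0) / tot0, 1e-8)
})

test_that("mass-action kinetics match an adaptive ODE oracle", {
    skip_if_not_installed("deSolve")
    p <- tinyParams(alphaV = 0, alphaE = 0, gammaS = 0, kBind = 0.5,
                    D = 0, pdeSubsteps = 10000L)
    f <- new("FieldState", s = matrix(1, 2, 2), e = matrix(2, 2, 2),
             b = matrix(0, 2, 2))
    out <- integrateFields(f, matrix(0L, 2, 2), p, duration = 1,
                           mode = "no_diffusion")
    ode <- deSolve::lsoda(
        c(s = 1, e = 2, b = 0), times = c(0, 1),
        function(t, y, parms) {
            r <- 0.5 * y["s"] * y["e"]
            list(c(-r, -r, r))
        }, parms = NULL, rtol = 1e-10, atol = 1e-12)
    expect_lt(abs(out@s[1, 1] - ode[2, "s"]) / ode[2, "s"], 1e-3)
    expect_lt(abs(out@b[1, 1] - ode[2, "b"]) / ode[2, "b"], 1e-3)
})

test_that("diffusion conserves mass, fixes constants and decays eigenmodes", {
    p <- referenceParams(latticeSide = 64L, D = 50)
    u <- matrix(3.7, 64, 64)
    expect_equal(diffusionStep(u, p, 0.01), u)    # constant field unchanged
    set.seed(9)
    v <- matrix(runif(64 * 64), 64)
    w <- diffusionStep(v, p, 0.015)
    expect_lt(abs(sum(w) - sum(v)) / sum(v), 1e-10)
    expect_error(diffusionStep(v, p, 1), "unstable")
    # cosine eigenmode of the zero-flux Laplacian decays like exp(-D q^2 t)
    L <- 64; h <- p@pixelSize; dt <- 0.01; nstep <- 100
    mode <- cos(pi * (seq_len(L) - 0.5) / L)
    grid <- matrix(mode, L, L)
    for (i in seq_len(nstep)) grid <- diffusionStep(grid, p, dt)
    amp <- sum(grid[, 1] * mode) / sum(mode^2)
    expect_lt(abs(amp / exp(-p@D * (pi / (L * h))^2 * dt * nstep) - 1), 0.01)
})

test_that("well-mix homogenizes while preserving the total", {
    u <- matrix(0, 10, 10); u[4, 7] <- 5
    v <- wellMix(u)
    expect_equal(unique(as.vector(v)), 0.05)
    expect_equal(sum(v), sum(u))
    expect_equal(wellMix(v), v)
})

test_that("field integration modes behave as defined", {
    p0 <- tinyParams(D = 0, pdeSubsteps = 8L)
    pD <- tinyParams(D = 50, pdeSubsteps = 64L)
    set.seed(11)
    mask <- matrix(as.integer(runif(576) < 0.4), 24)
    f <- emptyFields(p0)
    f@s <- matrix(runif(576), 24)
    # no_diffusion is identical to normal with D = 0
    a <- integrateFields(f, mask, p0, 1, "normal")
    b <- integrateFields(f, mask, p0, 1, "no_diffusion")
    expect_equal(a@s, b@s); expect_equal(a@e, b@e); expect_equal(a@b, b@b)
    # well_mixed leaves s spatially uniform after every MCS
    w <- integrateFields(f, mask, pD, 1, "well_mixed")
    expect_lt(diff(range(w@s)), 1e-12)
    # b is pointwise non-decreasing and e grows only inside the mask
    f2 <- emptyFields(pD)
    prevB <- f2@b
    for (t in 1:100) {
        f2 <- integrateFields(f2, mask, pD, 1, "normal")
        expect_true(all(f2@b >= prevB))
        prevB <- f2@b
    }
    expect_true(all(f2@e[mask == 0L] == 0))
    expect_true(all(f2@e[mask == 1L] > 0))
    expect_true(min(f2@s) >= 0 && min(f2@e) >= 0 && min(f2@b) >= 0)
})
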