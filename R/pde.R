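#' One reaction substep of the VEGF/matrix kinetics
#'
#' Pointwise forward-Euler update of the mass-action system: soluble VEGF is
#' produced uniformly at rate `alphaV`, degraded at rate `gammaS`, and binds
#' free matrix sites with second-order rate `kBind`; free binding sites are
#' produced at rate `alphaE` inside cells only; bound VEGF accumulates and
#' is never removed. Negative excursions are clipped to zero with a warning
#' (they cannot occur at a stable substep size).
#'
#' @param fields a [FieldState-class].
#' @param mask a [BinaryPattern-class] (or 0/1 matrix) marking cell sites.
#' @param params a [ModelParams-class].
#' @param dt substep length, s. Must satisfy the positivity heuristic
#'   `dt * kBind * max(e) < 1`.
#' @return updated [FieldState-class].
#' @export
reactionStep <- function(fields, mask, params, dt) {
    m <- asMaskMatrix(mask)
    if (dt <= 0) stop("'dt' must be > 0")
    if (dt * params@kBind * max(fields@e) >= 1)
        stop("reaction substep too large for positivity: increase pdeSubsteps")
    out <- pde_integrate_cpp(fields@s, fields@e, fields@b, m,
                             params@alphaV, params@alphaE, params@kBind,
                             params@gammaS, 0, params@pixelSize^2, dt,
                             1L, 1L)
    if (out$clipped > 0)
        warning(sprintf("%d negative field excursions clipped to 0",
                        out$clipped))
    new("FieldState", s = out$s, e = out$e, b = out$b)
}

#' One diffusion substep of the soluble field
#'
#' 5-point finite-difference Laplacian, forward Euler, with zero-flux
#' (reflecting) boundaries; total mass is conserved to rounding error.
#'
#' @param grid numeric matrix (the soluble VEGF concentration).
#' @param params a [ModelParams-class] (supplies `D` and `pixelSize`).
#' @param dt substep length, s; must satisfy `dt <= pixelSize^2/(4 D)`.
#' @return the diffused matrix.
#' @export
diffusionStep <- function(grid, params, dt) {
    if (params@D > 0) {
        bound <- params@pixelSize^2 / (4 * params@D)
        if (dt > bound * (1 + 1e-12))
            stop(sprintf(
                "diffusion substep dt = %.4g s unstable (bound %.4g s); use pdeSubsteps >= %d",
                dt, bound, ceiling(params@mcsSeconds / bound)))
    }
    pde_diffuse_cpp(grid, params@D, params@pixelSize^2, dt)
}

#' Homogenize a field over the lattice
#'
#' Sets every site to the grid mean, preserving total mass exactly. Used by
#' the well-mixed transport mode of the diffusivity analysis.
#'
#' @param grid numeric matrix.
#' @return matrix with every entry equal to `mean(grid)`.
#' @export
wellMix <- function(grid) {
    matrix(mean(grid), nrow(grid), ncol(grid))
}

#' Integrate the fields over one Monte Carlo step
#'
#' Performs `pdeSubsteps` operator-split substeps over `duration` seconds.
#' Transport of the soluble field depends on `mode`: `"normal"` alternates
#' reaction and diffusion, `"no_diffusion"` performs reaction only, and
#' `"well_mixed"` redistributes soluble VEGF homogeneously after every
#' reaction substep.
#'
#' @inheritParams reactionStep
#' @param duration integration time, s (one MCS worth).
#' @param mode `"normal"`, `"no_diffusion"` or `"well_mixed"`.
#' @return updated [FieldState-class].
#' @examples
#' p <- referenceParams(latticeSide = 16L)
#' st <- initializeCells(1L, "regular", p)
#' f <- integrateFields(emptyFields(p), cellMask(st), p, 1)
#' sum(f@s) > 0
#' @export
integrateFields <- function(fields, mask, params, duration = params@mcsSeconds,
                            mode = c("normal", "no_diffusion", "well_mixed")) {
    mode <- match.arg(mode)
    m <- asMaskMatrix(mask)
    nsub <- params@pdeSubsteps
    dt <- duration / nsub
    if (dt * params@kBind * max(fields@e) >= 1)
        stop("reaction substep too large for positivity: increase pdeSubsteps")
    if (mode == "normal" && params@D > 0) {
        bound <- params@pixelSize^2 / (4 * params@D)
        if (dt > bound * (1 + 1e-12))
            stop(sprintf(
                "diffusion substep dt = %.4g s unstable (bound %.4g s); use pdeSubsteps >= %d",
                dt, bound, ceiling(duration / bound)))
    }
    modeCode <- c(normal = 0L, no_diffusion = 1L, well_mixed = 2L)[[mode]]
    out <- pde_integrate_cpp(fields@s, fields@e, fields@b, m,
                             params@alphaV, params@alphaE, params@kBind,
                             params@gammaS, params@D, params@pixelSize^2,
                             dt, nsub, modeCode)
    if (out$clipped > 0)
        warning(sprintf("%d negative field excursions clipped to 0",
                        out$clipped))
    new("FieldState", s = out$s, e = out$e, b = out$b)
}

# Accept a BinaryPattern, logical or numeric 0/1 matrix as a mask.
asMaskMatrix <- function(mask) {
    if (is(mask, "BinaryPattern")) return(mask@mask)
    if (is.logical(mask)) return(matrix(as.integer(mask), nrow(mask)))
    if (is.numeric(mask)) {
        m <- matrix(as.integer(mask != 0), nrow(mask))
        return(m)
    }
    stop("mask must be a BinaryPattern or a 0/1 matrix")
}
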