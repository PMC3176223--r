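#' Reference model parameters
#'
#' Returns the reference parameter set used throughout the package, with any
#' number of named overrides. The cellular Potts energies follow the
#' conventions of the published Potts models of vascular patterning
#' (fluctuation energy 25, cell-cell binding energy 40 with the cell-medium
#' energy at half that value so the cell-medium surface tension
#' Jcm - Jcc/2 vanishes, area stiffness 25). The chemotaxis budget is split
#' 80/20 between bound and soluble VEGF, reflecting the stronger signalling
#' of the matrix-anchored form. The reaction rates are set so that binding
#' is fast relative to production on the one-hour timescale of the
#' simulation, and the diffusion coefficient is at the literature scale for
#' soluble VEGF isoforms in tissue (tens of um^2/s). See the package
#' vignette for the full rationale of every value.
#'
#' @param ... named overrides of any [ModelParams-class] slot, e.g.
#'   `latticeSide = 200`, `muB = 500`.
#' @return a validated [ModelParams-class] object.
#' @examples
#' p <- referenceParams(latticeSide = 100L, seed = 7L)
#' p@ATarget
#' @export
referenceParams <- function(...) {
    defaults <- list(
        D = 50,            # um^2/s
        alphaV = 1e-3,     # a.u./s, uniform paracrine source
        alphaE = 1e-3,     # a.u./s, inside cells only
        kBind = 0.5,       # 1/(a.u. s): binding fast vs production
        gammaS = 3e-4,     # 1/s (soluble half-life ~ 40 min)
        TFluct = 35,
        ATarget = 100,     # px (400 um^2 at 2 um/px; spread angioblast)
        lambdaArea = 25,
        Jcc = 40,
        Jcm = 20,          # = Jcc/2: zero cell-medium surface tension
        muTotal = 1000,
        muB = 800,
        muS = 200,
        neighborOrder = 2L,
        copyOrder = 2L,
        latticeSide = 400L,
        pixelSize = 2,     # um
        mcsSeconds = 1,
        pdeSubsteps = 64L, # dt = 1/64 s <= pixelSize^2/(4 D) = 0.02 s
        seed = 1L
    )
    over <- list(...)
    bad <- setdiff(names(over), names(defaults))
    if (length(bad))
        stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    defaults[names(over)] <- over
    ints <- c("neighborOrder", "copyOrder", "latticeSide", "pdeSubsteps",
              "seed")
    for (nm in ints) defaults[[nm]] <- as.integer(defaults[[nm]])
    do.call(new, c(list("ModelParams"), defaults))
}

#' Scenario presets
#'
#' Named simulation scenarios bundling parameters with a cell count, initial
#' mesh and run length:
#' \describe{
#'   \item{reference}{400 x 400 lattice (800 x 800 um), 1100 cells
#'     (~1720 cells/mm^2, the density measured in embryo micrographs),
#'     3000 MCS. The headline network-formation scenario.}
#'   \item{dynamics}{as `reference` but 800 cells (1250 cells/mm^2), the
#'     constant population used to study formation dynamics.}
#'   \item{reference-scaled}{200 x 200 lattice with density-matched 275
#'     cells, 1500 MCS; quarter-domain preset for desk-scale work.}
#'   \item{dynamics-scaled}{200 x 200 lattice, 200 cells, 1500 MCS;
#'     density-matched scaling of `dynamics`.}
#'   \item{sweep-scaled}{200 x 200 lattice, 200 cells, 1500 MCS; the
#'     preset used by the parameter sweeps. Its cell count matches the
#'     coverage (~0.5) of the published reference morphology rather than
#'     the nominal reference cell count, which matters because coverage,
#'     not count, controls how lacunae respond to signalling
#'     perturbations; the quarter-domain develops ~20 distinct lacunae,
#'     enough for replicate statistics.}
#' }
#'
#' @param name one of the preset names above.
#' @param ... parameter overrides forwarded to [referenceParams()].
#' @return list with elements `params`, `nCells`, `initMode`, `totalMcs`.
#' @examples
#' sc <- scenarioPreset("sweep-scaled", seed = 3L)
#' sc$nCells
#' @export
scenarioPreset <- function(name = c("reference", "dynamics",
                                    "reference-scaled", "dynamics-scaled",
                                    "sweep-scaled"), ...) {
    name <- match.arg(name)
    spec <- switch(name,
        "reference"        = list(side = 400L, cells = 1100L, mcs = 3000L),
        "dynamics"         = list(side = 400L, cells = 800L,  mcs = 3000L),
        "reference-scaled" = list(side = 200L, cells = 275L,  mcs = 1500L),
        "dynamics-scaled"  = list(side = 200L, cells = 200L,  mcs = 1500L),
        "sweep-scaled"     = list(side = 200L, cells = 200L,  mcs = 1500L))
    over <- list(...)
    if (is.null(over$latticeSide)) over$latticeSide <- spec$side
    params <- do.call(referenceParams, over)
    list(params = params, nCells = spec$cells, initMode = "regular",
         totalMcs = spec$mcs)
}

#' @describeIn referenceParams isotropic cell diameter 2 sqrt(ATarget/pi)
#'   implied by the target area, in pixels.
#' @param params a [ModelParams-class] object.
#' @export
isotropicDiameter <- function(params) {
    2 * sqrt(params@ATarget / pi)
}

setMethod("show", "ModelParams", function(object) {
    cat("ModelParams\n")
    cat(sprintf("  lattice %d px (%.0f um/px), %g s/MCS, %d PDE substeps\n",
                object@latticeSide, object@pixelSize, object@mcsSeconds,
                object@pdeSubsteps))
    cat(sprintf("  PDE: D=%g alphaV=%g alphaE=%g kBind=%g gammaS=%g\n",
                object@D, object@alphaV, object@alphaE, object@kBind,
                object@gammaS))
    cat(sprintf("  CPM: T=%g A=%g lambda=%g Jcc=%g Jcm=%g order=%d\n",
                object@TFluct, object@ATarget, object@lambdaArea,
                object@Jcc, object@Jcm, object@neighborOrder))
    cat(sprintf("  chemotaxis: muB=%g muS=%g (total %g); seed %d\n",
                object@muB, object@muS, object@muTotal, object@seed))
})

setMethod("show", "SimulationState", function(object) {
    cat(sprintf("SimulationState: %d x %d lattice, %d cells, %d MCS elapsed\n",
                nrow(object@sigma), ncol(object@sigma), nrow(object@cells),
                object@mcs))
})

setMethod("show", "FieldState", function(object) {
    cat(sprintf(
        "FieldState %d x %d: total s=%.4g, e=%.4g, b=%.4g\n",
        nrow(object@s), ncol(object@s), sum(object@s), sum(object@e),
        sum(object@b)))
})

setMethod("show", "BinaryPattern", function(object) {
    cat(sprintf("BinaryPattern %d x %d (%.2g um/px), coverage %.3f\n",
                nrow(object@mask), ncol(object@mask), object@pixelSize,
                mean(object@mask)))
})

setMethod("show", "SimulationRun", function(object) {
    cat(sprintf(
        "SimulationRun: %d cells (%s mesh), %d MCS, field mode '%s', %d snapshots\n",
        object@nCells, object@initMode, object@state@mcs, object@fieldMode,
        length(object@snapshots)))
})
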