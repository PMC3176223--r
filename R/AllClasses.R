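#' Model parameters for the coupled Potts/reaction-diffusion model
#'
#' Holds every constant of the simulation: the reaction-diffusion rates of
#' the VEGF/matrix fields, the cellular Potts energies, and the lattice and
#' scheduling geometry. Rates are in units of concentration (arbitrary
#' units, a.u.) and seconds; lengths in lattice pixels unless stated.
#'
#' @slot D VEGF diffusion coefficient, um^2/s. Only the soluble field
#'   diffuses.
#' @slot alphaV soluble VEGF production rate, a.u./s, applied uniformly over
#'   the whole domain (paracrine source in the adjacent tissue layer).
#' @slot alphaE matrix binding-site production rate, a.u./s, applied only at
#'   cell-occupied sites.
#' @slot kBind second-order binding rate for soluble VEGF + free site ->
#'   bound VEGF, 1/(a.u. s).
#' @slot gammaS degradation rate of soluble VEGF, 1/s. Bound VEGF is never
#'   degraded.
#' @slot TFluct fluctuation energy (cell-motility analogue of temperature).
#' @slot ATarget cell target area, pixels.
#' @slot lambdaArea area-constraint stiffness, energy/pixel^2.
#' @slot Jcc cell-cell boundary binding energy per neighbor interface.
#' @slot Jcm cell-medium boundary binding energy per neighbor interface.
#' @slot muTotal total chemotaxis strength, energy per unit concentration.
#' @slot muB,muS chemotaxis strengths toward bound and soluble VEGF;
#'   muB + muS must equal muTotal.
#' @slot neighborOrder neighborhood order for boundary-energy sums
#'   (1 = von Neumann, 2 = Moore, up to 4).
#' @slot copyOrder neighborhood order from which copy attempts draw their
#'   source site; defaults to `neighborOrder`.
#' @slot latticeSide lattice side length, pixels (>= 8).
#' @slot pixelSize physical side length of one lattice site, um.
#' @slot mcsSeconds physical seconds represented by one Monte Carlo step.
#' @slot pdeSubsteps number of PDE integration substeps per MCS; the substep
#'   dt = mcsSeconds/pdeSubsteps must satisfy the explicit-diffusion
#'   stability bound dt <= pixelSize^2/(4 D).
#' @slot seed RNG seed used by [runSimulation()].
#'
#' @seealso [referenceParams()] for the documented defaults.
#' @export
setClass("ModelParams", representation(
    D = "numeric", alphaV = "numeric", alphaE = "numeric",
    kBind = "numeric", gammaS = "numeric",
    TFluct = "numeric", ATarget = "numeric", lambdaArea = "numeric",
    Jcc = "numeric", Jcm = "numeric",
    muTotal = "numeric", muB = "numeric", muS = "numeric",
    neighborOrder = "integer", copyOrder = "integer",
    latticeSide = "integer", pixelSize = "numeric",
    mcsSeconds = "numeric", pdeSubsteps = "integer", seed = "integer"
))

setValidity("ModelParams", function(object) {
    msg <- character()
    nonneg <- c("D", "alphaV", "alphaE", "kBind", "gammaS", "TFluct",
                "ATarget", "lambdaArea")
    for (nm in nonneg) {
        if (length(slot(object, nm)) != 1 || is.na(slot(object, nm)) ||
            slot(object, nm) < 0) {
            msg <- c(msg, sprintf("'%s' must be a single value >= 0", nm))
        }
    }
    if (object@latticeSide < 8L)
        msg <- c(msg, "'latticeSide' must be >= 8")
    if (object@pixelSize <= 0)
        msg <- c(msg, "'pixelSize' must be > 0")
    if (object@mcsSeconds <= 0 || object@pdeSubsteps < 1L)
        msg <- c(msg, "'mcsSeconds' must be > 0 and 'pdeSubsteps' >= 1")
    if (abs(object@muB + object@muS - object@muTotal) >
        1e-8 * max(1, abs(object@muTotal)))
        msg <- c(msg, "muB + muS must equal muTotal")
    if (!object@neighborOrder %in% 1:4 || !object@copyOrder %in% 1:4)
        msg <- c(msg, "'neighborOrder' and 'copyOrder' must be in 1..4")
    if (object@D > 0) {
        dt <- object@mcsSeconds / object@pdeSubsteps
        bound <- object@pixelSize^2 / (4 * object@D)
        if (dt > bound * (1 + 1e-12)) {
            msg <- c(msg, sprintf(
                "PDE substep dt = %.4g s violates the diffusion stability bound %.4g s; use pdeSubsteps >= %d",
                dt, bound, ceiling(object@mcsSeconds / bound)))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Cellular Potts configuration
#'
#' The lattice of cell indices plus per-cell bookkeeping. Index 0 is the
#' medium; indices 1..N label cells. `cells$area` is maintained
#' incrementally by the Monte Carlo kernel and always equals the exact count
#' of lattice sites carrying that index.
#'
#' @slot sigma integer matrix, latticeSide x latticeSide, of cell indices.
#' @slot cells data.frame with columns `index`, `type` (always
#'   "angioblast") and `area` (pixels).
#' @slot mcs integer, Monte Carlo steps elapsed.
#' @slot pixelSize physical pixel size, um (carried for mask export).
#' @export
setClass("SimulationState", representation(
    sigma = "matrix", cells = "data.frame", mcs = "integer",
    pixelSize = "numeric"
))

setValidity("SimulationState", function(object) {
    msg <- character()
    if (!is.integer(object@sigma))
        msg <- c(msg, "'sigma' must be an integer matrix")
    idx <- sort(unique(as.vector(object@sigma)))
    idx <- idx[idx > 0L]
    if (!all(idx %in% object@cells$index))
        msg <- c(msg, "every cell index in sigma must have a record in 'cells'")
    if (nrow(object@cells)) {
        recount <- tabulate(object@sigma[object@sigma > 0L],
                            nbins = max(object@cells$index))
        if (!identical(as.integer(object@cells$area),
                       as.integer(recount[object@cells$index])))
            msg <- c(msg, "'cells$area' disagrees with a recount of sigma")
    }
    if (length(msg)) msg else TRUE
})

#' Reaction-diffusion field state
#'
#' Three co-registered non-negative concentration grids: soluble VEGF `s`,
#' free matrix binding sites `e`, and matrix-bound VEGF `b`.
#'
#' @slot s,e,b numeric matrices of identical dimension.
#' @export
setClass("FieldState", representation(
    s = "matrix", e = "matrix", b = "matrix"
))

setValidity("FieldState", function(object) {
    msg <- character()
    if (!identical(dim(object@s), dim(object@e)) ||
        !identical(dim(object@s), dim(object@b)))
        msg <- c(msg, "'s', 'e' and 'b' must share dimensions")
    if (min(object@s) < 0 || min(object@e) < 0 || min(object@b) < 0)
        msg <- c(msg, "fields must be non-negative everywhere")
    if (length(msg)) msg else TRUE
})

#' Binary vascular pattern
#'
#' A 2D binary raster in which vascular (cell-covered) pixels are 1 and
#' avascular pixels (medium, lacunae) are 0, together with the physical
#' pixel size. This is the common input of the morphometric suite, whether
#' it came from the simulator ([cellMask()]) or from a segmented micrograph
#' ([readMask()]).
#'
#' @slot mask integer matrix of 0/1 values.
#' @slot pixelSize physical pixel side length, um.
#' @export
setClass("BinaryPattern", representation(
    mask = "matrix", pixelSize = "numeric"
))

setValidity("BinaryPattern", function(object) {
    msg <- character()
    if (!is.integer(object@mask))
        msg <- c(msg, "'mask' must be an integer matrix")
    if (length(object@mask) && !all(object@mask %in% c(0L, 1L)))
        msg <- c(msg, "'mask' values must be 0 or 1")
    if (object@pixelSize <= 0)
        msg <- c(msg, "'pixelSize' must be > 0")
    if (length(msg)) msg else TRUE
})

#' Skeleton graph of a thinned vascular network
#'
#' Nodes are merge-corrected branch points of the skeleton; edges are traced
#' skeleton segments between junctions/endpoints that survive node merging.
#'
#' @slot skeleton integer 0/1 matrix, the thinned pattern.
#' @slot nodes data.frame: `id`, `row`, `col` (centroid of merged raw branch
#'   pixels), `degree`, `width` (local half-width, px), `nRaw` (raw branch
#'   pixels merged into the node).
#' @slot edges data.frame: `from`, `to` (node ids; NA for endpoint-terminated
#'   segments), `length` (traced path length, px).
#' @export
setClass("SkeletonGraph", representation(
    skeleton = "matrix", nodes = "data.frame", edges = "data.frame"
))

#' Morphometric feature record of a binary vascular pattern
#'
#' @slot nComponents number of 8-connected vascular components (Betti 0).
#' @slot nLacunae number of enclosed avascular holes (Betti 1).
#' @slot lacunae data.frame with per-lacuna `area` (px), `perimeter` (px) and
#'   `roundness` (isoperimetric quotient in (0, 1]).
#' @slot coverage fraction of vascular pixels.
#' @slot percolative TRUE when one vascular component spans the image both
#'   horizontally and vertically.
#' @slot spanningLength pixel count of the thinned network.
#' @slot cordWidths per-skeleton-pixel Euclidean distance to the nearest
#'   avascular pixel (half cord width), px.
#' @slot nNodes merge-corrected branch point count.
#' @slot degrees node degree per corrected node.
#' @slot interfaceLength count of 4-adjacent vascular/avascular pixel pairs.
#' @slot fractalDimension box-counting dimension (of the skeleton by
#'   default).
#' @slot lacunarity gliding-box lacunarity averaged over the box series.
#' @slot lacunarityCurve data.frame `boxSize`, `lambda`.
#' @slot pixelSize um per pixel.
#' @export
setClass("MorphometricRecord", representation(
    nComponents = "numeric", nLacunae = "numeric", lacunae = "data.frame",
    coverage = "numeric", percolative = "logical",
    spanningLength = "numeric", cordWidths = "numeric",
    nNodes = "numeric", degrees = "numeric",
    interfaceLength = "numeric", fractalDimension = "numeric",
    lacunarity = "numeric", lacunarityCurve = "data.frame",
    pixelSize = "numeric"
))

#' A completed simulation run
#'
#' @slot params the [ModelParams-class] used.
#' @slot state final [SimulationState-class].
#' @slot fields final [FieldState-class].
#' @slot snapshots list of `list(mcs =, sigma =)` records captured every
#'   `snapshotEvery` MCS (plus fields when requested).
#' @slot nCells,initMode,fieldMode run configuration.
#' @export
setClass("SimulationRun", representation(
    params = "ModelParams", state = "SimulationState", fields = "FieldState",
    snapshots = "list", nCells = "integer", initMode = "character",
    fieldMode = "character"
))
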