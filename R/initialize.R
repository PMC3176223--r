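#' Seed cells on the lattice
#'
#' Places `nCells` compact square patches of approximately the target area on
#' a regular mesh, or on a semi-random mesh obtained by displacing every
#' center from its regular position by an integer offset of magnitude
#' strictly smaller than one isotropic cell diameter. Cells are seeded at
#' (near) target area so the dynamics start without a growth burn-in phase.
#' Consumes the current RNG stream (only in `semi_random` mode).
#'
#' @param nCells number of cells; `nCells * ATarget` must fit the lattice.
#' @param mode `"regular"` or `"semi_random"`.
#' @param params a [ModelParams-class] object.
#' @param maxRetries bounded number of re-draws per cell when a displaced
#'   placement would overlap an earlier cell.
#' @return a [SimulationState-class] with disjoint, connected square cells.
#' @examples
#' p <- referenceParams(latticeSide = 100L)
#' st <- initializeCells(4L, "regular", p)
#' st@cells
#' @export
initializeCells <- function(nCells, mode = c("regular", "semi_random"),
                            params, maxRetries = 100L) {
    mode <- match.arg(mode)
    L <- params@latticeSide
    if (nCells * params@ATarget > L^2)
        stop("overcrowding: nCells * ATarget exceeds the lattice area")
    sigma <- matrix(0L, L, L)
    if (nCells == 0L) {
        return(new("SimulationState", sigma = sigma,
                   cells = data.frame(index = integer(), type = character(),
                                      area = integer()),
                   mcs = 0L, pixelSize = params@pixelSize))
    }
    side <- max(1L, as.integer(round(sqrt(params@ATarget))))
    nGrid <- ceiling(sqrt(nCells))
    spacing <- L / nGrid
    centers <- expand.grid(i = seq_len(nGrid), j = seq_len(nGrid))
    # when nCells < nGrid^2, spread the vacancies evenly over the mesh
    # instead of leaving an unseeded stripe at the end
    pick <- unique(as.integer(round(seq(1, nGrid^2, length.out = nCells))))
    k <- nGrid^2
    while (length(pick) < nCells) {   # fill rounding collisions
        pick <- union(pick, k)
        k <- k - 1L
    }
    centers <- centers[sort(pick), , drop = FALSE]
    cr <- (centers$i - 0.5) * spacing
    cc <- (centers$j - 0.5) * spacing
    dIso <- isotropicDiameter(params)
    half <- side %/% 2L
    place <- function(r0, c0, idx) {
        rs <- max(1L, r0):min(L, r0 + side - 1L)
        cs <- max(1L, c0):min(L, c0 + side - 1L)
        block <- sigma[rs, cs, drop = FALSE]
        if (any(block != 0L)) return(FALSE)
        sigma[rs, cs] <<- idx
        TRUE
    }
    for (k in seq_len(nCells)) {
        if (mode == "regular") {
            ok <- place(as.integer(round(cr[k])) - half,
                        as.integer(round(cc[k])) - half, k)
            if (!ok)
                stop("overcrowding: regular mesh placements overlap; ",
                     "reduce nCells or ATarget")
        } else {
            ok <- FALSE
            for (try in seq_len(maxRetries)) {
                repeat {
                    dr <- sample.int(2L * ceiling(dIso) + 1L, 1L) -
                        ceiling(dIso) - 1L
                    dc <- sample.int(2L * ceiling(dIso) + 1L, 1L) -
                        ceiling(dIso) - 1L
                    if (dr * dr + dc * dc < dIso^2) break
                }
                if (place(as.integer(round(cr[k] + dr)) - half,
                          as.integer(round(cc[k] + dc)) - half, k)) {
                    ok <- TRUE
                    break
                }
            }
            if (!ok)
                stop(sprintf(
                    "overcrowding: cell %d could not be placed after %d draws",
                    k, maxRetries))
        }
    }
    areas <- tabulate(sigma[sigma > 0L], nbins = nCells)
    new("SimulationState", sigma = sigma,
        cells = data.frame(index = seq_len(nCells),
                           type = rep("angioblast", nCells),
                           area = as.integer(areas)),
        mcs = 0L, pixelSize = params@pixelSize)
}

#' Zero-initialized fields matching a parameter set
#'
#' All three concentrations start at zero: the dynamics are entirely driven
#' by production, which is the only initial condition consistent with a
#' model in which nothing pre-exists the cells.
#'
#' @param params a [ModelParams-class] object.
#' @return a [FieldState-class] of zeros.
#' @export
emptyFields <- function(params) {
    L <- params@latticeSide
    z <- matrix(0, L, L)
    new("FieldState", s = z, e = z, b = z)
}

#' Binary cell mask of a simulation state
#'
#' @param state a [SimulationState-class].
#' @return a [BinaryPattern-class]: 1 where a cell occupies the site, 0 for
#'   medium.
#' @export
cellMask <- function(state) {
    new("BinaryPattern",
        mask = matrix(as.integer(state@sigma > 0L), nrow(state@sigma)),
        pixelSize = state@pixelSize)
}
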