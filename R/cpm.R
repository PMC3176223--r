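#' Total energy of a cellular Potts configuration
#'
#' H = sum over neighbor pairs of the binding energy J (Jcc between two
#' cells, Jcm between a cell and the medium, zero within one object) plus
#' the area penalty `lambdaArea * (area - ATarget)^2` summed over cells
#' (never over the medium). Each unordered pair within the
#' `neighborOrder` neighborhood is counted once; virtual sites beyond the
#' lattice edge count as medium.
#'
#' @param state a [SimulationState-class].
#' @param params a [ModelParams-class].
#' @return the scalar energy.
#' @export
cpmHamiltonian <- function(state, params) {
    cpm_hamiltonian_cpp(state@sigma, as.integer(state@cells$area),
                        params@Jcc, params@Jcm, params@lambdaArea,
                        params@ATarget, params@neighborOrder)
}

#' Construct a copy attempt
#'
#' A copy attempt proposes that the source site copies its cell index into
#' the neighboring target site. Coordinates are 1-based (row, col).
#'
#' @param source,target length-2 integer vectors (row, col); must be
#'   distinct lattice neighbors within the copy neighborhood.
#' @param state a [SimulationState-class] used for validation.
#' @param params a [ModelParams-class].
#' @return a list with `source`, `target`, `sourceIndex`, `targetIndex`.
#' @export
copyAttempt <- function(source, target, state, params) {
    stopifnot(length(source) == 2L, length(target) == 2L)
    d <- target - source
    offs <- cpm_neighborhood(params@copyOrder)
    if (!any(offs[, 1] == d[1] & offs[, 2] == d[2]))
        stop("target is not a copy-neighborhood neighbor of source")
    list(source = as.integer(source), target = as.integer(target),
         sourceIndex = state@sigma[source[1], source[2]],
         targetIndex = state@sigma[target[1], target[2]])
}

#' Energy change of a copy attempt
#'
#' Computes the local change in boundary and area energy if the source site
#' copied its index into the target site, plus the chemotaxis bias
#' `-muB (b(target) - b(source)) - muS (s(target) - s(source))`, which
#' favors extensions up-gradient of (mostly bound) VEGF. Only interfaces
#' and areas touched by the copy are evaluated; the result is exactly the
#' full Hamiltonian difference plus the chemotaxis work term.
#'
#' @param state a [SimulationState-class].
#' @param fields a [FieldState-class].
#' @param attempt a [copyAttempt()] list.
#' @param params a [ModelParams-class].
#' @return the scalar energy change of the proposed copy.
#' @export
cpmDeltaH <- function(state, fields, attempt, params) {
    cpm_delta_h_cpp(state@sigma, as.integer(state@cells$area),
                    fields@s, fields@b,
                    attempt$target[1] - 1L, attempt$target[2] - 1L,
                    attempt$source[1] - 1L, attempt$source[2] - 1L,
                    params@Jcc, params@Jcm, params@lambdaArea,
                    params@ATarget, params@muB, params@muS,
                    params@neighborOrder)
}

#' Metropolis acceptance probability
#'
#' Energy-lowering copies are always accepted; energy-raising copies are
#' accepted with Boltzmann probability exp(-dH/T). At `TFluct = 0` the
#' limit applies: accept iff `dH <= 0`.
#'
#' @param dH energy change(s) of the attempt; vectorized.
#' @param TFluct fluctuation energy (>= 0).
#' @return acceptance probabilities in [0, 1].
#' @examples
#' acceptanceProbability(c(-5, 0, 1), TFluct = 1)
#' @export
acceptanceProbability <- function(dH, TFluct) {
    if (any(TFluct < 0)) stop("'TFluct' must be >= 0")
    n <- max(length(dH), length(TFluct))
    dH <- rep_len(dH, n)
    TFluct <- rep_len(TFluct, n)
    p <- numeric(n)
    p[dH <= 0] <- 1
    hot <- dH > 0 & TFluct > 0
    p[hot] <- exp(-dH[hot] / TFluct[hot])
    p
}

#' Advance the cellular Potts configuration by Monte Carlo steps
#'
#' One MCS performs `latticeSide^2` random copy attempts: draw a target
#' site, draw a source site from its copy neighborhood (attempts whose
#' source would lie outside the lattice are skipped), evaluate the energy
#' change including chemotaxis against the current fields, and accept by
#' the Metropolis rule. Copies that would erase a cell's last pixel or
#' split a cell into disconnected pieces are rejected outright (cells are
#' connected subdomains and the cell count is conserved); the split test
#' is the local Yokoi simple-point criterion on the retracting cell. Cell
#' areas are maintained incrementally. Consumes the R RNG stream.
#'
#' @param state a [SimulationState-class].
#' @param fields a [FieldState-class] (chemotaxis substrate).
#' @param params a [ModelParams-class].
#' @param nSteps number of MCS to perform.
#' @return the updated [SimulationState-class]; the fraction of accepted
#'   attempts is available as `attr(, "acceptanceRate")`.
#' @export
monteCarloStep <- function(state, fields, params, nSteps = 1L) {
    sigma <- state@sigma + 0L        # force copies: kernel works in place
    areas <- as.integer(state@cells$area) + 0L
    diag <- cpm_mcs_cpp(sigma, areas, fields@s, fields@b, as.integer(nSteps),
                        params@Jcc, params@Jcm, params@lambdaArea,
                        params@ATarget, params@muB, params@muS,
                        params@TFluct, params@neighborOrder,
                        params@copyOrder)
    cells <- state@cells
    cells$area <- areas
    out <- new("SimulationState", sigma = sigma, cells = cells,
               mcs = state@mcs + as.integer(nSteps),
               pixelSize = state@pixelSize)
    attr(out, "acceptanceRate") <- diag$accepted / max(1, diag$attempts)
    out
}
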