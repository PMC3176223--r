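#' Normalized cell lengths from an elliptic shape approximation
#'
#' For every cell, computes the covariance matrix (inertia tensor) of its
#' occupied pixel coordinates; the cell length is the full major axis of
#' the moment-equivalent ellipse, L = 4 sqrt(lambda1) with lambda1 the
#' leading eigenvalue. Lengths are normalized by the diameter of an
#' isotropic (circular) cell of the target area, 2 sqrt(ATarget/pi), so a
#' round cell at target area scores ~1. A one-pixel cell has length 1
#' pixel by definition.
#'
#' @param state a [SimulationState-class].
#' @param params a [ModelParams-class] (supplies the target area).
#' @return named numeric vector of normalized lengths, one per cell.
#' @examples
#' p <- referenceParams(latticeSide = 64L)
#' st <- initializeCells(2L, "regular", p)
#' cellLengths(st, p)
#' @export
cellLengths <- function(state, params) {
    dIso <- isotropicDiameter(params)
    idx <- state@cells$index
    if (!length(idx)) return(setNames(numeric(), character()))
    pos <- which(state@sigma > 0L, arr.ind = TRUE)
    lab <- state@sigma[state@sigma > 0L]
    out <- vapply(idx, function(i) {
        pts <- pos[lab == i, , drop = FALSE]
        n <- nrow(pts)
        if (n == 0L) return(NA_real_)
        if (n == 1L) return(1 / dIso)
        mu <- colMeans(pts)
        xc <- pts[, 1] - mu[1]; yc <- pts[, 2] - mu[2]
        cxx <- mean(xc^2); cyy <- mean(yc^2); cxy <- mean(xc * yc)
        lambda1 <- (cxx + cyy) / 2 + sqrt(((cxx - cyy) / 2)^2 + cxy^2)
        4 * sqrt(lambda1) / dIso
    }, numeric(1))
    setNames(out, idx)
}
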