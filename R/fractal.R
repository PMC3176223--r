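#' Box-counting fractal dimension
#'
#' Covers the image with boxes of side 2, 4, 8, ... up to a quarter of the
#' smaller image side, counts boxes containing at least one foreground
#' pixel per scale, and returns the least-squares slope of log N(eps)
#' against log(1/eps). Applied to the thinned network by default in
#' [analyzePattern()].
#'
#' @inheritParams countComponents
#' @param boxSizes integer box sides; defaults to the geometric series
#'   above.
#' @return the estimated dimension; errors when fewer than two scales
#'   contain foreground (e.g. an empty mask).
#' @examples
#' fractalDimension(primitivePattern("bar", side = 64L, width = 1L,
#'   length = 64L))
#' @export
fractalDimension <- function(pattern, boxSizes = NULL) {
    m <- asMaskMatrix(pattern)
    if (is.null(boxSizes)) boxSizes <- defaultBoxSizes(dim(m))
    counts <- vapply(boxSizes, function(r) boxCount(m, r), numeric(1))
    ok <- counts > 0
    if (sum(ok) < 2)
        stop("fractal dimension needs >= 2 scales with occupied boxes")
    fit <- lm(log(counts[ok]) ~ log(1 / boxSizes[ok]))
    unname(coef(fit)[2])
}

defaultBoxSizes <- function(dims) {
    top <- max(2L, min(dims) %/% 4L)
    sizes <- 2L
    while (tail(sizes, 1L) * 2L <= top) sizes <- c(sizes, tail(sizes, 1L) * 2L)
    sizes
}

# number of r x r boxes (anchored at a regular grid) containing foreground
boxCount <- function(m, r) {
    bi <- (seq_len(nrow(m)) - 1L) %/% r
    bj <- (seq_len(ncol(m)) - 1L) %/% r
    occ <- rowsum(t(rowsum(m, bi)), bj)
    sum(occ > 0)
}

#' Gliding-box lacunarity
#'
#' For every box size r in the series, slides an r x r window over all
#' positions, computes the window mass M, and forms
#' Lambda(r) = var(M)/mean(M)^2 + 1 (population variance). The summary
#' value is the mean of Lambda(r) over the series; the full curve is
#' returned alongside. Measures the "gappiness" (translational
#' heterogeneity) of the pattern; 1 for a uniform mask, large for sparse
#' clustered patterns.
#'
#' @inheritParams fractalDimension
#' @return list with `value` (mean over scales) and `curve` (data.frame
#'   `boxSize`, `lambda`).
#' @examples
#' lacunarity(matrix(1L, 20, 20))$value  # exactly 1
#' @export
lacunarity <- function(pattern, boxSizes = NULL) {
    m <- asMaskMatrix(pattern)
    if (is.null(boxSizes)) boxSizes <- defaultBoxSizes(dim(m))
    boxSizes <- boxSizes[boxSizes <= min(dim(m))]
    lam <- vapply(boxSizes, function(r) {
        mass <- glideMass(m, r)
        mu <- mean(mass)
        if (mu == 0) return(NA_real_)
        v <- mean(mass^2) - mu^2
        v / mu^2 + 1
    }, numeric(1))
    curve <- data.frame(boxSize = boxSizes, lambda = lam)
    list(value = mean(lam, na.rm = TRUE), curve = curve)
}

# masses of all r x r windows via an integral image
glideMass <- function(m, r) {
    nr <- nrow(m); nc <- ncol(m)
    S <- matrix(0, nr + 1L, nc + 1L)
    S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
    i <- seq_len(nr - r + 1L); j <- seq_len(nc - r + 1L)
    S[i + r, j + r, drop = FALSE] - S[i, j + r, drop = FALSE] -
        S[i + r, j, drop = FALSE] + S[i, j, drop = FALSE]
}
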