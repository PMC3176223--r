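#' Grid-network fixture of known topology
#'
#' A rectangular lattice of struts enclosing `holesPerSide^2` identical
#' square holes. By construction the pattern is a single component
#' (Betti 0 = 1) with `holesPerSide^2` lacunae, coverage
#' 1 - holes/(canvas area), and, with `margin = 0`, percolative. Serves as
#' a ground-truth oracle for the morphometric suite.
#'
#' @param holesPerSide number of holes along each side.
#' @param holeSize hole side length, px.
#' @param strutWidth strut width, px.
#' @param margin background margin around the grid, px (0 keeps the grid
#'   flush with the image border, hence percolative).
#' @param pixelSize um per pixel for the returned pattern.
#' @return a [BinaryPattern-class].
#' @examples
#' countLacunae(gridNetwork(3L, holeSize = 6L, strutWidth = 3L))  # 9
#' @export
gridNetwork <- function(holesPerSide, holeSize, strutWidth, margin = 0L,
                        pixelSize = 1) {
    h <- as.integer(holesPerSide)
    core <- h * holeSize + (h + 1L) * strutWidth
    side <- core + 2L * margin
    if (h < 1L || holeSize < 1L || strutWidth < 1L)
        stop("holesPerSide, holeSize and strutWidth must be >= 1")
    m <- matrix(0L, side, side)
    m[(margin + 1L):(margin + core), (margin + 1L):(margin + core)] <- 1L
    for (i in seq_len(h)) {
        for (j in seq_len(h)) {
            r0 <- margin + i * strutWidth + (i - 1L) * holeSize + 1L
            c0 <- margin + j * strutWidth + (j - 1L) * holeSize + 1L
            m[r0:(r0 + holeSize - 1L), c0:(c0 + holeSize - 1L)] <- 0L
        }
    }
    new("BinaryPattern", mask = m, pixelSize = pixelSize)
}

#' Geometric primitive fixtures
#'
#' Rasterized primitives with analytically known geometry and topology:
#' `disk` (area ~ pi r^2), `square`, `bar` (skeleton length ~ bar length),
#' `cross` (one degree-4 branch point), and `ring` (Betti numbers 1, 1).
#'
#' @param kind primitive name.
#' @param side canvas side, px.
#' @param radius disk/ring outer radius, px.
#' @param thickness ring thickness, px.
#' @param width,length bar width and length, px.
#' @param squareSide square side, px.
#' @param arm cross arm width, px.
#' @param pixelSize um per pixel.
#' @return a [BinaryPattern-class] centered on the canvas.
#' @examples
#' countLacunae(primitivePattern("ring", side = 41L, radius = 15,
#'   thickness = 4))  # 1
#' @export
primitivePattern <- function(kind = c("disk", "square", "bar", "cross",
                                      "ring"),
                             side = 64L, radius = 20, thickness = 4,
                             width = 3L, length = 50L, squareSide = 20L,
                             arm = 3L, pixelSize = 1) {
    kind <- match.arg(kind)
    side <- as.integer(side)
    ctr <- floor((side + 1) / 2)   # integer center so width-1 shapes exist
    xs <- matrix(seq_len(side), side, side)
    ys <- matrix(seq_len(side), side, side, byrow = TRUE)
    r2 <- (xs - ctr)^2 + (ys - ctr)^2
    # centered integer interval of exact extent n
    span <- function(z, n) {
        lo <- ctr - (n - 1L) %/% 2L
        z >= lo & z <= lo + n - 1L
    }
    m <- switch(kind,
        disk = (r2 <= radius^2),
        ring = (r2 <= radius^2) & (r2 > (radius - thickness)^2),
        square = span(xs, squareSide) & span(ys, squareSide),
        bar = span(xs, width) & span(ys, length),
        cross = span(xs, arm) | span(ys, arm))
    new("BinaryPattern", mask = matrix(as.integer(m), side),
        pixelSize = pixelSize)
}

#' Random smoothed-noise mask
#'
#' Thresholded smoothed uniform noise with the requested coverage (the
#' threshold is the matching quantile of the smoothed field, so the
#' realized coverage is exact up to ties). Used as property-test input for
#' oracle-equivalence checks. Consumes the current RNG stream.
#'
#' @param side canvas side, px.
#' @param density requested coverage fraction in [0, 1].
#' @param smoothing Gaussian blur sigma, px (0 for raw noise).
#' @param pixelSize um per pixel.
#' @return a [BinaryPattern-class].
#' @examples
#' set.seed(1)
#' coverage(randomMask(50L, density = 0.4))
#' @export
randomMask <- function(side, density, smoothing = 2, pixelSize = 1) {
    stopifnot(density >= 0, density <= 1)
    side <- as.integer(side)
    if (density == 0)
        return(new("BinaryPattern", mask = matrix(0L, side, side),
                   pixelSize = pixelSize))
    if (density == 1)
        return(new("BinaryPattern", mask = matrix(1L, side, side),
                   pixelSize = pixelSize))
    z <- matrix(runif(side * side), side, side)
    if (smoothing > 0)
        z <- EBImage::gblur(z, sigma = smoothing)
    thr <- quantile(z, probs = 1 - density, names = FALSE)
    new("BinaryPattern", mask = matrix(as.integer(z > thr), side),
        pixelSize = pixelSize)
}
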