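#' Number of vascular components (Betti number 0)
#'
#' Counts 8-connected foreground components of the binary pattern. Together
#' with [countLacunae()] these are the two Betti numbers of the pattern
#' under the standard dual convention: foreground 8-connected, background
#' 4-connected.
#'
#' @param pattern a [BinaryPattern-class] or 0/1 matrix.
#' @return non-negative integer count.
#' @export
countComponents <- function(pattern) {
    m <- asMaskMatrix(pattern)
    max(label_components_cpp(m, 8L), 0L)
}

#' Number of lacunae (Betti number 1)
#'
#' Counts enclosed avascular holes: 4-connected background components that
#' do not touch the image border. Set `includeBorder = TRUE` to also count
#' background regions cropped by the image edge, as can be appropriate for
#' micrograph cut-outs. With the default `minArea = 1` the count is the
#' exact first Betti number of the pattern; network-level analyses
#' ([analyzePattern()], [trackDynamics()]) raise the floor to suppress
#' single-pixel membrane-roughness speckles that no imaging pipeline would
#' score as avascular zones.
#'
#' @inheritParams countComponents
#' @param includeBorder also count border-touching background components.
#' @param minArea smallest hole area (px) that counts as a lacuna.
#' @return non-negative integer count.
#' @export
countLacunae <- function(pattern, includeBorder = FALSE, minArea = 1L) {
    length(lacunaLabels(pattern, includeBorder, minArea)$keep)
}

# Label the background 4-connected; return the label matrix and the label
# ids that count as lacunae.
lacunaLabels <- function(pattern, includeBorder = FALSE, minArea = 1L) {
    m <- asMaskMatrix(pattern)
    bg <- matrix(as.integer(m == 0L), nrow(m))
    lab <- label_components_cpp(bg, 4L)
    n <- max(lab)
    if (n == 0L) return(list(labels = lab, keep = integer()))
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border <- border[border > 0L]
    keep <- setdiff(seq_len(n), if (includeBorder) integer() else border)
    if (minArea > 1L && length(keep)) {
        sizes <- tabulate(lab[lab > 0L], nbins = n)
        keep <- keep[sizes[keep] >= minArea]
    }
    list(labels = lab, keep = keep)
}

#' Per-lacuna geometry
#'
#' For every enclosed lacuna: its area in pixels, the length of the traced
#' boundary contour, and the isoperimetric quotient Q = 4 pi A / P^2
#' (capped at 1), where A and P are the area and perimeter of the polygon
#' traced through the boundary pixel centers (diagonal steps count
#' sqrt(2)). Under this convention an n x n square hole has Q = pi/4
#' exactly. For degenerate lacunae whose center polygon has no interior
#' (single pixels, one-pixel-wide slits) the pixel-edge ("crack") contour
#' is used instead, keeping Q in (0, 1].
#'
#' @inheritParams countLacunae
#' @return data.frame with columns `area`, `perimeter`, `roundness`; zero
#'   rows when the pattern has no lacunae.
#' @examples
#' ring <- primitivePattern("ring", side = 41L, radius = 15, thickness = 5)
#' lacunaStats(ring)
#' @export
lacunaStats <- function(pattern, includeBorder = FALSE, minArea = 1L) {
    ll <- lacunaLabels(pattern, includeBorder, minArea)
    if (!length(ll$keep))
        return(data.frame(area = numeric(), perimeter = numeric(),
                          roundness = numeric()))
    rows <- lapply(ll$keep, function(id) {
        px <- which(ll$labels == id, arr.ind = TRUE)
        area <- nrow(px)
        tr <- traceContour(ll$labels == id)
        P <- tr$length
        Apoly <- tr$area
        if (P > 0 && Apoly > 0) {
            Q <- min(1, 4 * pi * Apoly / P^2)
        } else {
            # crack contour fallback for degenerate (thin) lacunae
            Pc <- crackPerimeter(ll$labels == id)
            P <- Pc
            Q <- min(1, 4 * pi * area / Pc^2)
        }
        data.frame(area = area, perimeter = P, roundness = Q)
    })
    do.call(rbind, rows)
}

# Moore-neighbor contour tracing with Jacob's stopping criterion.
# Returns the polygonal length through boundary pixel centers and the
# shoelace area of the traced polygon.
traceContour <- function(bin) {
    idx <- which(bin, arr.ind = TRUE)
    if (nrow(idx) == 1L) return(list(length = 0, area = 0))
    # start: topmost pixel of the leftmost occupied column
    c0 <- min(idx[, 2])
    r0 <- min(idx[idx[, 2] == c0, 1])
    nr <- nrow(bin); nc <- ncol(bin)
    at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && bin[r, c]
    # clockwise Moore neighborhood starting west (in matrix coords:
    # rows grow down, cols grow right)
    dr <- c(0, -1, -1, -1, 0, 1, 1, 1)
    dc <- c(-1, -1, 0, 1, 1, 1, 0, -1)
    cur <- c(r0, c0)
    entry <- 1L   # came from the west (backtrack direction index)
    path <- list(cur)
    startPair <- NULL
    repeat {
        found <- FALSE
        k <- entry
        for (step in 1:8) {
            k <- (k %% 8L) + 1L
            rr <- cur[1] + dr[k]; cc <- cur[2] + dc[k]
            if (at(rr, cc)) {
                # next backtrack: the neighbor checked just before k
                prev <- k - 1L
                if (prev < 1L) prev <- 8L
                entry <- backIndex(dr, dc, cur, c(rr, cc), prev)
                cur <- c(rr, cc)
                found <- TRUE
                break
            }
        }
        if (!found) break  # isolated pixel (cannot happen here)
        pair <- c(cur, entry)
        if (is.null(startPair)) {
            startPair <- pair
        } else if (identical(pair, startPair)) {
            break
        }
        path[[length(path) + 1L]] <- cur
        if (length(path) > 8L * nrow(idx) + 8L) break  # safety
    }
    pts <- do.call(rbind, path)
    if (nrow(pts) < 2L) return(list(length = 0, area = 0))
    dx <- diff(pts[, 1]); dy <- diff(pts[, 2])
    len <- sum(sqrt(dx^2 + dy^2))
    x <- pts[-nrow(pts), 1]; y <- pts[-nrow(pts), 2]
    x2 <- pts[-1, 1]; y2 <- pts[-1, 2]
    area <- abs(sum(x * y2 - x2 * y)) / 2
    list(length = len, area = area)
}

# Direction index pointing from the new pixel back toward the previously
# checked (background) neighbor of the old pixel.
backIndex <- function(dr, dc, old, new, prevK) {
    br <- old[1] + dr[prevK] - new[1]
    bc <- old[2] + dc[prevK] - new[2]
    k <- which(dr == br & dc == bc)
    if (length(k) != 1L) k <- which(dr == -(new[1] - old[1]) &
                                    dc == -(new[2] - old[2]))
    k[1]
}

# Length of the pixel-edge boundary: 4 * area - 2 * (4-adjacent
# internal pairs).
crackPerimeter <- function(bin) {
    m <- bin + 0L
    horiz <- sum(m[-nrow(m), ] & m[-1, ])
    vert <- sum(m[, -ncol(m)] & m[, -1])
    4 * sum(m) - 2 * (horiz + vert)
}

#' Vascular coverage
#'
#' Ratio of vascular (nonzero) pixels to the image size.
#'
#' @inheritParams countComponents
#' @return fraction in [0, 1].
#' @export
coverage <- function(pattern) {
    mean(asMaskMatrix(pattern))
}

#' Percolation of the vascular pattern
#'
#' TRUE when a single 8-connected vascular component touches both the left
#' and right image columns and both the top and bottom rows, i.e. spans the
#' image horizontally and vertically.
#'
#' @inheritParams countComponents
#' @return logical flag.
#' @export
isPercolative <- function(pattern) {
    m <- asMaskMatrix(pattern)
    lab <- label_components_cpp(m, 8L)
    if (max(lab) == 0L) return(FALSE)
    left <- unique(lab[, 1]); right <- unique(lab[, ncol(lab)])
    top <- unique(lab[1, ]); bottom <- unique(lab[nrow(lab), ])
    cand <- Reduce(intersect, list(left, right, top, bottom))
    any(cand > 0L)
}

#' Cell-lacuna interface length
#'
#' Counts 4-adjacent foreground/background pixel pairs, the pixel-unit
#' length of the boundary between vascular and avascular regions. The image
#' border itself contributes nothing.
#'
#' @inheritParams countComponents
#' @return non-negative count.
#' @export
interfaceLength <- function(pattern) {
    m <- asMaskMatrix(pattern)
    horiz <- sum(m[-nrow(m), ] != m[-1, ])
    vert <- sum(m[, -ncol(m)] != m[, -1])
    horiz + vert
}
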