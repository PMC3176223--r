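#' Thin a pattern to its skeleton
#'
#' Morphological thinning (Guo-Hall parallel thinning iterated to
#' stability), which reduces the vascular structures to a one-pixel-wide
#' skeletal remnant while preserving the connectivity of both foreground
#' and background, hence both Betti numbers of the pattern.
#'
#' @inheritParams countComponents
#' @return a [BinaryPattern-class] holding the skeleton.
#' @export
skeletonize <- function(pattern) {
    m <- asMaskMatrix(pattern)
    px <- if (is(pattern, "BinaryPattern")) pattern@pixelSize else 1
    new("BinaryPattern", mask = thin_guo_hall_cpp(m), pixelSize = px)
}

#' Spanning length of the network
#'
#' The total pixel count of the thinned network.
#'
#' @param skeleton a [BinaryPattern-class] from [skeletonize()] (or 0/1
#'   matrix).
#' @return non-negative count.
#' @export
spanningLength <- function(skeleton) {
    sum(asMaskMatrix(skeleton))
}

#' Cord half-widths along the skeleton
#'
#' The Euclidean distance from each skeleton pixel to the nearest avascular
#' pixel of the original pattern, i.e. half the local cord width. The
#' distance transform treats the image border as avascular.
#'
#' @inheritParams countComponents
#' @param skeleton the matching skeleton ([skeletonize()] output); computed
#'   when missing.
#' @return numeric vector, one value (>= 1) per skeleton pixel.
#' @export
cordWidths <- function(pattern, skeleton = NULL) {
    m <- asMaskMatrix(pattern)
    if (is.null(skeleton)) skeleton <- skeletonize(pattern)
    sk <- asMaskMatrix(skeleton)
    d <- distanceToBackground(m)
    as.numeric(d[sk > 0L])
}

# Euclidean distance of foreground pixels to the nearest background pixel;
# the border beyond the image counts as background (pad with zeros).
distanceToBackground <- function(m) {
    pad <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
    pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
    d <- EBImage::distmap(pad, metric = "euclidean")
    matrix(as.numeric(d[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)]), nrow(m))
}

#' Build the merge-corrected node graph of a skeleton
#'
#' Raw branch points are skeleton pixels with three or more skeleton
#' neighbors among their 8 adjacent sites. Skeleton segments between branch
#' points and endpoints are traced into edges. Because thinning leaves
#' clusters of adjacent branch pixels on thick cords, raw nodes are then
#' merged agglomeratively: two connected nodes merge whenever their
#' Euclidean separation is strictly smaller than the larger of their local
#' half-widths (distance to the nearest avascular pixel). Merged nodes take
#' the centroid position of their raw pixels; edges internal to a merged
#' node are dropped and the node degree is the number of remaining incident
#' edges.
#'
#' @param skeleton a [BinaryPattern-class] from [skeletonize()].
#' @param pattern the original pattern (for the width transform); when
#'   missing the skeleton itself is used, giving all widths 1.
#' @return a [SkeletonGraph-class].
#' @examples
#' g <- buildNodeGraph(skeletonize(primitivePattern("cross",
#'   side = 31L, arm = 3L)))
#' nrow(g@nodes)
#' @export
buildNodeGraph <- function(skeleton, pattern = NULL) {
    sk <- asMaskMatrix(skeleton)
    empty <- new("SkeletonGraph", skeleton = sk,
                 nodes = data.frame(id = integer(), row = numeric(),
                                    col = numeric(), degree = integer(),
                                    width = numeric(), nRaw = integer()),
                 edges = data.frame(from = integer(), to = integer(),
                                    length = numeric()))
    pix <- which(sk > 0L, arr.ind = TRUE)
    if (!nrow(pix)) return(empty)
    widthMap <- if (is.null(pattern)) distanceToBackground(sk)
                else distanceToBackground(asMaskMatrix(pattern))
    nr <- nrow(sk)
    key <- function(r, c) (c - 1L) * nr + r
    id <- matrix(0L, nr, ncol(sk))
    id[pix] <- seq_len(nrow(pix))
    offs <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
    neighborIds <- function(k) {
        r <- pix[k, 1]; c <- pix[k, 2]
        rr <- r + offs[, 1]; cc <- c + offs[, 2]
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= ncol(sk)
        ids <- id[cbind(rr[ok], cc[ok])]
        ids[ids > 0L]
    }
    nbr <- lapply(seq_len(nrow(pix)), neighborIds)
    pixDeg <- lengths(nbr)
    isNode <- pixDeg >= 3L          # raw branch pixels
    isEnd <- pixDeg <= 1L           # endpoints and isolated pixels
    term <- isNode | isEnd          # segment terminals
    # trace segments between terminals through degree-2 path pixels
    edgeList <- list()
    seen <- new.env(hash = TRUE)
    markEdge <- function(a, b, firstStep) {
        tag <- paste(a, firstStep, sep = "-")
        if (!is.null(seen[[tag]])) return(NULL)
        seen[[tag]] <- TRUE
        len <- stepLen(pix[a, ], pix[firstStep, ])
        prev <- a; cur <- firstStep
        while (!term[cur]) {
            nxt <- setdiff(nbr[[cur]], prev)
            # at a diagonal shortcut the path pixel can see 2+ pixels;
            # prefer continuing to a terminal, else the first path pixel
            if (length(nxt) == 0L) break
            if (length(nxt) > 1L) {
                tnx <- nxt[term[nxt]]
                nxt <- if (length(tnx)) tnx[1] else nxt[1]
            }
            len <- len + stepLen(pix[cur, ], pix[nxt, ])
            prev <- cur; cur <- nxt
        }
        if (term[cur]) {
            # mark reverse traversal as seen
            seen[[paste(cur, prev, sep = "-")]] <- TRUE
            list(from = a, to = cur, length = len)
        } else NULL
    }
    for (a in which(term)) {
        for (b in nbr[[a]]) {
            e <- if (term[b]) {
                tag <- paste(a, b, sep = "-")
                if (is.null(seen[[tag]])) {
                    seen[[tag]] <- TRUE
                    seen[[paste(b, a, sep = "-")]] <- TRUE
                    list(from = a, to = b,
                         length = stepLen(pix[a, ], pix[b, ]))
                } else NULL
            } else markEdge(a, b, b)
            if (!is.null(e)) edgeList[[length(edgeList) + 1L]] <- e
        }
    }
    rawNodes <- which(isNode)
    if (!length(rawNodes)) return(empty)
    edges <- if (length(edgeList)) do.call(rbind, lapply(edgeList, as.data.frame))
             else data.frame(from = integer(), to = integer(),
                             length = numeric())
    mergeNodeGraph(pix, widthMap, rawNodes, edges, isEnd, sk)
}

stepLen <- function(p, q) sqrt(sum((p - q)^2))

# Agglomerative merging of raw branch nodes connected by short edges.
mergeNodeGraph <- function(pix, widthMap, rawNodes, edges, isEnd, sk) {
    group <- seq_along(rawNodes)           # group id per raw node
    names(group) <- rawNodes
    pos <- cbind(pix[rawNodes, 1], pix[rawNodes, 2])
    wid <- widthMap[pix[rawNodes, , drop = FALSE]]
    centroid <- function(g) {
        sel <- group == g
        colMeans(pos[sel, , drop = FALSE])
    }
    gwidth <- function(g) max(wid[group == g])
    # only node-node edges can trigger merging
    nodeEdge <- edges$from %in% rawNodes & edges$to %in% rawNodes
    repeat {
        merged <- FALSE
        for (i in which(nodeEdge)) {
            ga <- group[[as.character(edges$from[i])]]
            gb <- group[[as.character(edges$to[i])]]
            if (ga == gb) next
            pa <- centroid(ga); pb <- centroid(gb)
            sep <- sqrt(sum((pa - pb)^2))
            if (sep < max(gwidth(ga), gwidth(gb))) {
                group[group == gb] <- ga
                merged <- TRUE
            }
        }
        if (!merged) break
    }
    gids <- unique(group)
    nodeRow <- vapply(gids, function(g) centroid(g)[1], numeric(1))
    nodeCol <- vapply(gids, function(g) centroid(g)[2], numeric(1))
    nodeWid <- vapply(gids, gwidth, numeric(1))
    nRaw <- vapply(gids, function(g) sum(group == g), numeric(1))
    remap <- setNames(seq_along(gids), gids)
    toNode <- function(rawId) {
        ch <- as.character(rawId)
        if (ch %in% names(group)) remap[[as.character(group[[ch]])]]
        else NA_integer_
    }
    if (nrow(edges)) {
        ef <- vapply(edges$from, toNode, numeric(1))
        et <- vapply(edges$to, toNode, numeric(1))
        keep <- !(is.na(ef) & is.na(et)) &
            (is.na(ef) | is.na(et) | ef != et)   # drop internal edges
        edges2 <- data.frame(from = ef[keep], to = et[keep],
                             length = edges$length[keep])
    } else {
        edges2 <- data.frame(from = integer(), to = integer(),
                             length = numeric())
    }
    deg <- vapply(seq_along(gids), function(k)
        sum(edges2$from == k, na.rm = TRUE) + sum(edges2$to == k, na.rm = TRUE),
        numeric(1))
    nodes <- data.frame(id = seq_along(gids), row = nodeRow, col = nodeCol,
                        degree = as.integer(deg), width = nodeWid,
                        nRaw = as.integer(nRaw))
    new("SkeletonGraph", skeleton = sk, nodes = nodes, edges = edges2)
}

setMethod("show", "SkeletonGraph", function(object) {
    cat(sprintf("SkeletonGraph: %d nodes, %d edges, %d skeleton px\n",
                nrow(object@nodes), nrow(object@edges),
                sum(object@skeleton)))
})
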