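#' Full morphometric analysis of a binary pattern
#'
#' Composes every morphometric feature into one record: component and
#' lacuna counts (the two Betti numbers), per-lacuna geometry, coverage,
#' percolation, skeleton spanning length and cord widths, merge-corrected
#' node count with degrees, interface length, and the fractal dimension and
#' lacunarity of the thinned network (set `fractalOnMask = TRUE` to measure
#' the filled pattern instead).
#'
#' @inheritParams countComponents
#' @param state optional [SimulationState-class]; when given (with
#'   `params`), normalized cell lengths are attached as
#'   `attr(, "cellLengths")`.
#' @param params a [ModelParams-class], required with `state`.
#' @param fractalOnMask measure fractal dimension and lacunarity on the
#'   full mask rather than the skeleton.
#' @param minLacunaArea smallest hole area (px) scored as a lacuna; the
#'   default of 4 px (16 um^2 at the reference resolution) suppresses
#'   single-pixel membrane-roughness speckles, far below any biological
#'   lacuna.
#' @return a [MorphometricRecord-class].
#' @examples
#' rec <- analyzePattern(gridNetwork(3L, holeSize = 8L, strutWidth = 3L))
#' rec@nLacunae
#' @export
analyzePattern <- function(pattern, state = NULL, params = NULL,
                           fractalOnMask = FALSE, minLacunaArea = 4L) {
    m <- asMaskMatrix(pattern)
    px <- if (is(pattern, "BinaryPattern")) pattern@pixelSize else 1
    pat <- new("BinaryPattern", mask = m, pixelSize = px)
    skel <- skeletonize(pat)
    widths <- cordWidths(pat, skel)
    graph <- buildNodeGraph(skel, pat)
    fracTarget <- if (fractalOnMask) pat else skel
    fd <- tryCatch(fractalDimension(fracTarget), error = function(e) NA_real_)
    lac <- if (sum(asMaskMatrix(fracTarget)) > 0) lacunarity(fracTarget)
           else list(value = NA_real_,
                     curve = data.frame(boxSize = integer(),
                                        lambda = numeric()))
    rec <- new("MorphometricRecord",
               nComponents = as.numeric(countComponents(pat)),
               nLacunae = as.numeric(countLacunae(pat,
                                                  minArea = minLacunaArea)),
               lacunae = lacunaStats(pat, minArea = minLacunaArea),
               coverage = coverage(pat),
               percolative = isPercolative(pat),
               spanningLength = as.numeric(spanningLength(skel)),
               cordWidths = widths,
               nNodes = as.numeric(nrow(graph@nodes)),
               degrees = as.numeric(graph@nodes$degree),
               interfaceLength = as.numeric(interfaceLength(pat)),
               fractalDimension = fd,
               lacunarity = lac$value,
               lacunarityCurve = lac$curve,
               pixelSize = px)
    if (!is.null(state)) {
        if (is.null(params))
            stop("'params' is required when 'state' is given")
        attr(rec, "cellLengths") <- cellLengths(state, params)
    }
    rec
}

#' @describeIn analyzePattern flatten a record to a one-row data.frame of
#'   scalar features (distribution-valued features are summarized by their
#'   mean).
#' @param x a [MorphometricRecord-class].
#' @param row.names,optional,... ignored; present for the generic.
#' @exportS3Method base::as.data.frame
as.data.frame.MorphometricRecord <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
    data.frame(
        nComponents = x@nComponents,
        nLacunae = x@nLacunae,
        meanLacunaArea = if (nrow(x@lacunae)) mean(x@lacunae$area) else NA,
        meanRoundness = if (nrow(x@lacunae)) mean(x@lacunae$roundness) else NA,
        coverage = x@coverage,
        percolative = x@percolative,
        spanningLength = x@spanningLength,
        meanCordWidth = if (length(x@cordWidths)) mean(x@cordWidths) else NA,
        nNodes = x@nNodes,
        meanDegree = if (length(x@degrees)) mean(x@degrees) else NA,
        interfaceLength = x@interfaceLength,
        fractalDimension = x@fractalDimension,
        lacunarity = x@lacunarity)
}

setMethod("show", "MorphometricRecord", function(object) {
    cat("MorphometricRecord\n")
    cat(sprintf("  components %g, lacunae %g, coverage %.3f, percolative %s\n",
                object@nComponents, object@nLacunae, object@coverage,
                object@percolative))
    cat(sprintf("  spanning length %g px, nodes %g, interface %g px\n",
                object@spanningLength, object@nNodes,
                object@interfaceLength))
    cat(sprintf("  fractal dimension %.3f, lacunarity %.3f\n",
                object@fractalDimension, object@lacunarity))
})
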