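#' Read a binary mask from a PNG or TIFF file
#'
#' Accepts single-channel (or grayscale-equal RGB) images whose pixels are
#' strictly binary (0 or full intensity). Non-binary images are rejected
#' with a suggestion to threshold them first.
#'
#' @param path image path; format chosen by extension (.png, .tif/.tiff).
#' @param pixelSize um per pixel to attach to the pattern.
#' @return a [BinaryPattern-class] (vascular = 1).
#' @export
readMask <- function(path, pixelSize = 1) {
    ext <- tolower(tools::file_ext(path))
    img <- switch(ext,
        png = png::readPNG(path),
        tif = ,
        tiff = tiff::readTIFF(path),
        stop("unsupported mask format: .", ext))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    vals <- unique(round(as.vector(img), 6))
    if (!all(vals %in% c(0, 1)))
        stop("mask image is not binary; threshold it first, e.g. at 0.5")
    new("BinaryPattern", mask = matrix(as.integer(img > 0.5), nrow(img)),
        pixelSize = pixelSize)
}

#' Write a binary mask as a PNG or TIFF file
#'
#' Vascular pixels are written white (full intensity), avascular black.
#' A write/read roundtrip reproduces the mask exactly.
#'
#' @param pattern a [BinaryPattern-class] (or 0/1 matrix).
#' @param path output path; format chosen by extension.
#' @return the path, invisibly.
#' @export
writeMask <- function(pattern, path) {
    m <- asMaskMatrix(pattern)
    ext <- tolower(tools::file_ext(path))
    img <- matrix(as.numeric(m), nrow(m))
    switch(ext,
        png = png::writePNG(img, path),
        tif = ,
        tiff = tiff::writeTIFF(img, path),
        stop("unsupported mask format: .", ext))
    invisible(path)
}

#' Load a model configuration from YAML
#'
#' The YAML file holds [ModelParams-class] fields plus optional scenario
#' keys (`nCells`, `initMode`, `totalMcs`, `fieldMode`). Unknown keys are
#' an error naming the offending key. See
#' `system.file("extdata", "reference.yaml", package = "vasculogen")` for
#' the canonical reference configuration.
#'
#' @param path YAML file path.
#' @return list with `params` ([ModelParams-class]) and `scenario` (list).
#' @export
loadConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    paramKeys <- c("D", "alphaV", "alphaE", "kBind", "gammaS", "TFluct",
                   "ATarget", "lambdaArea", "Jcc", "Jcm", "muTotal", "muB",
                   "muS", "neighborOrder", "copyOrder", "latticeSide",
                   "pixelSize", "mcsSeconds", "pdeSubsteps", "seed")
    scenKeys <- c("nCells", "initMode", "totalMcs", "fieldMode")
    bad <- setdiff(names(cfg), c(paramKeys, scenKeys))
    if (length(bad))
        stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    params <- do.call(referenceParams, cfg[intersect(names(cfg), paramKeys)])
    scenario <- cfg[intersect(names(cfg), scenKeys)]
    list(params = params, scenario = scenario)
}

#' Save a model configuration to YAML
#'
#' @param params a [ModelParams-class].
#' @param path output YAML path.
#' @param scenario optional list of scenario keys (`nCells`, `initMode`,
#'   `totalMcs`, `fieldMode`) to include.
#' @return the path, invisibly.
#' @export
saveConfig <- function(params, path, scenario = list()) {
    vals <- lapply(slotNames(params), function(nm) slot(params, nm))
    names(vals) <- slotNames(params)
    yaml::write_yaml(c(vals, scenario), path)
    invisible(path)
}

#' Save morphometric records or sweep tables
#'
#' @param records a data.frame of features (e.g. from [runRepetitions()]
#'   or a sweep).
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return the path, invisibly.
#' @export
saveReport <- function(records, path, format = c("csv", "json")) {
    format <- match.arg(format)
    if (format == "csv") {
        write.csv(records, path, row.names = FALSE)
    } else {
        jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows")
    }
    invisible(path)
}

#' Write a simulation snapshot to disk
#'
#' Writes the cell mask as PNG alongside an RDS archive of the full state
#' and fields, plus a reproducibility manifest (seed, configuration,
#' package version, timestamp).
#'
#' @param state a [SimulationState-class].
#' @param fields a [FieldState-class].
#' @param params the [ModelParams-class] of the run.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSnapshot <- function(state, fields, params, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeMask(cellMask(state), file.path(dir, "mask.png"))
    saveRDS(list(state = state, fields = fields),
            file.path(dir, "snapshot.rds"))
    saveConfig(params, file.path(dir, "config.yaml"))
    manifest <- list(
        seed = params@seed,
        mcs = state@mcs,
        package = "vasculogen",
        version = as.character(utils::packageVersion("vasculogen")),
        configHash = unname(tools::md5sum(file.path(dir, "config.yaml"))),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE)
    invisible(dir)
}
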