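#' Sensitivity of network morphometry to the reaction rates
#'
#' Varies each reaction-rate parameter (binding rate, VEGF production,
#' matrix production, soluble-VEGF degradation) independently by the given
#' factors (10-fold decrease and increase by default), runs replicate
#' simulations per condition with the same seed list as the reference, and
#' reports each condition's morphometric summary next to the reference
#' row. Scaling a rate by 1 reproduces the reference exactly.
#'
#' @param scenario a [scenarioPreset()]-style list (`params`, `nCells`,
#'   `initMode`, `totalMcs`).
#' @param rates character vector of parameter names to vary.
#' @param factors multiplicative factors per condition.
#' @param seeds replicate seeds (3 by default, matching the published
#'   sensitivity design).
#' @return data.frame: one row per (condition, feature-summary), columns
#'   `parameter`, `factor`, plus mean/sd of every scalar feature.
#' @export
sweepSensitivity <- function(scenario,
                             rates = c("kBind", "alphaV", "alphaE",
                                       "gammaS"),
                             factors = c(0.1, 10),
                             seeds = 1:3) {
    conds <- rbind(data.frame(parameter = "reference", factor = 1),
                   expand.grid(parameter = rates, factor = factors,
                               stringsAsFactors = FALSE))
    rows <- lapply(seq_len(nrow(conds)), function(i) {
        p <- scenario$params
        if (conds$parameter[i] != "reference") {
            slot(p, conds$parameter[i]) <-
                slot(p, conds$parameter[i]) * conds$factor[i]
        }
        rep <- runRepetitions(p, scenario$nCells, scenario$initMode,
                              scenario$totalMcs, seeds = seeds)
        summarizeCondition(rep, cbind(conds[i, , drop = FALSE]))
    })
    do.call(rbind, rows)
}

#' Sensitivity of network morphometry to VEGF transport
#'
#' Runs replicate simulations under the three transport regimes of the
#' soluble field: no diffusion, normal diffusion, and a well-mixed system
#' in which soluble VEGF is redistributed homogeneously after every
#' reaction step.
#'
#' @inheritParams sweepSensitivity
#' @param modes transport modes to compare (see [integrateFields()]).
#' @return data.frame keyed by `mode` with mean/sd per feature.
#' @export
sweepDiffusivity <- function(scenario,
                             modes = c("no_diffusion", "normal",
                                       "well_mixed"),
                             seeds = 1:3) {
    rows <- lapply(modes, function(md) {
        rep <- runRepetitions(scenario$params, scenario$nCells,
                              scenario$initMode, scenario$totalMcs,
                              fieldMode = md, seeds = seeds)
        summarizeCondition(rep, data.frame(mode = md))
    })
    do.call(rbind, rows)
}

#' Sweep of the bound/soluble chemotaxis split
#'
#' Varies the fraction of the total chemotactic strength assigned to bound
#' VEGF over [0, 1], holding the total fixed (muB = ratio * muTotal,
#' muS = muTotal - muB), and records the morphometric summary at each
#' ratio. Network formation degrades when soluble VEGF carries the
#' signal, since a well-diffused cue carries no spatially restricted
#' information.
#'
#' @inheritParams sweepSensitivity
#' @param ratios values of muB/muTotal to test.
#' @return data.frame keyed by `ratio` with mean/sd per feature.
#' @export
sweepChemotaxisRatio <- function(scenario,
                                 ratios = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                                 seeds = 1:3) {
    rows <- lapply(ratios, function(rt) {
        p <- scenario$params
        p@muB <- rt * p@muTotal
        p@muS <- p@muTotal - p@muB
        rep <- runRepetitions(p, scenario$nCells, scenario$initMode,
                              scenario$totalMcs, seeds = seeds)
        summarizeCondition(rep, data.frame(ratio = rt))
    })
    do.call(rbind, rows)
}

#' Morphometric dependence on cell density
#'
#' Varies the number of cells at fixed tissue size, runs replicates per
#' density, and locates the three critical points of the density response:
#' the percolation onset (midpoint between the last density at which the
#' majority of replicates fails to percolate and the first at which it
#' does), the node-count maximum, and the lacuna-count maximum (argmax of
#' the replicate-averaged curves).
#'
#' @inheritParams sweepSensitivity
#' @param cellCounts cell numbers to test (ascending).
#' @return list with `table` (per-density summaries incl. density in
#'   cells/mm^2) and `critical` (named list: `percolationOnset`,
#'   `nodeOptimum`, `lacunaOptimum`, each in cells/mm^2, NA when outside
#'   the swept range).
#' @export
sweepDensity <- function(scenario, cellCounts, seeds = 1:3) {
    cellCounts <- sort(as.integer(cellCounts))
    p <- scenario$params
    areaMm2 <- (p@latticeSide * p@pixelSize / 1000)^2
    rows <- lapply(cellCounts, function(nc) {
        rep <- runRepetitions(p, nc, scenario$initMode, scenario$totalMcs,
                              seeds = seeds)
        out <- summarizeCondition(rep, data.frame(nCells = nc))
        out$density <- nc / areaMm2
        out$fracPercolative <- mean(rep$records$percolative)
        out
    })
    tab <- do.call(rbind, rows)
    perc <- tab$fracPercolative >= 0.5
    onset <- if (any(perc) && !perc[1]) {
        k <- which(perc)[1]
        (tab$density[k - 1] + tab$density[k]) / 2
    } else if (all(perc)) tab$density[1] else NA_real_
    critical <- list(
        percolationOnset = onset,
        nodeOptimum = tab$density[which.max(tab$nNodes_mean)],
        lacunaOptimum = tab$density[which.max(tab$nLacunae_mean)])
    list(table = tab, critical = critical)
}

# One summary row per condition: <feature>_mean / <feature>_sd columns.
summarizeCondition <- function(rep, keyRow) {
    s <- rep$summary
    vals <- c(s$mean, s$sd)
    names(vals) <- c(paste0(s$feature, "_mean"), paste0(s$feature, "_sd"))
    cbind(keyRow, as.data.frame(as.list(vals)), row.names = NULL)
}
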