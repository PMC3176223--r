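#' Run a coupled Potts/reaction-diffusion simulation
#'
#' Seeds cells (unless a `state` to resume from is given), then alternates
#' one Monte Carlo step of cell dynamics with one MCS worth of field
#' integration using the current cell mask, for `totalMcs` steps. The run
#' is fully reproducible from `params@seed`: the seed is set once at the
#' start and all stochastic draws (semi-random placement, site/neighbor
#' choice, Metropolis acceptance) consume the single resulting stream, so
#' a run resumed from a snapshot is bitwise-identical to an uninterrupted
#' one.
#'
#' @param params a [ModelParams-class].
#' @param nCells number of cells to seed.
#' @param initMode `"regular"` or `"semi_random"` initial mesh.
#' @param totalMcs number of Monte Carlo steps (0 returns the initial
#'   configuration only).
#' @param fieldMode transport mode passed to [integrateFields()].
#' @param snapshotEvery capture a snapshot of `sigma` every this many MCS
#'   (`NULL` or 0 disables; the initial state is always snapshot 1 when
#'   enabled).
#' @param storeFields also keep the field state in each snapshot.
#' @param state,fields resume from this state instead of seeding (the RNG is
#'   then left untouched, continuing the caller's stream).
#' @return a [SimulationRun-class].
#' @examples
#' sc <- scenarioPreset("sweep-scaled")
#' run <- runSimulation(sc$params, sc$nCells, totalMcs = 2L)
#' run@state@mcs
#' @export
runSimulation <- function(params, nCells, initMode = "regular",
                          totalMcs, fieldMode = "normal",
                          snapshotEvery = NULL, storeFields = FALSE,
                          state = NULL, fields = NULL) {
    if (is.null(state)) {
        set.seed(params@seed)
        state <- initializeCells(nCells, initMode, params)
        fields <- emptyFields(params)
    } else if (is.null(fields)) {
        stop("when resuming from 'state', 'fields' must be given too")
    }
    nCells <- nrow(state@cells)
    snaps <- list()
    takeSnap <- function(st, fl) {
        rec <- list(mcs = st@mcs, sigma = st@sigma)
        if (storeFields) rec$fields <- fl
        snaps[[length(snaps) + 1L]] <<- rec
    }
    doSnap <- !is.null(snapshotEvery) && snapshotEvery > 0
    if (doSnap) takeSnap(state, fields)
    if (totalMcs > 0) {
        for (t in seq_len(totalMcs)) {
            state <- monteCarloStep(state, fields, params, 1L)
            fields <- integrateFields(fields, cellMask(state), params,
                                      params@mcsSeconds, fieldMode)
            if (doSnap && state@mcs %% snapshotEvery == 0)
                takeSnap(state, fields)
        }
    }
    new("SimulationRun", params = params, state = state, fields = fields,
        snapshots = snaps, nCells = as.integer(nCells),
        initMode = initMode, fieldMode = fieldMode)
}

#' Replicate runs with independent seeds
#'
#' Runs the same scenario for each seed, analyzes the final cell mask with
#' [analyzePattern()], and tabulates per-replicate features with their mean
#' and standard deviation.
#'
#' @inheritParams runSimulation
#' @param seeds integer vector of RNG seeds, one replicate each.
#' @param ... forwarded to [analyzePattern()].
#' @return list with `records` (one row per replicate, scalar features),
#'   `summary` (feature, mean, sd; sd is 0 for a single replicate) and
#'   `masks` (final [BinaryPattern-class] per replicate).
#' @export
runRepetitions <- function(params, nCells, initMode = "regular",
                           totalMcs, fieldMode = "normal",
                           seeds = seq_len(10L), ...) {
    stopifnot(length(seeds) >= 1)
    rows <- list()
    masks <- list()
    for (i in seq_along(seeds)) {
        p <- params
        p@seed <- as.integer(seeds[i])
        run <- runSimulation(p, nCells, initMode, totalMcs, fieldMode)
        mask <- cellMask(run@state)
        rec <- analyzePattern(mask, state = run@state, params = p, ...)
        row <- as.data.frame(rec)
        row$seed <- seeds[i]
        rows[[i]] <- row
        masks[[i]] <- mask
    }
    records <- do.call(rbind, rows)
    for (nm in names(records))
        if (is.logical(records[[nm]])) records[[nm]] <- as.numeric(records[[nm]])
    num <- vapply(records, is.numeric, logical(1)) & names(records) != "seed"
    summary <- data.frame(
        feature = names(records)[num],
        mean = vapply(records[num], mean, numeric(1)),
        sd = if (length(seeds) > 1)
            vapply(records[num], stats::sd, numeric(1)) else
            rep(0, sum(num)),
        row.names = NULL)
    list(records = records, summary = summary, masks = masks)
}

#' Time-resolved morphometrics of a simulation run
#'
#' For every stored snapshot, computes the number of isolated cellular
#' structures (Betti 0), the number of lacunae (Betti 1), the percolation
#' flag and, optionally, the normalized cell length distribution. Also
#' returns an occupancy map: the mean of the binary masks over a given MCS
#' window, visualizing which pixels were stably covered during remodelling.
#'
#' @param run a [SimulationRun-class] produced with `snapshotEvery` set.
#' @param cellLengthsAt MCS values (matched to snapshot times) at which to
#'   record normalized cell lengths; `NULL` for none.
#' @param occupancyWindow length-2 MCS interval for the occupancy map;
#'   `NULL` averages over all snapshots.
#' @param minLacunaArea smallest hole area scored as a lacuna (see
#'   [analyzePattern()]).
#' @return list with `series` (data.frame: mcs, nComponents, nLacunae,
#'   percolative), `cellLengths` (named list of numeric vectors), and
#'   `occupancy` (numeric matrix in [0, 1]).
#' @export
trackDynamics <- function(run, cellLengthsAt = NULL, occupancyWindow = NULL,
                          minLacunaArea = 4L) {
    if (!length(run@snapshots))
        stop("run has no snapshots; rerun with 'snapshotEvery'")
    px <- run@params@pixelSize
    rows <- lapply(run@snapshots, function(sn) {
        pat <- new("BinaryPattern",
                   mask = matrix(as.integer(sn$sigma > 0L), nrow(sn$sigma)),
                   pixelSize = px)
        data.frame(mcs = sn$mcs,
                   nComponents = countComponents(pat),
                   nLacunae = countLacunae(pat, minArea = minLacunaArea),
                   percolative = isPercolative(pat))
    })
    series <- do.call(rbind, rows)
    lengths <- list()
    if (!is.null(cellLengthsAt)) {
        for (tt in cellLengthsAt) {
            k <- which(vapply(run@snapshots, `[[`, 0, "mcs") == tt)
            if (!length(k))
                stop(sprintf("no snapshot at MCS %d", tt))
            sn <- run@snapshots[[k[1]]]
            st <- stateFromSigma(sn$sigma, run@params)
            lengths[[as.character(tt)]] <- cellLengths(st, run@params)
        }
    }
    times <- vapply(run@snapshots, `[[`, 0, "mcs")
    if (is.null(occupancyWindow)) occupancyWindow <- range(times)
    inWin <- times >= occupancyWindow[1] & times <= occupancyWindow[2]
    if (!any(inWin)) stop("occupancy window contains no snapshots")
    occ <- Reduce(`+`, lapply(run@snapshots[inWin],
                              function(sn) (sn$sigma > 0L) + 0)) / sum(inWin)
    list(series = series, cellLengths = lengths, occupancy = occ)
}

# Rebuild a SimulationState (with recounted areas) from a stored sigma grid.
stateFromSigma <- function(sigma, params) {
    idx <- sort(unique(as.vector(sigma)))
    idx <- idx[idx > 0L]
    areas <- if (length(idx)) tabulate(sigma[sigma > 0L], nbins = max(idx))
             else integer()
    cells <- data.frame(index = idx,
                        type = rep("angioblast", length(idx)),
                        area = as.integer(areas[idx]))
    new("SimulationState", sigma = sigma, cells = cells, mcs = 0L,
        pixelSize = params@pixelSize)
}

#' First network-closure time of a dynamics run
#'
#' Runs the scenario in chunks, checking the cell mask every `checkEvery`
#' MCS, and reports the first checkpoint at which the pattern is a single
#' 8-connected component and percolates in both directions.
#'
#' @inheritParams runSimulation
#' @param maxMcs give up after this many MCS.
#' @param checkEvery morphometric check interval, MCS.
#' @return the closure time in MCS, or `NA` if not reached by `maxMcs`.
#' @export
networkClosureTime <- function(params, nCells, initMode = "regular",
                               fieldMode = "normal", maxMcs = 1500L,
                               checkEvery = 100L) {
    run <- runSimulation(params, nCells, initMode, totalMcs = 0L,
                         fieldMode = fieldMode)
    state <- run@state
    fields <- run@fields
    t <- 0L
    while (t < maxMcs) {
        step <- min(checkEvery, maxMcs - t)
        run <- runSimulation(params, nCells, initMode, totalMcs = step,
                             fieldMode = fieldMode, state = state,
                             fields = fields)
        state <- run@state
        fields <- run@fields
        t <- t + step
        pat <- cellMask(state)
        if (countComponents(pat) == 1L && isPercolative(pat))
            return(t)
    }
    NA_integer_
}
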