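#' @include AllClasses.R landscape.R
NULL

#' Build an arithmetic temperature ladder
#'
#' Bath temperatures \code{T[n] = T0 + dT * n} for \code{n = 0 .. count - 1}.
#' The canonical replica-exchange schedule uses 24 baths from 290 K in 10 K
#' steps, ending at 520 K.
#'
#' @param T0 base temperature in kelvin (> 0).
#' @param dT ladder spacing in kelvin (> 0).
#' @param count number of heat baths (>= 1).
#' @return A \code{\link{TemperatureLadder}}.
#' @examples
#' temperatures(buildLadder(290, 10, 24))  # 290, 300, ..., 520
#' @export
buildLadder <- function(T0 = 290, dT = 10, count = 24L) {
    if (T0 <= 0 || dT <= 0) stop("T0 and dT must be positive")
    if (count < 1) stop("count must be >= 1")
    new("TemperatureLadder", T0 = as.numeric(T0), dT = as.numeric(dT),
        count = as.integer(count),
        temperatures = T0 + dT * (seq_len(count) - 1))
}

#' Swap-attempt and snapshot arithmetic
#'
#' \code{countSwapAttempts} is the number of times a swap of one alternating
#' pairing of all baths is attempted: \code{floor(totalLength /
#' swapInterval)}. \code{countSnapshots} is the number of frames stored per
#' bath after discarding the equilibration span:
#' \code{floor((totalLength - equilibration) / snapshotInterval)}.
#'
#' @param totalLength total run length in time units.
#' @param swapInterval,snapshotInterval intervals in the same units (> 0).
#' @param equilibration leading discarded span.
#' @return An integer count.
#' @examples
#' countSwapAttempts(1.2e6, 20)        # 60000
#' countSnapshots(1.2e6, 20, 2e5)      # 50000
#' @export
countSwapAttempts <- function(totalLength, swapInterval) {
    if (swapInterval <= 0) stop("swapInterval must be > 0")
    as.integer(floor(totalLength / swapInterval))
}

#' @rdname countSwapAttempts
#' @export
countSnapshots <- function(totalLength, snapshotInterval, equilibration = 0) {
    if (snapshotInterval <= 0) stop("snapshotInterval must be > 0")
    if (equilibration < 0 || equilibration >= totalLength)
        stop("need 0 <= equilibration < totalLength")
    as.integer(floor((totalLength - equilibration) / snapshotInterval))
}

#' Metropolis exchange probability for a replica swap
#'
#' The canonical acceptance rule for exchanging configurations between baths
#' at temperatures \code{Ti} and \code{Tj}:
#' \code{min(1, exp((1/kTi - 1/kTj) (Ei - Ej)))}.
#'
#' @param Ei,Ej current energies (kcal/mol) of the two baths.
#' @param Ti,Tj bath temperatures in kelvin (\code{Ti != Tj}).
#' @return Acceptance probability in [0, 1].
#' @export
swapAcceptProb <- function(Ei, Ej, Ti, Tj) {
    if (any(Ti == Tj)) stop("Ti and Tj must differ")
    if (!all(is.finite(c(Ei, Ej)))) stop("non-finite energy")
    pmin(1, exp((1 / (kBoltzmann * Ti) - 1 / (kBoltzmann * Tj)) * (Ei - Ej)))
}

#' Attempt one replica swap between two baths
#'
#' Draws a uniform random number and applies the Metropolis exchange rule
#' (\code{\link{swapAcceptProb}}). On acceptance the coordinate states are
#' exchanged and the energies follow their coordinates.
#'
#' @param stateI,stateJ lists with elements \code{coords} (numeric vector)
#'   and \code{energy} (kcal/mol).
#' @param Ti,Tj bath temperatures in kelvin.
#' @return A list with \code{accepted} (logical), \code{prob}, and the
#'   (possibly exchanged) \code{stateI}, \code{stateJ}.
#' @export
attemptPairSwap <- function(stateI, stateJ, Ti, Tj) {
    p <- swapAcceptProb(stateI$energy, stateJ$energy, Ti, Tj)
    accepted <- runif(1) < p
    if (accepted) {
        tmp <- stateI
        stateI <- stateJ
        stateJ <- tmp
    }
    list(accepted = accepted, prob = p, stateI = stateI, stateJ = stateJ)
}

#' Run replica-exchange Metropolis sampling over a variant landscape
#'
#' Simulates all baths of the ladder simultaneously. Within each bath, one
#' time unit is one Metropolis sweep (a single-coordinate proposal per
#' torsion, plus an occasional symmetric whole-torus jump). Every
#' \code{swapInterval} units, one randomly chosen pairing parity of adjacent
#' baths -- even pairs (1,2),(3,4),... or odd pairs (2,3),(4,5),... -- is
#' attempted with the Metropolis exchange rule. Snapshots of the requested
#' baths are stored every \code{snapshotInterval} units after the
#' equilibration span.
#'
#' @param landscape a \code{\link{VariantLandscape}}.
#' @param ladder a \code{\link{TemperatureLadder}}.
#' @param config a \code{\link{SamplerConfig}}; its seed determines the
#'   entire random stream (identical seeds give identical frame streams).
#' @param keepTemperatures temperatures (kelvin) whose snapshot sets are
#'   stored; \code{NULL} stores every bath.
#' @return A \code{\link{ParallelTemperingRun}}.
#' @examples
#' l <- VariantLandscape("wt", list(Basin("a", c(0, 0), 5, 25)))
#' run <- runParallelTempering(l, buildLadder(290, 10, 3),
#'     SamplerConfig(2000, 20, 20, 400, seed = 7), keepTemperatures = 310)
#' snapshotAt(run, 310)
#' @export
runParallelTempering <- function(landscape, ladder, config = SamplerConfig(),
                                 keepTemperatures = NULL) {
    p <- landscapeParams(landscape)
    d <- ncol(p$centers)
    if (d < 1L) stop("empty system: landscape has no mobile coordinates")
    tt <- temperatures(ladder)
    if (is.null(keepTemperatures)) keepTemperatures <- tt
    keepIdx <- match(keepTemperatures, tt)
    if (anyNA(keepIdx))
        stop("keepTemperatures must be bath temperatures of the ladder")

    # deterministic start: deepest live basin center (first basin if none)
    live <- which(p$depths > 0)
    init <- if (length(live)) p$centers[live[which.max(p$depths[live])], ]
            else p$centers[1, ]

    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(config@seed)
    res <- pt_run_cpp(p$centers, p$depths, p$widths, tt, kBoltzmann,
                      as.integer(config@totalLength),
                      as.integer(config@swapInterval),
                      as.integer(config@snapshotInterval),
                      as.integer(config@equilibration),
                      config@stepSize, config@jumpProb,
                      as.numeric(init), as.integer(keepIdx))

    times <- config@equilibration +
        config@snapshotInterval * seq_len(res$n_frames)
    snaps <- lapply(seq_along(keepIdx), function(j)
        new("SnapshotSet", variantId = landscape@variantId,
            temperature = tt[keepIdx[j]], frames = res$frames[[j]],
            times = times))
    names(snaps) <- as.character(tt[keepIdx])

    new("ParallelTemperingRun", variantId = landscape@variantId,
        snapshots = snaps, ladder = ladder, config = config,
        swapAttempts = as.integer(res$attempts),
        swapAccepts = as.integer(res$accepts))
}

#' Basin occupancies of a snapshot ensemble
#'
#' Assigns every frame to the nearest basin center (angular distance, ties
#' to the lower basin index) and returns the occupancy fractions --
#' the sampled counterpart of \code{\link{exactPopulations}}.
#'
#' @param snapshots a \code{\link{SnapshotSet}}.
#' @param landscape the \code{\link{VariantLandscape}} that was sampled.
#' @return Named numeric vector of occupancy fractions summing to 1.
#' @export
basinOccupancy <- function(snapshots, landscape) {
    p <- landscapeParams(landscape)
    X <- frames(snapshots)
    d2 <- vapply(seq_len(nrow(p$centers)), function(b)
        rowSums(wrapAngle(sweep(X, 2, p$centers[b, ]))^2), numeric(nrow(X)))
    nearest <- max.col(-d2, ties.method = "first")
    setNames(tabulate(nearest, nbins = nrow(p$centers)) / nrow(X),
             basinIds(landscape))
}
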