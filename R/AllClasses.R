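#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------- LoopSpec

#' Loop specification of a peptide aptamer
#'
#' Describes where the variable loop sits in the parental sequence: the loop
#' proper, the flanking residues included in the mutagenized region, and the
#' rigid scaffold positions used as the superposition reference. Defaults
#' follow the parental aptamer convention: loop at residues 35-44 with four
#' flanking residues on each side.
#'
#' @param parentSequence one-letter amino-acid string of the parent.
#' @param loopStart,loopEnd 1-based first/last residue of the variable loop.
#' @param flankWidth number of residues on each side of the loop included in
#'   the mutagenized region.
#' @param fixedReferencePositions positions treated as rigid scaffold for
#'   superposition; must be disjoint from the mutagenized region. Defaults to
#'   all positions outside the region.
#'
#' @return A \code{LoopSpec} object.
#' @examples
#' sp <- defaultLoopSpec()
#' loopRegion(sp)
#' @aliases LoopSpec-class
#' @export
LoopSpec <- function(parentSequence, loopStart = 35L, loopEnd = 44L,
                     flankWidth = 4L, fixedReferencePositions = NULL) {
    n <- nchar(parentSequence)
    region <- seq.int(max(1L, loopStart - flankWidth),
                      min(n, loopEnd + flankWidth))
    if (is.null(fixedReferencePositions))
        fixedReferencePositions <- setdiff(seq_len(n), region)
    new("LoopSpec", parentSequence = as.character(parentSequence),
        loopStart = as.integer(loopStart), loopEnd = as.integer(loopEnd),
        flankWidth = as.integer(flankWidth),
        fixedReferencePositions = as.integer(fixedReferencePositions))
}

setClass("LoopSpec",
    representation(parentSequence = "character", loopStart = "integer",
                   loopEnd = "integer", flankWidth = "integer",
                   fixedReferencePositions = "integer"),
    validity = function(object) {
        n <- nchar(object@parentSequence)
        msg <- character()
        if (length(object@parentSequence) != 1L || n < 1L)
            msg <- c(msg, "parentSequence must be a single non-empty string")
        if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", object@parentSequence))
            msg <- c(msg, "parentSequence must use one-letter amino-acid codes")
        if (object@loopStart >= object@loopEnd)
            msg <- c(msg, "loopStart must be < loopEnd")
        if (object@loopStart < 1L || object@loopEnd > n)
            msg <- c(msg, "loop positions must lie within the sequence")
        if (object@flankWidth < 0L)
            msg <- c(msg, "flankWidth must be >= 0")
        region <- seq.int(max(1L, object@loopStart - object@flankWidth),
                          min(n, object@loopEnd + object@flankWidth))
        if (length(intersect(object@fixedReferencePositions, region)) > 0L)
            msg <- c(msg, "fixedReferencePositions overlap the mutagenized region")
        if (length(msg)) msg else TRUE
    })

#' Region labels of a loop specification
#'
#' @param spec a \code{\link{LoopSpec}}.
#' @return \code{loopRegion}: integer positions of loop plus flanks;
#'   \code{regionLabels}: a character vector over all positions with values
#'   \code{"loop"}, \code{"flank"} or \code{"scaffold"}.
#' @export
loopRegion <- function(spec) {
    n <- nchar(spec@parentSequence)
    seq.int(max(1L, spec@loopStart - spec@flankWidth),
            min(n, spec@loopEnd + spec@flankWidth))
}

#' @rdname loopRegion
#' @export
regionLabels <- function(spec) {
    n <- nchar(spec@parentSequence)
    lab <- rep("scaffold", n)
    lab[loopRegion(spec)] <- "flank"
    lab[spec@loopStart:spec@loopEnd] <- "loop"
    lab
}

## ------------------------------------------------------------------- Basin

#' Conformational basin of a surrogate loop landscape
#'
#' A negative Gaussian well in angular (torsion) space: energy contribution
#' \code{-depth * exp(-dist^2 / (2 width^2))} where \code{dist} is the
#' wrapped Euclidean distance (degrees) to the basin center.
#'
#' @param id basin label.
#' @param center numeric vector of torsion coordinates (degrees).
#' @param depth well depth in kcal/mol (> 0).
#' @param width well width in degrees (> 0).
#' @return A \code{Basin} object.
#' @aliases Basin-class
#' @export
Basin <- function(id, center, depth, width) {
    new("Basin", id = as.character(id), center = as.numeric(center),
        depth = as.numeric(depth), width = as.numeric(width))
}

setClass("Basin",
    representation(id = "character", center = "numeric",
                   depth = "numeric", width = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@depth) != 1L || !is.finite(object@depth) ||
            object@depth <= 0) msg <- c(msg, "depth must be a positive scalar")
        if (length(object@width) != 1L || !is.finite(object@width) ||
            object@width <= 0) msg <- c(msg, "width must be a positive scalar")
        if (length(object@center) < 1L || !all(is.finite(object@center)))
            msg <- c(msg, "center must be a finite coordinate vector")
        if (length(msg)) msg else TRUE
    })

## -------------------------------------------------------- VariantLandscape

#' Surrogate energy landscape of one aptamer variant
#'
#' The loop of a variant is modelled on a periodic torsion torus whose energy
#' is a sum of negative Gaussian wells (\code{\link{Basin}}), one per
#' conformational basin. A mutation's effect is encoded as a per-basin
#' perturbation (kcal/mol) subtracted from the well depth; a perturbation
#' reaching the depth abolishes the basin for that variant.
#'
#' @param variantId variant label (e.g. \code{"R5G42"}, \code{"F39I"}).
#' @param basins list of \code{\link{Basin}} objects (shared coordinates).
#' @param perturbations named numeric vector, basin id -> kcal/mol offset.
#' @param temperature analysis temperature in kelvin.
#' @return A \code{VariantLandscape}.
#' @examples
#' l <- VariantLandscape("wt", list(Basin("a", c(0, 0), 5, 25)))
#' landscapeEnergy(l, c(0, 0))
#' @aliases VariantLandscape-class
#' @export
VariantLandscape <- function(variantId, basins, perturbations = numeric(0),
                             temperature = 310) {
    new("VariantLandscape", variantId = as.character(variantId),
        basins = basins, perturbations = perturbations,
        temperature = as.numeric(temperature))
}

setClass("VariantLandscape",
    representation(variantId = "character", basins = "list",
                   perturbations = "numeric", temperature = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@basins) < 1L)
            msg <- c(msg, "at least one basin is required")
        if (!all(vapply(object@basins, is, logical(1), "Basin")))
            msg <- c(msg, "basins must be a list of Basin objects")
        else {
            ids <- vapply(object@basins, function(b) b@id, character(1))
            if (anyDuplicated(ids))
                msg <- c(msg, "basin ids must be unique")
            dims <- vapply(object@basins, function(b) length(b@center),
                           integer(1))
            if (length(unique(dims)) > 1L)
                msg <- c(msg, "basin centers must share one dimensionality")
            if (length(object@perturbations) &&
                !all(names(object@perturbations) %in% ids))
                msg <- c(msg, "perturbation names must match basin ids")
        }
        if (length(object@temperature) != 1L || object@temperature <= 0)
            msg <- c(msg, "temperature must be a positive scalar (kelvin)")
        if (length(msg)) msg else TRUE
    })

#' @rdname loopscape-generics
#' @export
setMethod("basins", "VariantLandscape", function(x) x@basins)

#' @rdname loopscape-generics
#' @export
setMethod("variantId", "VariantLandscape", function(x) x@variantId)

#' @rdname loopscape-generics
#' @export
setMethod("effectiveDepths", "VariantLandscape", function(x) {
    ids <- basinIds(x)
    depth <- vapply(x@basins, function(b) b@depth, numeric(1))
    pert <- setNames(numeric(length(ids)), ids)
    if (length(x@perturbations))
        pert[names(x@perturbations)] <- x@perturbations
    setNames(depth - pert, ids)
})

#' Basin ids of a landscape
#' @param landscape a \code{\link{VariantLandscape}}.
#' @return Character vector of basin ids in declaration order.
#' @export
basinIds <- function(landscape) {
    vapply(landscape@basins, function(b) b@id, character(1))
}

setMethod("show", "VariantLandscape", function(object) {
    d <- length(object@basins[[1]]@center)
    eff <- effectiveDepths(object)
    cat("VariantLandscape '", object@variantId, "': ",
        length(object@basins), " basins on a ", d,
        "-dimensional torsion torus\n", sep = "")
    cat("  effective depths (kcal/mol): ",
        paste(sprintf("%s=%.2f", names(eff), eff), collapse = ", "),
        "\n  analysis temperature: ", object@temperature, " K\n", sep = "")
})

## ------------------------------------------------------------ PlantedTruth

#' Planted ground truth of a synthetic variant panel
#'
#' Exact Boltzmann populations (grid summation) of every basin of every
#' variant at the analysis temperature, the basin designated as the binder
#' conformer for each target, and the population threshold that converts
#' populations into binding calls.
#'
#' @aliases PlantedTruth-class
#' @name PlantedTruth
NULL

setClass("PlantedTruth",
    representation(populations = "data.frame", designated = "character",
                   threshold = "numeric"),
    validity = function(object) {
        msg <- character()
        need <- c("variant", "basin", "population")
        if (!all(need %in% names(object@populations)))
            msg <- c(msg, "populations needs columns variant, basin, population")
        else {
            s <- tapply(object@populations$population,
                        object@populations$variant, sum)
            if (any(abs(s - 1) > 1e-9))
                msg <- c(msg, "per-variant populations must sum to 1 (+/- 1e-9)")
        }
        if (length(msg)) msg else TRUE
    })

setMethod("show", "PlantedTruth", function(object) {
    cat("PlantedTruth:", length(unique(object@populations$variant)),
        "variants x", length(unique(object@populations$basin)), "basins;",
        "binder basins:",
        paste(names(object@designated), object@designated, sep = "->",
              collapse = ", "),
        sprintf("; threshold %.3f\n", object@threshold))
})

## --------------------------------------------------------- PhenotypeMatrix

#' Variant-by-target binding phenotype matrix
#'
#' Yeast two-hybrid binding calls: \code{"binds"}, \code{"no_binding"} or
#' \code{"undetermined"}; rows are variants, columns targets.
#'
#' @param calls character matrix with row names (variants) and column names
#'   (targets) and values in the three-level call vocabulary.
#' @return A \code{PhenotypeMatrix}.
#' @examples
#' pm <- PhenotypeMatrix(matrix(c("binds", "no_binding"), 1, 2,
#'   dimnames = list("v1", c("A", "B"))))
#' binders(pm, "A")
#' @aliases PhenotypeMatrix-class
#' @export
PhenotypeMatrix <- function(calls) {
    new("PhenotypeMatrix", calls = calls)
}

setClass("PhenotypeMatrix",
    representation(calls = "matrix"),
    validity = function(object) {
        msg <- character()
        ok <- c("binds", "no_binding", "undetermined")
        if (!is.character(object@calls) || !all(object@calls %in% ok))
            msg <- c(msg, "calls must be 'binds', 'no_binding' or 'undetermined'")
        if (is.null(rownames(object@calls)) || is.null(colnames(object@calls)))
            msg <- c(msg, "calls must have variant row names and target column names")
        if (length(msg)) msg else TRUE
    })

#' @rdname loopscape-generics
#' @export
setMethod("phenotypeCalls", "PhenotypeMatrix", function(x) x@calls)

#' @rdname loopscape-generics
#' @export
setMethod("binders", "PhenotypeMatrix", function(x, target) {
    if (!target %in% colnames(x@calls))
        stop("unknown target: ", target)
    rownames(x@calls)[x@calls[, target] == "binds"]
})

#' @rdname loopscape-generics
#' @export
setMethod("nonBinders", "PhenotypeMatrix", function(x, target) {
    if (!target %in% colnames(x@calls))
        stop("unknown target: ", target)
    rownames(x@calls)[x@calls[, target] == "no_binding"]
})

setMethod("show", "PhenotypeMatrix", function(object) {
    cat("PhenotypeMatrix:", nrow(object@calls), "variants x",
        ncol(object@calls), "targets\n")
    print(object@calls)
})

## ------------------------------------------------------------ VariantPanel

#' Synthetic variant panel
#'
#' Bundle produced by \code{\link{makeVariantPanel}}: one surrogate landscape
#' per variant, the planted ground truth, and the phenotype matrix implied by
#' thresholding the true populations.
#'
#' @aliases VariantPanel-class
#' @name VariantPanel
NULL

setClass("VariantPanel",
    representation(landscapes = "list", truth = "PlantedTruth",
                   phenotype = "PhenotypeMatrix", loopSpec = "LoopSpec"))

#' @rdname loopscape-generics
#' @export
setMethod("landscapes", "VariantPanel", function(x) x@landscapes)

#' @rdname loopscape-generics
#' @export
setMethod("plantedTruth", "VariantPanel", function(x) x@truth)

#' @rdname loopscape-generics
#' @export
setMethod("phenotypeCalls", "VariantPanel", function(x) x@phenotype@calls)

setMethod("show", "VariantPanel", function(object) {
    cat("VariantPanel:", length(object@landscapes), "variants,",
        length(basinIds(object@landscapes[[1]])), "basins,",
        ncol(object@phenotype@calls), "targets\n")
})

## ------------------------------------------------------- TemperatureLadder

#' Arithmetic temperature ladder for parallel tempering
#'
#' Bath temperatures \code{T[n] = T0 + dT * n}, \code{n = 0 .. count - 1}.
#' The canonical schedule (290 K, 10 K, 24 baths) spans 290-520 K.
#'
#' @aliases TemperatureLadder-class
#' @name TemperatureLadder
NULL

setClass("TemperatureLadder",
    representation(T0 = "numeric", dT = "numeric", count = "integer",
                   temperatures = "numeric"),
    validity = function(object) {
        msg <- character()
        if (object@count < 1L) msg <- c(msg, "count must be >= 1")
        if (object@dT <= 0) msg <- c(msg, "dT must be > 0")
        if (object@T0 <= 0) msg <- c(msg, "T0 must be > 0")
        if (length(object@temperatures) != object@count ||
            is.unsorted(object@temperatures, strictly = TRUE))
            msg <- c(msg, "temperatures must be strictly increasing")
        if (length(msg)) msg else TRUE
    })

#' @rdname loopscape-generics
#' @export
setMethod("temperatures", "TemperatureLadder", function(x) x@temperatures)

setMethod("show", "TemperatureLadder", function(object) {
    cat("TemperatureLadder:", object@count, "baths,",
        object@temperatures[1], "K to",
        object@temperatures[object@count], "K (dT =", object@dT, "K)\n")
})

## ----------------------------------------------------------- SamplerConfig

#' Parallel-tempering run schedule
#'
#' Time is measured in abstract simulation units (one Metropolis sweep per
#' unit). The default schedule mirrors the canonical protocol: total length
#' 1.2e6 units with swap and snapshot attempts every 20 units and the first
#' 2e5 units discarded as equilibration, leaving 50,000 production frames
#' per bath.
#'
#' @param totalLength total run length in time units.
#' @param swapInterval units between replica-swap attempts.
#' @param snapshotInterval units between stored snapshots.
#' @param equilibration leading span discarded before snapshots are stored.
#' @param stepSize half-width (degrees) of the per-coordinate proposal.
#' @param jumpProb per-bath per-sweep probability of a whole-torus uniform
#'   jump proposal (symmetric, hence plain Metropolis); aids basin-to-basin
#'   mixing in deep-well landscapes.
#' @param seed integer seed for the run.
#' @return A \code{SamplerConfig}.
#' @aliases SamplerConfig-class
#' @export
SamplerConfig <- function(totalLength = 1.2e6, swapInterval = 20,
                          snapshotInterval = 20, equilibration = 2e5,
                          stepSize = 30, jumpProb = 0.5, seed = 1L) {
    new("SamplerConfig", totalLength = as.numeric(totalLength),
        swapInterval = as.numeric(swapInterval),
        snapshotInterval = as.numeric(snapshotInterval),
        equilibration = as.numeric(equilibration),
        stepSize = as.numeric(stepSize), jumpProb = as.numeric(jumpProb),
        seed = as.integer(seed))
}

setClass("SamplerConfig",
    representation(totalLength = "numeric", swapInterval = "numeric",
                   snapshotInterval = "numeric", equilibration = "numeric",
                   stepSize = "numeric", jumpProb = "numeric",
                   seed = "integer"),
    validity = function(object) {
        msg <- character()
        if (object@equilibration < 0 ||
            object@equilibration >= object@totalLength)
            msg <- c(msg, "need 0 <= equilibration < totalLength")
        if (object@swapInterval <= 0 ||
            object@swapInterval > object@totalLength)
            msg <- c(msg, "swapInterval must be in (0, totalLength]")
        if (object@snapshotInterval <= 0 ||
            object@snapshotInterval > object@totalLength)
            msg <- c(msg, "snapshotInterval must be in (0, totalLength]")
        if (object@stepSize <= 0) msg <- c(msg, "stepSize must be > 0")
        if (object@jumpProb < 0 || object@jumpProb > 1)
            msg <- c(msg, "jumpProb must be in [0, 1]")
        if (length(msg)) msg else TRUE
    })

setMethod("show", "SamplerConfig", function(object) {
    cat(sprintf(paste0("SamplerConfig: total %g, swap every %g, snapshot",
                       " every %g, equilibration %g (seed %d)\n"),
                object@totalLength, object@swapInterval,
                object@snapshotInterval, object@equilibration, object@seed))
})

## ------------------------------------------------------------- SnapshotSet

#' Time-ordered snapshot ensemble of one bath
#'
#' Frames of loop torsion coordinates saved from one heat bath of a
#' parallel-tempering run, with their simulation-time stamps.
#'
#' @aliases SnapshotSet-class
#' @name SnapshotSet
NULL

setClass("SnapshotSet",
    representation(variantId = "character", temperature = "numeric",
                   frames = "matrix", times = "numeric"),
    validity = function(object) {
        msg <- character()
        if (nrow(object@frames) != length(object@times))
            msg <- c(msg, "one time stamp per frame required")
        if (length(object@times) > 1L &&
            is.unsorted(object@times, strictly = TRUE))
            msg <- c(msg, "times must be strictly increasing")
        if (length(msg)) msg else TRUE
    })

#' @rdname loopscape-generics
#' @export
setMethod("frames", "SnapshotSet", function(x) x@frames)

#' @rdname loopscape-generics
#' @export
setMethod("frameTimes", "SnapshotSet", function(x) x@times)

#' @rdname loopscape-generics
#' @export
setMethod("variantId", "SnapshotSet", function(x) x@variantId)

#' @rdname loopscape-generics
#' @export
setMethod("bathTemperature", "SnapshotSet", function(x) x@temperature)

setMethod("show", "SnapshotSet", function(object) {
    cat("SnapshotSet '", object@variantId, "' at ", object@temperature,
        " K: ", nrow(object@frames), " frames x ", ncol(object@frames),
        " torsions\n", sep = "")
})

## --------------------------------------------------- ParallelTemperingRun

#' Result of a parallel-tempering run
#'
#' Holds one \code{\link{SnapshotSet}} per stored bath plus per-adjacent-pair
#' swap attempt/acceptance counters.
#'
#' @aliases ParallelTemperingRun-class
#' @name ParallelTemperingRun
NULL

setClass("ParallelTemperingRun",
    representation(variantId = "character", snapshots = "list",
                   ladder = "TemperatureLadder", config = "SamplerConfig",
                   swapAttempts = "integer", swapAccepts = "integer"),
    validity = function(object) {
        if (any(object@swapAccepts > object@swapAttempts))
            "swap acceptances exceed attempts" else TRUE
    })

#' @rdname loopscape-generics
#' @export
setMethod("snapshotAt", "ParallelTemperingRun", function(x, temperature) {
    i <- match(temperature, temperatures(x@ladder))
    if (is.na(i)) stop("temperature ", temperature, " K is not in the ladder")
    key <- as.character(temperature)
    if (!key %in% names(x@snapshots))
        stop("bath at ", temperature, " K was not stored in this run")
    x@snapshots[[key]]
})

#' @rdname loopscape-generics
#' @export
setMethod("temperatures", "ParallelTemperingRun",
          function(x) temperatures(x@ladder))

#' @rdname loopscape-generics
#' @export
setMethod("swapStatistics", "ParallelTemperingRun", function(x) {
    tt <- temperatures(x@ladder)
    n <- length(tt)
    if (n < 2L) return(data.frame(pair = character(0), attempts = integer(0),
                                  accepts = integer(0), rate = numeric(0)))
    data.frame(pair = paste(tt[-n], tt[-1], sep = "-"),
               attempts = x@swapAttempts, accepts = x@swapAccepts,
               rate = ifelse(x@swapAttempts > 0,
                             x@swapAccepts / x@swapAttempts, NA_real_))
})

setMethod("show", "ParallelTemperingRun", function(object) {
    cat("ParallelTemperingRun '", object@variantId, "': ",
        length(object@snapshots), " stored baths, ",
        sum(object@swapAttempts), " pairwise swap attempts (",
        sprintf("%.1f%%", 100 * sum(object@swapAccepts) /
                    max(1L, sum(object@swapAttempts))),
        " accepted)\n", sep = "")
})

## ---------------------------------------------------------- StructureFrame

#' Cartesian structure frame (3-D clustering mode)
#'
#' One snapshot represented by mobile loop pseudo-atoms plus the rigid
#' scaffold reference atoms used for superposition.
#'
#' @param variantId variant label.
#' @param time simulation-time stamp.
#' @param mobile numeric matrix (n x 3) of loop pseudo-atom coordinates.
#' @param reference numeric matrix (m x 3) of scaffold reference atoms.
#' @return A \code{StructureFrame}.
#' @aliases StructureFrame-class
#' @export
StructureFrame <- function(variantId, time, mobile, reference) {
    new("StructureFrame", variantId = as.character(variantId),
        time = as.numeric(time), mobile = as.matrix(mobile),
        reference = as.matrix(reference))
}

setClass("StructureFrame",
    representation(variantId = "character", time = "numeric",
                   mobile = "matrix", reference = "matrix"),
    validity = function(object) {
        msg <- character()
        if (ncol(object@mobile) != 3L || ncol(object@reference) != 3L)
            msg <- c(msg, "coordinates must be n x 3 matrices")
        if (nrow(object@mobile) < 1L)
            msg <- c(msg, "at least one mobile atom required")
        if (!all(is.finite(object@mobile)) || !all(is.finite(object@reference)))
            msg <- c(msg, "coordinates must be finite")
        if (length(msg)) msg else TRUE
    })

## --------------------------------------------------------- ConformerCatalog

#' Catalog of loop conformers from pooled clustering
#'
#' Leader-clustering result over frames pooled across variants: cluster
#' centers (the founding frames), a per-frame conformer assignment, and the
#' frame metadata (variant, time). Conformers are labelled 1..K by
#' descending pooled population, ties by creation order.
#'
#' @aliases ConformerCatalog-class
#' @name ConformerCatalog
NULL

setClass("ConformerCatalog",
    representation(centers = "matrix", assignment = "integer",
                   variant = "character", time = "numeric",
                   cutoff = "numeric", mode = "character",
                   denom = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@assignment) != length(object@variant) ||
            length(object@assignment) != length(object@time))
            msg <- c(msg, "assignment, variant and time must align")
        if (length(object@assignment) &&
            (min(object@assignment) < 1L ||
             max(object@assignment) > nrow(object@centers)))
            msg <- c(msg, "assignments must index the centers")
        if (object@cutoff <= 0) msg <- c(msg, "cutoff must be > 0")
        if (length(msg)) msg else TRUE
    })

#' @rdname loopscape-generics
#' @export
setMethod("assignments", "ConformerCatalog", function(x) x@assignment)

#' @rdname loopscape-generics
#' @export
setMethod("centers", "ConformerCatalog", function(x) x@centers)

#' @rdname loopscape-generics
#' @export
setMethod("cutoff", "ConformerCatalog", function(x) x@cutoff)

#' @rdname loopscape-generics
#' @export
setMethod("nConformers", "ConformerCatalog", function(x) nrow(x@centers))

#' @rdname loopscape-generics
#' @export
setMethod("conformerSizes", "ConformerCatalog", function(x) {
    tabulate(x@assignment, nbins = nrow(x@centers))
})

setMethod("show", "ConformerCatalog", function(object) {
    sz <- conformerSizes(object)
    cat("ConformerCatalog:", nrow(object@centers), "conformers over",
        length(object@assignment), "frames from",
        length(unique(object@variant)), "variants",
        sprintf("(cutoff %g, %s mode)\n", object@cutoff, object@mode))
    cat("  sizes:", paste(head(sz, 10), collapse = ", "),
        if (length(sz) > 10) "...", "\n")
})

## --------------------------------------------------------- BlockStatistics

#' Block-averaged population statistics
#'
#' Per-block population percentages of one conformer, their mean, and the
#' standard error of the mean \code{sqrt(sum((x - xbar)^2) / (n (n - 1)))}.
#'
#' @aliases BlockStatistics-class
#' @name BlockStatistics
NULL

setClass("BlockStatistics",
    representation(observations = "numeric", mean = "numeric",
                   sem = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@observations) < 2L)
            msg <- c(msg, "need at least two blocks")
        if (object@sem < 0) msg <- c(msg, "SEM must be >= 0")
        if (length(msg)) msg else TRUE
    })

setMethod("show", "BlockStatistics", function(object) {
    cat(sprintf("BlockStatistics: mean %.3f, SEM %.3f over %d blocks\n",
                object@mean, object@sem, length(object@observations)))
})

## --------------------------------------------------------- PopulationTable

#' Per-variant conformer population table
#'
#' For every (variant, conformer) pair: mean population percentage over
#' contiguous trajectory blocks, its SEM, the populated call (mean strictly
#' above twice the SEM), and the free energy relative to the variant's most
#' populated conformer, \code{-kT ln(P_i / P_max)} (NA where not populated).
#'
#' @aliases PopulationTable-class
#' @name PopulationTable
NULL

setClass("PopulationTable",
    representation(table = "data.frame", temperature = "numeric",
                   boltzmann = "numeric", nBlocks = "integer"),
    validity = function(object) {
        msg <- character()
        need <- c("variant", "conformer", "pop_pct", "sem_pct", "populated",
                  "dG_kcal_mol")
        if (!all(need %in% names(object@table)))
            msg <- c(msg, paste("table needs columns:",
                                paste(need, collapse = ", ")))
        else {
            s <- tapply(object@table$pop_pct, object@table$variant, sum)
            if (any(abs(s - 100) > 1e-6))
                msg <- c(msg, "per-variant populations must sum to 100")
            pop <- object@table[object@table$populated, , drop = FALSE]
            if (nrow(pop) && any(pop$dG_kcal_mol < -1e-9, na.rm = TRUE))
                msg <- c(msg, "dG must be >= 0")
        }
        if (length(msg)) msg else TRUE
    })

#' @describeIn PopulationTable coerce to a plain data frame.
#' @param x,row.names,optional,... standard \code{as.data.frame} arguments.
#' @export
setMethod("as.data.frame", "PopulationTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@table)

setMethod("show", "PopulationTable", function(object) {
    cat("PopulationTable at", object@temperature, "K:",
        length(unique(object@table$variant)), "variants x",
        length(unique(object@table$conformer)), "conformers,",
        object@nBlocks, "blocks\n")
    print(head(object@table, 8), row.names = FALSE)
    if (nrow(object@table) > 8) cat("  ...\n")
})

## --------------------------------------------------------- CandidateReport

#' Candidate binding conformers for one target
#'
#' Output of \code{\link{consensusConformers}}: the conformers populated in
#' every binder of the target, optionally filtered by an accessibility
#' threshold, minus those vetoed by being populated in a non-binder (unless
#' annotated veto-exempt). The accessibility cost of a candidate is its
#' maximum free energy over the binders.
#'
#' @aliases CandidateReport-class
#' @name CandidateReport
NULL

setClass("CandidateReport",
    representation(target = "character", binderSet = "character",
                   nonBinderSet = "character", considered = "integer",
                   candidateSet = "integer", cost = "numeric",
                   exclusionLog = "data.frame", dGmax = "numeric",
                   noBinders = "logical"),
    validity = function(object) {
        msg <- character()
        excl <- unique(object@exclusionLog$conformer)
        if (length(intersect(object@candidateSet, excl)) > 0L)
            msg <- c(msg, "candidates and exclusions must be disjoint")
        if (!setequal(union(object@candidateSet, excl), object@considered))
            msg <- c(msg, "every considered conformer must be a candidate or excluded")
        if (length(msg)) msg else TRUE
    })

#' @rdname loopscape-generics
#' @export
setMethod("candidates", "CandidateReport", function(x) x@candidateSet)

#' @rdname loopscape-generics
#' @export
setMethod("exclusions", "CandidateReport", function(x) x@exclusionLog)

setMethod("show", "CandidateReport", function(object) {
    cat("CandidateReport for target '", object@target, "'\n", sep = "")
    if (object@noBinders) {
        cat("  WARNING: no binders for this target; empty report\n")
        return(invisible(NULL))
    }
    cat("  binders:", paste(object@binderSet, collapse = ", "), "\n")
    cat("  non-binders:", paste(object@nonBinderSet, collapse = ", "), "\n")
    cat("  candidates:",
        if (length(object@candidateSet)) {
            cc <- object@cost[as.character(object@candidateSet)]
            paste(ifelse(is.na(cc),
                         sprintf("%d", object@candidateSet),
                         sprintf("%d (cost %.2f kcal/mol)",
                                 object@candidateSet, cc)),
                  collapse = ", ")
        } else "none", "\n")
    if (nrow(object@exclusionLog)) {
        cat("  excluded:\n")
        for (i in seq_len(nrow(object@exclusionLog)))
            cat("    conformer", object@exclusionLog$conformer[i], "-",
                object@exclusionLog$reason[i], "\n")
    }
})

## ------------------------------------------------------------ CloneLibrary

#' Synthetic mutant clone library
#'
#' Clone sequences (substitution-only mutants of the parent) together with
#' the true planted mutation list of each clone, for screen-analysis tests.
#'
#' @aliases CloneLibrary-class
#' @name CloneLibrary
NULL

setClass("CloneLibrary",
    representation(sequences = "AAStringSet", parent = "character",
                   loopSpec = "LoopSpec", truth = "list"),
    validity = function(object) {
        msg <- character()
        if (length(object@truth) != length(object@sequences))
            msg <- c(msg, "one truth record per clone required")
        w <- Biostrings::width(object@sequences)
        if (length(w) && any(w != nchar(object@parent)))
            msg <- c(msg, "clones must have the parent's length (substitution-only)")
        if (length(msg)) msg else TRUE
    })

#' @rdname loopscape-generics
#' @export
setMethod("cloneSequences", "CloneLibrary", function(x) x@sequences)

#' @rdname loopscape-generics
#' @export
setMethod("cloneTruth", "CloneLibrary", function(x) x@truth)

setMethod("show", "CloneLibrary", function(object) {
    nmut <- vapply(object@truth, nrow, integer(1))
    cat("CloneLibrary:", length(object@sequences), "clones of length",
        nchar(object@parent), sprintf("(mean %.2f planted mutations)\n",
                                      mean(nmut)))
})
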