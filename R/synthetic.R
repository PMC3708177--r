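#' @include AllClasses.R landscape.R
NULL

# internal: run code with a private RNG stream, restoring the caller's
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

#' Default loop specification
#'
#' A synthetic stand-in for the parental aptamer scaffold: a 105-residue
#' sequence (deterministic filler, not a natural protein) carrying the
#' anchor residues of the parental loop -- cysteines at 32 and 47, serine
#' 35, threonine 38, phenylalanine 39 and leucine 44 -- with the variable
#' loop at residues 35-44 and four flanking residues on each side.
#'
#' @return A \code{\link{LoopSpec}}.
#' @export
defaultLoopSpec <- function() {
    filler <- strsplit("ADEFGHIKLMNPQRSTVWYA", "")[[1]]  # cycle without Cys
    s <- rep(filler, length.out = 105)
    s[c(32, 47)] <- "C"
    s[35] <- "S"
    s[38] <- "T"
    s[39] <- "F"
    s[44] <- "L"
    LoopSpec(paste(s, collapse = ""), loopStart = 35, loopEnd = 44,
             flankWidth = 4)
}

# fixed well-separated center layouts on the 2-D torus (degrees); pairwise
# angular RMS separation >= 90
basinLayout2d <- list(
    NULL,
    rbind(c(0, 0), c(180, 0)),
    rbind(c(0, 0), c(120, 120), c(-120, -120)),
    rbind(c(0, 0), c(180, 0), c(0, 180), c(180, 180)),
    rbind(c(0, 0), c(180, 0), c(0, 180), c(180, 180), c(90, 90)),
    rbind(c(0, 0), c(180, 0), c(0, 180), c(180, 180), c(90, 90),
          c(-90, -90)))

#' Generate a synthetic variant panel with planted ground truth
#'
#' Builds one surrogate loop landscape per variant on a shared set of
#' well-separated conformational basins (negative Gaussian wells on a
#' torsion torus), plants a designated binder basin per target, and encodes
#' each variant's binding phenotype by abolishing the designated basin
#' (perturbation equal to the well depth) in non-binders while leaving it
#' untouched in binders. Non-designated basins receive small random depth
#' perturbations so populations vary across variants. The planted truth is
#' computed analytically by grid summation (\code{\link{exactPopulations}})
#' and the phenotype matrix is derived from it by thresholding the
#' designated basin's population -- so truth and phenotype are consistent
#' by construction, with no hidden randomness.
#'
#' By default the panel mirrors the classic five-variant design: the parent
#' binds both targets and each remaining variant binds exactly one, giving
#' three binders and two non-binders per target.
#'
#' @param spec a \code{\link{LoopSpec}} (sequence bookkeeping only).
#' @param nBasins number of basins (2-6).
#' @param targets character vector of target names (>= 1, at most
#'   \code{nBasins - 1} so every target gets its own designated basin and
#'   at least one basin stays shared).
#' @param seed integer seed; identical seeds give identical panels.
#' @param nVariants number of variants (>= 2).
#' @param variantIds optional variant labels (first is the parent).
#' @param binderPattern optional logical matrix (variants x targets); the
#'   default makes the parent bind everything and splits the rest.
#' @param width basin width in degrees.
#' @param depthRange range (kcal/mol) over which basin depths are evenly
#'   spaced, deepest first.
#' @param noise half-width (kcal/mol) of the uniform depth perturbation
#'   applied to non-designated basins of non-parent variants.
#' @param nTorsionPairs number of collective torsion pairs (coordinate
#'   dimension is twice this; default 1, i.e. a 2-D torus).
#' @param popThreshold population fraction of the designated basin above
#'   which a variant is called a binder (the two-hybrid detection
#'   threshold of the generator; a free parameter, not an inferred
#'   biological constant).
#' @param gridResolution grid spacing (degrees) for the analytic truth.
#' @param temperature analysis temperature in kelvin.
#' @return A \code{\link{VariantPanel}}.
#' @examples
#' panel <- makeVariantPanel(seed = 1)
#' phenotypeCalls(panel)
#' @export
makeVariantPanel <- function(spec = defaultLoopSpec(), nBasins = 5L,
                             targets = c("CnA", "NS5A-TP2"), seed = 1L,
                             nVariants = 5L, variantIds = NULL,
                             binderPattern = NULL, width = 25,
                             depthRange = c(9.0, 8.2), noise = 0.2,
                             nTorsionPairs = 1L, popThreshold = 0.05,
                             gridResolution = 2, temperature = 310) {
    if (nBasins < 2L) stop("invalid configuration: nBasins must be >= 2")
    if (nBasins > length(basinLayout2d))
        stop("invalid configuration: at most ", length(basinLayout2d),
             " well-separated basins supported")
    if (length(targets) < 1L) stop("at least one target required")
    if (length(targets) > nBasins - 1L)
        stop("invalid configuration: need nBasins > number of targets")
    if (nVariants < 2L) stop("need at least two variants")
    if (is.null(variantIds))
        variantIds <- c("parent", paste0("mut", seq_len(nVariants - 1L)))
    if (anyDuplicated(variantIds)) stop("duplicate variant ids")
    if (length(variantIds) != nVariants)
        stop("variantIds must have length nVariants")

    if (is.null(binderPattern)) {
        binderPattern <- matrix(FALSE, nVariants, length(targets))
        binderPattern[1, ] <- TRUE                      # parent binds all
        if (nVariants > 1L) {
            if (length(targets) == 1L) {
                # alternate binder / non-binder after the parent
                for (i in 2:nVariants)
                    binderPattern[i, 1L] <- (i %% 2L == 1L)
            } else {
                # each mutant keeps exactly one target, cycling
                tgt <- rep(seq_along(targets), length.out = nVariants - 1L)
                for (i in 2:nVariants) binderPattern[i, tgt[i - 1L]] <- TRUE
            }
        }
    }
    dimnames(binderPattern) <- list(variantIds, targets)

    withSeed(seed, {
        # centers: fixed layout per torsion pair, independently shifted
        base <- basinLayout2d[[nBasins]]
        C <- do.call(cbind, lapply(seq_len(nTorsionPairs), function(q) {
            shift <- runif(2, -180, 180)
            wrapAngle(sweep(base, 2, shift, "+") +
                      matrix(runif(2L * nBasins, -4, 4), nBasins, 2))
        }))
        depths <- seq(depthRange[1], depthRange[2], length.out = nBasins)
        basinList <- lapply(seq_len(nBasins), function(b)
            Basin(as.character(b), C[b, ], depths[b], width))
        # designated binder basin per target: shallowest basins, one each
        designated <- setNames(as.character(nBasins - seq_along(targets) + 1L),
                               targets)

        lands <- vector("list", nVariants)
        names(lands) <- variantIds
        for (i in seq_len(nVariants)) {
            pert <- setNames(numeric(nBasins), as.character(seq_len(nBasins)))
            free <- setdiff(as.character(seq_len(nBasins)), designated)
            if (i > 1L)
                pert[free] <- runif(length(free), -noise, noise)
            for (t in targets)
                if (!binderPattern[i, t])
                    pert[designated[[t]]] <- depths[as.integer(designated[[t]])] + 1
            lands[[i]] <- VariantLandscape(variantIds[i], basinList,
                                           perturbations = pert,
                                           temperature = temperature)
        }

        tp <- do.call(rbind, lapply(variantIds, function(v) {
            p <- exactPopulations(lands[[v]], gridResolution = gridResolution,
                                  temperature = temperature)
            data.frame(variant = v, basin = names(p), population = unname(p))
        }))
        truth <- new("PlantedTruth", populations = tp,
                     designated = designated, threshold = popThreshold)

        calls <- matrix("no_binding", nVariants, length(targets),
                        dimnames = list(variantIds, targets))
        for (v in variantIds) for (t in targets) {
            p <- tp$population[tp$variant == v & tp$basin == designated[[t]]]
            if (p > popThreshold) calls[v, t] <- "binds"
        }
        if (!identical(unname(calls == "binds"), unname(binderPattern)))
            stop("internal inconsistency: thresholded phenotype does not ",
                 "match the requested binder pattern; adjust depths/noise")

        new("VariantPanel", landscapes = lands, truth = truth,
            phenotype = PhenotypeMatrix(calls), loopSpec = spec)
    })
}

#' Generate a synthetic mutant clone library
#'
#' Emulates low-frequency region-directed random mutagenesis: clones are
#' drawn i.i.d. from the parent with independent per-position substitution
#' probabilities over the mutagenized region (loop plus flanks) and a small
#' uniform rate elsewhere; substitutions only, no indels. Each clone
#' records its true mutation list for downstream test oracles. The default
#' per-position rate of 0.1 over the 18-residue region makes the expected
#' fraction of clones with at least one in-region mutation
#' \code{1 - 0.9^18 = 0.85}.
#'
#' @param spec a \code{\link{LoopSpec}}.
#' @param nClones number of clones.
#' @param mutationRateProfile per-position substitution probability over
#'   the mutagenized region (length must equal the region length).
#' @param scaffoldRate per-position substitution probability outside the
#'   region.
#' @param seed integer seed.
#' @return A \code{\link{CloneLibrary}}.
#' @examples
#' lib <- makeCloneLibrary(defaultLoopSpec(), 10, seed = 1)
#' cloneTruth(lib)[[1]]
#' @export
makeCloneLibrary <- function(spec, nClones,
                             mutationRateProfile = NULL,
                             scaffoldRate = 0.008, seed = 1L) {
    region <- loopRegion(spec)
    if (is.null(mutationRateProfile))
        mutationRateProfile <- rep(0.1, length(region))
    if (length(mutationRateProfile) != length(region))
        stop("mutationRateProfile length (", length(mutationRateProfile),
             ") must equal the mutagenized-region length (", length(region), ")")
    if (any(mutationRateProfile < 0 | mutationRateProfile > 1) ||
        scaffoldRate < 0 || scaffoldRate > 1)
        stop("mutation probabilities must lie in [0, 1]")
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    parent <- strsplit(spec@parentSequence, "")[[1]]
    n <- length(parent)
    rate <- rep(scaffoldRate, n)
    rate[region] <- mutationRateProfile

    withSeed(seed, {
        seqs <- character(nClones)
        truth <- vector("list", nClones)
        for (i in seq_len(nClones)) {
            hit <- which(stats::runif(n) < rate)
            s <- parent
            if (length(hit)) {
                to <- vapply(hit, function(p)
                    sample(setdiff(aa, parent[p]), 1L), character(1))
                s[hit] <- to
                truth[[i]] <- data.frame(position = hit, from = parent[hit],
                                         to = to)
            } else {
                truth[[i]] <- data.frame(position = integer(0),
                                         from = character(0),
                                         to = character(0))
            }
            seqs[i] <- paste(s, collapse = "")
        }
        ids <- sprintf("clone%04d", seq_len(nClones))
        names(truth) <- ids
        new("CloneLibrary",
            sequences = AAStringSet(setNames(seqs, ids)),
            parent = spec@parentSequence, loopSpec = spec, truth = truth)
    })
}

#' Generate synthetic proliferation-assay replicates
#'
#' Replicate proliferation scores per condition: \code{mean + noise}, with
#' Gaussian noise of standard deviation \code{sem * sqrt(nReps)} so that
#' the expected standard error of the replicate mean equals \code{sem}.
#' The reference condition is fixed at exactly 100 in every replicate --
#' the score scale is normalized to the reference within each experiment
#' by construction.
#'
#' @param effectSizes named numeric vector: condition -> mean score.
#' @param sem target standard error of the mean, recycled over conditions.
#' @param nReps replicates per condition (>= 2).
#' @param seed integer seed.
#' @param referenceLabel name of the reference condition (default "Trx").
#' @return A data frame with columns condition, replicate, score; the
#'   reference label is stored in attribute \code{"reference"}.
#' @examples
#' makeAssayReadouts(c(R5G42 = 70), sem = 5, nReps = 4, seed = 1)
#' @export
makeAssayReadouts <- function(effectSizes, sem, nReps = 4L, seed = 1L,
                              referenceLabel = "Trx") {
    if (nReps < 2L) stop("insufficient replicates: nReps must be >= 2")
    sem <- rep_len(sem, length(effectSizes))
    withSeed(seed, {
        out <- do.call(rbind, lapply(seq_along(effectSizes), function(i)
            data.frame(condition = names(effectSizes)[i],
                       replicate = seq_len(nReps),
                       score = effectSizes[[i]] +
                           rnorm(nReps, 0, sem[i] * sqrt(nReps)))))
        ref <- data.frame(condition = referenceLabel,
                          replicate = seq_len(nReps), score = 100)
        out <- rbind(ref, out)
        rownames(out) <- NULL
        attr(out, "reference") <- referenceLabel
        out
    })
}
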