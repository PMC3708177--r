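#' @include AllClasses.R populations.R sampler.R
NULL

# internal: accept a PopulationTable or an equivalent data frame
popFrame <- function(pop) {
    tb <- if (is(pop, "PopulationTable")) as.data.frame(pop) else pop
    need <- c("variant", "conformer", "populated", "dG_kcal_mol")
    if (!all(need %in% names(tb)))
        stop("population table needs columns: ", paste(need, collapse = ", "))
    tb
}

# internal: does an annotation row apply to (variant, conformer, target)?
annotationApplies <- function(ann, variant, conformer, target) {
    (is.na(ann$variant) | ann$variant == "" | ann$variant == variant) &
    (ann$conformer == conformer) &
    (is.na(ann$target) | ann$target == "" | ann$target == target)
}

#' Nominate candidate binding conformers for a target
#'
#' The conformational-selection inference: a conformer can explain binding
#' to a target only if it is (1) populated in every variant that binds the
#' target, (2) optionally accessible at moderate free-energy cost -- maximum
#' free energy over the binders at most \code{dGmax} -- and (3) not
#' populated in any variant that fails to bind the target (otherwise the
#' conformer alone cannot discriminate binders from non-binders).
#' Undetermined phenotypes are ignored on both sides.
#'
#' The plain non-binder veto of step 3 can be overridden by expert
#' annotations: a \code{veto_exempt} annotation suppresses a specific
#' variant's veto of a conformer (e.g. when chemical reasoning attributes
#' the lost binding to a side-chain property rather than conformer absence),
#' and \code{force_exclude} removes a conformer with a recorded reason.
#' Annotations are always explicit inputs, never inferred.
#'
#' @param pop a \code{\link{PopulationTable}} (or data frame with columns
#'   variant, conformer, populated, dG_kcal_mol).
#' @param pheno a \code{\link{PhenotypeMatrix}}.
#' @param target target name (a column of \code{pheno}).
#' @param dGmax optional accessibility threshold in kcal/mol (step 2 is
#'   skipped when NULL).
#' @param annotations optional data frame with columns variant, conformer,
#'   target, action (\code{"veto_exempt"} or \code{"force_exclude"}) and
#'   reason; NA variant/target fields match anything.
#' @return A \code{\link{CandidateReport}}; candidates are sorted by
#'   ascending accessibility cost.
#' @examples
#' rec <- tableOneReconstruction()
#' candidates(consensusConformers(rec$populations, rec$phenotype, "CnA"))
#' @export
consensusConformers <- function(pop, pheno, target, dGmax = NULL,
                                annotations = NULL) {
    tb <- popFrame(pop)
    if (!target %in% colnames(phenotypeCalls(pheno)))
        stop("unknown target: ", target)
    bind <- intersect(binders(pheno, target), unique(tb$variant))
    nobind <- intersect(nonBinders(pheno, target), unique(tb$variant))

    if (!length(bind)) {
        warning("no binders for target '", target, "'; empty report")
        return(new("CandidateReport", target = target,
                   binderSet = character(0), nonBinderSet = nobind,
                   considered = integer(0), candidateSet = integer(0),
                   cost = numeric(0),
                   exclusionLog = data.frame(conformer = integer(0),
                                             reason = character(0)),
                   dGmax = if (is.null(dGmax)) NA_real_ else dGmax,
                   noBinders = TRUE))
    }

    conformers <- sort(unique(tb$conformer))
    isPop <- function(v, k) {
        r <- tb$populated[tb$variant == v & tb$conformer == k]
        length(r) == 1L && isTRUE(r)
    }
    dgOf <- function(v, k) {
        r <- tb$dG_kcal_mol[tb$variant == v & tb$conformer == k]
        if (length(r) == 1L) r else NA_real_
    }

    # step 1: populated in ALL binders
    considered <- conformers[vapply(conformers, function(k)
        all(vapply(bind, isPop, logical(1), k = k)), logical(1))]
    cost <- setNames(vapply(considered, function(k) {
        dg <- vapply(bind, dgOf, numeric(1), k = k)
        if (all(is.na(dg))) NA_real_ else max(dg, na.rm = TRUE)
    }, numeric(1)), as.character(considered))

    excl <- data.frame(conformer = integer(0), reason = character(0))
    keep <- considered

    # step 2: accessibility threshold on max-over-binders dG
    if (!is.null(dGmax)) {
        over <- keep[!is.na(cost[as.character(keep)]) &
                     cost[as.character(keep)] > dGmax]
        for (k in over)
            excl <- rbind(excl, data.frame(conformer = k,
                reason = sprintf("accessibility %.2f kcal/mol > threshold %.2f",
                                 cost[as.character(k)], dGmax)))
        keep <- setdiff(keep, over)
    }

    # step 3: non-binder veto, subject to annotations
    ann <- annotations
    for (k in keep) {
        if (!is.null(ann) && nrow(ann)) {
            forced <- ann[ann$action == "force_exclude" &
                          annotationApplies(ann, NA, k, target), , drop = FALSE]
            if (nrow(forced)) {
                excl <- rbind(excl, data.frame(conformer = k,
                    reason = paste("force-excluded:", forced$reason[1])))
                next
            }
        }
        vetoed <- character(0)
        for (v in nobind) {
            if (!isPop(v, k)) next
            exempt <- !is.null(ann) && nrow(ann) &&
                any(ann$action == "veto_exempt" &
                    annotationApplies(ann, v, k, target))
            if (!exempt) vetoed <- c(vetoed, v)
        }
        if (length(vetoed))
            excl <- rbind(excl, data.frame(conformer = k,
                reason = paste("populated in non-binder",
                               paste(vetoed, collapse = ", "))))
    }
    keep <- setdiff(keep, excl$conformer)
    keep <- keep[order(cost[as.character(keep)], keep, na.last = TRUE)]

    new("CandidateReport", target = target, binderSet = bind,
        nonBinderSet = nobind, considered = as.integer(considered),
        candidateSet = as.integer(keep), cost = cost,
        exclusionLog = excl,
        dGmax = if (is.null(dGmax)) NA_real_ else as.numeric(dGmax),
        noBinders = FALSE)
}

#' Accessibility profile of one conformer across variants
#'
#' The free-energy cost of the conformer relative to each variant's most
#' populated conformer; \code{NA} (printed as \code{"n.p."}) where the
#' conformer is not populated for that variant -- never zero.
#'
#' @param pop a \code{\link{PopulationTable}} or equivalent data frame.
#' @param variants variant ids to profile.
#' @param conformer conformer label.
#' @return Named numeric vector of free energies (kcal/mol) with NA for
#'   not-populated variants.
#' @export
accessibilityProfile <- function(pop, variants, conformer) {
    tb <- popFrame(pop)
    if (!conformer %in% tb$conformer)
        stop("conformer ", conformer, " is not in the table")
    out <- setNames(rep(NA_real_, length(variants)), variants)
    for (v in variants) {
        r <- tb[tb$variant == v & tb$conformer == conformer, , drop = FALSE]
        if (nrow(r) == 1L && isTRUE(r$populated))
            out[v] <- r$dG_kcal_mol
    }
    out
}

#' Worked example: the five-variant panel reconstruction
#'
#' The populated/not-populated pattern of loop conformers 2, 4, 7, 9 and 13
#' across the parental aptamer R5G42 and its single mutants S35P, S35A,
#' F39I and F39Y, with their yeast two-hybrid binding phenotypes for CnA
#' and NS5A-TP2, and the aromaticity annotation that exempts F39I from the
#' non-binder veto on conformers 4 and 9. Free energies are given only for
#' conformer 13 (0.2, 2.3 and 1.2 kcal/mol for F39I, R5G42 and S35P); the
#' remaining cells are NA.
#'
#' @return A list with \code{populations} (data frame), \code{phenotype}
#'   (a \code{\link{PhenotypeMatrix}}) and \code{annotations} (data frame).
#' @examples
#' rec <- tableOneReconstruction()
#' candidates(consensusConformers(rec$populations, rec$phenotype,
#'     "NS5A-TP2", annotations = rec$annotations))  # conformers 4 and 9
#' @export
tableOneReconstruction <- function() {
    dir <- system.file("extdata", package = "loopscape")
    popu <- read.csv(file.path(dir, "panel_populated_flags.csv"),
                     stringsAsFactors = FALSE)
    popu$populated <- as.logical(popu$populated)
    ph <- read.csv(file.path(dir, "panel_phenotypes.csv"),
                   row.names = 1, check.names = FALSE,
                   stringsAsFactors = FALSE)
    ann <- read.csv(file.path(dir, "panel_annotations.csv"),
                    stringsAsFactors = FALSE)
    list(populations = popu,
         phenotype = PhenotypeMatrix(as.matrix(ph)),
         annotations = ann)
}

#' End-to-end recovery of the planted binder conformer
#'
#' Validation harness: samples every variant of a synthetic panel with
#' replica exchange, pools the analysis-temperature ensembles, clusters
#' them into conformers, builds the population table, runs the concordance
#' inference per target, and checks the result against the planted truth.
#' Success for a target means the candidate set is exactly the conformer
#' corresponding to the designated binder basin.
#'
#' @param panel a \code{\link{VariantPanel}} from
#'   \code{\link{makeVariantPanel}}.
#' @param ladder temperature ladder (default the canonical 290-520 K, 24
#'   baths).
#' @param config sampler schedule; \code{config@seed} is combined with the
#'   variant index so each variant gets its own stream.
#' @param cutoff clustering cutoff in degrees.
#' @param analysisTemperature bath analysed (default 310 K; must be in the
#'   ladder).
#' @return A list: \code{success} (named logical per target),
#'   \code{reports} (CandidateReports), \code{populationTable},
#'   \code{basinConformer} (basin id -> conformer label map),
#'   \code{cellRecovery} (fraction of variant x basin cells whose sampled
#'   mean is within 3 SEM of the planted population), and \code{catalog}.
#' @export
recoverPlantedBinder <- function(panel, ladder = buildLadder(290, 10, 24),
                                 config = SamplerConfig(),
                                 cutoff = 40, analysisTemperature = 310) {
    lands <- landscapes(panel)
    truth <- plantedTruth(panel)
    snaps <- vector("list", length(lands))
    names(snaps) <- names(lands)
    for (i in seq_along(lands)) {
        cfg <- config
        cfg@seed <- config@seed + i - 1L
        run <- runParallelTempering(lands[[i]], ladder, cfg,
                                    keepTemperatures = analysisTemperature)
        snaps[[i]] <- snapshotAt(run, analysisTemperature)
    }
    catalog <- clusterFrames(snaps, cutoff = cutoff, mode = "angular")
    pop <- buildPopulationTable(catalog, temperature = analysisTemperature)

    # map each planted basin to its nearest catalog conformer
    refLand <- lands[[1]]
    bIds <- basinIds(refLand)
    bCenters <- do.call(rbind, lapply(basins(refLand), function(b) b@center))
    cen <- centers(catalog)
    basinConformer <- setNames(vapply(seq_along(bIds), function(b) {
        d <- vapply(seq_len(nrow(cen)), function(k)
            catalogDistance(catalog, bCenters[b, ], cen[k, ]), numeric(1))
        which.min(d)
    }, integer(1)), bIds)

    # per-cell recovery: sampled mean within 3 SEM of the planted
    # population, plus a 0.05-percentage-point absolute floor covering the
    # grid discretization of the truth and the boundary offset between
    # catalog centers (founding frames) and exact basin centers
    tb <- as.data.frame(pop)
    tp <- truth@populations
    ok <- logical(0)
    for (i in seq_len(nrow(tp))) {
        k <- basinConformer[[as.character(tp$basin[i])]]
        r <- tb[tb$variant == tp$variant[i] & tb$conformer == k, , drop = FALSE]
        dev <- abs(r$pop_pct - 100 * tp$population[i])
        ok <- c(ok, dev <= 3 * r$sem_pct + 0.05)
    }

    targets <- names(truth@designated)
    reports <- lapply(targets, function(t)
        consensusConformers(pop, panel@phenotype, t))
    names(reports) <- targets
    success <- vapply(targets, function(t) {
        want <- basinConformer[[truth@designated[[t]]]]
        identical(as.integer(candidates(reports[[t]])), as.integer(want))
    }, logical(1))

    list(success = success, reports = reports, populationTable = pop,
         basinConformer = basinConformer, cellRecovery = mean(ok),
         catalog = catalog)
}
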