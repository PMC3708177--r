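#' @include AllClasses.R clustering.R
NULL

#' Block statistics of a numeric sample
#'
#' Wraps per-block observations with their mean and the standard error of
#' the mean \code{sqrt(sum((x_i - xbar)^2) / (n (n - 1)))}.
#'
#' @param observations numeric vector of per-block values (length >= 2).
#' @return A \code{\link{BlockStatistics}} object.
#' @examples
#' blockStatistics(c(10, 20, 30, 40))  # mean 25, SEM 6.455
#' @export
blockStatistics <- function(observations) {
    new("BlockStatistics", observations = as.numeric(observations),
        mean = mean(observations), sem = semOfMean(observations))
}

#' Block-averaged conformer populations for one variant
#'
#' Splits the variant's time-ordered conformer assignments into
#' \code{nBlocks} contiguous equal spans (a trailing remainder is dropped
#' with a message) and computes, per conformer, the percentage of each
#' block's frames assigned to it, the mean over blocks and its SEM.
#'
#' @param assignment integer vector of conformer labels in time order.
#' @param conformers conformer labels to tabulate (defaults to all labels
#'   present in \code{assignment}).
#' @param nBlocks number of blocks (default 4).
#' @return A list with \code{stats} (data frame: conformer, mean_pct,
#'   sem_pct) and \code{blocks} (nBlocks x conformers percentage matrix).
#' @examples
#' blockPopulation(rep(c(1, 1, 1, 2), 25))$stats
#' @export
blockPopulation <- function(assignment, conformers = NULL, nBlocks = 4L) {
    if (nBlocks < 2L) stop("nBlocks must be >= 2")
    n <- length(assignment)
    if (n < nBlocks) stop("fewer frames than blocks")
    if (is.null(conformers)) conformers <- sort(unique(assignment))
    size <- n %/% nBlocks
    dropped <- n - size * nBlocks
    if (dropped > 0)
        message("dropping trailing remainder of ", dropped, " frame(s)")
    idx <- rep(seq_len(nBlocks), each = size)
    kept <- assignment[seq_len(size * nBlocks)]
    B <- vapply(conformers, function(k)
        100 * tapply(kept == k, idx, mean), numeric(nBlocks))
    B <- matrix(B, nrow = nBlocks,
                dimnames = list(NULL, as.character(conformers)))
    stats <- data.frame(conformer = conformers,
                        mean_pct = colMeans(B),
                        sem_pct = apply(B, 2, semOfMean),
                        row.names = NULL)
    list(stats = stats, blocks = B)
}

#' Populated call from block statistics
#'
#' A conformer is regarded as populated when its mean population strictly
#' exceeds twice the standard error of the mean; small populations of low
#' statistical significance (and empty conformers, whose SEM is zero) are
#' regarded as not populated.
#'
#' @param stats a \code{\link{BlockStatistics}} object, or a numeric mean
#'   together with \code{sem}.
#' @param sem the SEM when \code{stats} is given as a plain mean.
#' @return Logical populated flag.
#' @examples
#' significanceCall(blockStatistics(c(9, 11, 10, 10)))  # TRUE
#' significanceCall(4, 2)                               # FALSE (boundary)
#' @export
significanceCall <- function(stats, sem = NULL) {
    if (is(stats, "BlockStatistics")) {
        m <- stats@mean
        s <- stats@sem
    } else {
        m <- stats
        s <- sem
    }
    m > 2 * s
}

#' Relative conformer free energy from populations
#'
#' \code{dG = -kT ln(P_i / P_max)} in kcal/mol with
#' \code{k = 0.0019872} kcal/(mol K): zero for the most populated conformer
#' and strictly decreasing in \code{P_i}. \code{P_i} and \code{P_max} may
#' be fractions or percentages, as long as they share a scale.
#'
#' @param Pi population of the conformer of interest (> 0).
#' @param Pmax population of the most populated conformer (>= Pi).
#' @param temperature temperature in kelvin (default 310).
#' @return Free-energy difference in kcal/mol.
#' @examples
#' freeEnergy(0.5, 1, 310)  # 0.427 kcal/mol
#' @export
freeEnergy <- function(Pi, Pmax, temperature = 310) {
    if (any(Pi <= 0))
        stop("undefined free energy: P_i must be > 0 (report as not populated)")
    if (any(Pi > Pmax)) stop("P_i must not exceed P_max")
    -kBoltzmann * temperature * log(Pi / Pmax) + 0   # + 0 avoids -0
}

#' Build the per-variant conformer population table
#'
#' For every variant in the catalog: block-averaged population percentages
#' and SEMs per conformer (over all catalog conformers, including empty
#' ones), the populated call (mean > 2 SEM), and the free energy relative
#' to the variant's most populated conformer. \code{P_max} is taken over
#' the populated conformers of that variant; not-populated conformers carry
#' an NA free energy and export as \code{"n.p."}.
#'
#' @param catalog a \code{\link{ConformerCatalog}} of pooled frames.
#' @param temperature analysis temperature in kelvin (default 310).
#' @param nBlocks number of trajectory blocks for the error estimate
#'   (default 4).
#' @return A \code{\link{PopulationTable}}.
#' @export
buildPopulationTable <- function(catalog, temperature = 310, nBlocks = 4L) {
    variants <- unique(catalog@variant)
    if (!length(variants)) stop("catalog contains no frames")
    K <- nConformers(catalog)
    rows <- lapply(variants, function(v) {
        bp <- blockPopulation(variantAssignments(catalog, v),
                              conformers = seq_len(K), nBlocks = nBlocks)
        st <- bp$stats
        populated <- st$mean_pct > 2 * st$sem_pct
        dG <- rep(NA_real_, K)
        if (any(populated)) {
            pmax <- max(st$mean_pct[populated])
            dG[populated] <- freeEnergy(st$mean_pct[populated], pmax,
                                        temperature)
        }
        data.frame(variant = v, conformer = st$conformer,
                   pop_pct = st$mean_pct, sem_pct = st$sem_pct,
                   populated = populated, dG_kcal_mol = dG)
    })
    new("PopulationTable", table = do.call(rbind, rows),
        temperature = as.numeric(temperature), boltzmann = kBoltzmann,
        nBlocks = as.integer(nBlocks))
}

#' Format a population table in the classic layout
#'
#' One row per conformer, one column per variant, each populated cell
#' printed as \code{"percentage (error) dG"} rounded to one decimal and
#' \code{"n.p."} for not-populated cells.
#'
#' @param pop a \code{\link{PopulationTable}}.
#' @return A character matrix (conformers x variants).
#' @export
formatPopulationTable <- function(pop) {
    tb <- as.data.frame(pop)
    variants <- unique(tb$variant)
    conformers <- sort(unique(tb$conformer))
    out <- matrix("n.p.", length(conformers), length(variants),
                  dimnames = list(as.character(conformers), variants))
    for (i in seq_len(nrow(tb))) {
        if (!tb$populated[i]) next
        out[as.character(tb$conformer[i]), tb$variant[i]] <-
            sprintf("%.1f (%.1f) %.1f", tb$pop_pct[i], tb$sem_pct[i],
                    tb$dG_kcal_mol[i])
    }
    out
}
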