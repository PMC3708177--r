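#' @include AllClasses.R
NULL

#' Classify the mutations of one clone
#'
#' Position-wise comparison of a clone against the parent (substitution-only
#' model; a length mismatch is rejected rather than aligned). Each mutation
#' is tagged with its region -- \code{loop}, \code{flank} or
#' \code{scaffold} -- according to the loop specification.
#'
#' @param clone clone amino-acid sequence (character or AAString).
#' @param parent parent sequence of equal length.
#' @param spec a \code{\link{LoopSpec}}.
#' @return A data frame (position, from, to, region) with attributes
#'   \code{inRegion} (any mutation in loop or flank) and
#'   \code{singleLoop} (exactly one mutation overall, located in the loop).
#' @examples
#' sp <- defaultLoopSpec()
#' p <- sp@parentSequence
#' m <- p
#' substr(m, 39, 39) <- "I"   # the F39I mutant
#' classifyClone(m, p, sp)
#' @export
classifyClone <- function(clone, parent, spec) {
    clone <- as.character(clone)
    parent <- as.character(parent)
    if (nchar(clone) != nchar(parent))
        stop("alignment not supported: clone and parent lengths differ ",
             "(substitution-only contract)")
    a <- strsplit(clone, "")[[1]]
    b <- strsplit(parent, "")[[1]]
    pos <- which(a != b)
    lab <- regionLabels(spec)
    out <- data.frame(position = pos, from = b[pos], to = a[pos],
                      region = lab[pos], stringsAsFactors = FALSE)
    attr(out, "inRegion") <- any(out$region %in% c("loop", "flank"))
    attr(out, "singleLoop") <- nrow(out) == 1L && out$region[1] == "loop"
    out
}

#' Per-position mutation frequency profile of a clone library
#'
#' Counts mutations at every parent position over all clones and reports
#' the per-position frequency (count / clone count) with region labels,
#' plus library-level summaries. Because the natural denominator of
#' "fraction of clones mutated in the targeted region" is ambiguous (all
#' clones, or only clones carrying at least one mutation), both are
#' reported.
#'
#' @param clones a \code{\link{CloneLibrary}}, or a character vector /
#'   AAStringSet of clone sequences (then \code{parent} and \code{spec}
#'   are required).
#' @param parent parent sequence (taken from the library if omitted).
#' @param spec a \code{\link{LoopSpec}} (taken from the library if
#'   omitted).
#' @return A list: \code{profile} (data frame: position, region, count,
#'   frequency), \code{nClones}, \code{nMutated}, and the summary
#'   fractions \code{fracInRegionAll}, \code{fracInRegionMutated},
#'   \code{fracSingleLoopAll}, \code{fracSingleLoopMutated}.
#' @export
mutationProfile <- function(clones, parent = NULL, spec = NULL) {
    if (is(clones, "CloneLibrary")) {
        parent <- clones@parent
        spec <- clones@loopSpec
        seqs <- as.character(cloneSequences(clones))
    } else {
        if (is.null(parent) || is.null(spec))
            stop("parent and spec are required for plain sequences")
        seqs <- as.character(clones)
    }
    if (!length(seqs)) {
        warning("empty clone library; empty profile")
        return(list(profile = data.frame(position = integer(0),
                                         region = character(0),
                                         count = integer(0),
                                         frequency = numeric(0)),
                    nClones = 0L, nMutated = 0L,
                    fracInRegionAll = NA_real_,
                    fracInRegionMutated = NA_real_,
                    fracSingleLoopAll = NA_real_,
                    fracSingleLoopMutated = NA_real_))
    }
    n <- nchar(parent)
    lab <- regionLabels(spec)
    counts <- integer(n)
    inRegion <- logical(length(seqs))
    singleLoop <- logical(length(seqs))
    mutated <- logical(length(seqs))
    for (i in seq_along(seqs)) {
        cl <- classifyClone(seqs[i], parent, spec)
        counts[cl$position] <- counts[cl$position] + 1L
        mutated[i] <- nrow(cl) > 0L
        inRegion[i] <- attr(cl, "inRegion")
        singleLoop[i] <- attr(cl, "singleLoop")
    }
    list(profile = data.frame(position = seq_len(n), region = lab,
                              count = counts,
                              frequency = counts / length(seqs)),
         nClones = length(seqs), nMutated = sum(mutated),
         fracInRegionAll = mean(inRegion),
         fracInRegionMutated = if (any(mutated))
             sum(inRegion) / sum(mutated) else NA_real_,
         fracSingleLoopAll = mean(singleLoop),
         fracSingleLoopMutated = if (any(mutated))
             sum(singleLoop) / sum(mutated) else NA_real_)
}

#' Cross-tabulate binding phenotypes of a screened library
#'
#' Partitions the tested clones into five classes -- binding both targets,
#' one target only (each), neither, and undetermined (not expressed or
#' missing calls) -- and reports counts plus truncated integer percentages.
#' Percentages are truncated toward zero (each reported percentage sits
#' within one point below the exact value); full-precision values are
#' returned alongside.
#'
#' @param calls data frame of per-clone calls with one column per target,
#'   values in \code{binds}/\code{no_binding}/\code{undetermined} (NA
#'   counts as undetermined).
#' @param targetA,targetB the two column names to cross-tabulate.
#' @return A list with \code{counts}, \code{percent} (integer),
#'   \code{percentExact}, and \code{total}.
#' @examples
#' calls <- data.frame(CnA = c("binds", "binds", "no_binding"),
#'                     NS5A = c("binds", "no_binding", "no_binding"))
#' phenotypeCrosstab(calls, "CnA", "NS5A")$counts
#' @export
phenotypeCrosstab <- function(calls, targetA, targetB) {
    if (!all(c(targetA, targetB) %in% names(calls)))
        stop("calls must contain columns '", targetA, "' and '", targetB, "'")
    a <- as.character(calls[[targetA]])
    b <- as.character(calls[[targetB]])
    undet <- is.na(a) | is.na(b) | a == "undetermined" | b == "undetermined"
    cls <- ifelse(undet, "undetermined",
           ifelse(a == "binds" & b == "binds", "both",
           ifelse(a == "binds", "onlyA",
           ifelse(b == "binds", "onlyB", "neither"))))
    lev <- c("both", "onlyA", "onlyB", "neither", "undetermined")
    counts <- setNames(as.integer(table(factor(cls, levels = lev))), lev)
    names(counts) <- c("both", paste0(targetA, "_only"),
                       paste0(targetB, "_only"), "neither", "undetermined")
    total <- length(cls)
    exact <- 100 * counts / total
    list(counts = counts, percent = as.integer(trunc(exact)),
         percentExact = exact, total = total)
}
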