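#' @include AllClasses.R
NULL

#' Superpose a structure frame onto a reference frame
#'
#' Least-squares rigid-body fit (Kabsch) on the scaffold reference atoms;
#' the mobile loop atoms are carried through the same transform. In the
#' angular (torsion) representation there is no rigid-body freedom, so
#' superposition is the identity with fit-RMSD 0.
#'
#' @param x a \code{\link{StructureFrame}} (3-D mode) or numeric torsion
#'   vector (angular mode).
#' @param reference the reference \code{\link{StructureFrame}} (or torsion
#'   vector).
#' @param ... unused.
#' @return A list with \code{frame} (the transformed frame) and \code{rmsd}
#'   (fit RMSD over the reference atoms).
#' @export
setMethod("superpose", signature("StructureFrame", "StructureFrame"),
          function(x, reference, ...) {
    nr <- nrow(x@reference)
    if (nr != nrow(reference@reference))
        stop("reference-atom counts differ")
    if (nr < 3L)
        stop("underdetermined fit: need >= 3 reference atoms")
    xyz <- as.numeric(t(rbind(x@reference, x@mobile)))
    fixed <- as.numeric(t(rbind(reference@reference, reference@mobile)))
    inds <- seq_len(3L * nr)
    moved <- bio3d::fit.xyz(fixed = fixed, mobile = xyz,
                            fixed.inds = inds, mobile.inds = inds)
    M <- matrix(moved, ncol = 3, byrow = TRUE)
    refNew <- M[seq_len(nr), , drop = FALSE]
    out <- StructureFrame(x@variantId, x@time,
                          mobile = M[-seq_len(nr), , drop = FALSE],
                          reference = refNew)
    fitRmsd <- sqrt(sum((refNew - reference@reference)^2) / nr)
    list(frame = out, rmsd = fitRmsd)
})

#' @rdname superpose
#' @export
setMethod("superpose", signature("numeric", "numeric"),
          function(x, reference, ...) {
    if (length(x) != length(reference)) stop("torsion dimensionality mismatch")
    list(frame = x, rmsd = 0)
})

#' Loop RMSD between two frames
#'
#' Root-mean-square deviation over the mobile loop pseudo-atoms (3-D mode,
#' frames assumed superposed onto a common reference) or the shortest-arc
#' angular RMS difference in degrees (angular mode). Symmetric, and zero
#' exactly when the coordinates are equal.
#'
#' @param x,y two \code{\link{StructureFrame}}s or two numeric torsion
#'   vectors.
#' @param ... unused.
#' @return The RMSD (coordinate units, or degrees in angular mode).
#' @examples
#' loopRMSD(c(0, 0), c(350, 10))  # 10: shortest arc wraps at 180
#' @export
setMethod("loopRMSD", signature("StructureFrame", "StructureFrame"),
          function(x, y, ...) {
    if (!identical(dim(x@mobile), dim(y@mobile)))
        stop("mobile-atom shape mismatch")
    sqrt(sum((x@mobile - y@mobile)^2) / nrow(x@mobile))
})

#' @rdname loopRMSD
#' @export
setMethod("loopRMSD", signature("numeric", "numeric"), function(x, y, ...) {
    if (length(x) != length(y)) stop("torsion dimensionality mismatch")
    sqrt(mean(wrapAngle(x - y)^2))
})

#' Cluster pooled frames into loop conformers
#'
#' Leader (first-fit) clustering with a fixed RMSD cutoff over frames pooled
#' across variants: frames are scanned in input order (variants in their
#' declared order, frames in time order); a frame within the cutoff of an
#' existing center joins the first such center (in creation order),
#' otherwise it founds a new center. Conformers are then relabelled 1..K by
#' descending pooled population (ties by creation order). Every frame ends
#' within the cutoff of its center, and centers are pairwise more than the
#' cutoff apart.
#'
#' @param x a named list of \code{\link{SnapshotSet}}s (angular mode), or a
#'   list of superposed \code{\link{StructureFrame}}s (3-D mode).
#' @param cutoff clustering cutoff: degrees of angular RMS in angular mode
#'   (default 40, the surrogate counterpart of the 2-Angstrom Cartesian
#'   cutoff), coordinate units in 3-D mode.
#' @param mode \code{"angular"} or \code{"xyz"}.
#' @return A \code{\link{ConformerCatalog}}.
#' @examples
#' l <- VariantLandscape("wt", list(Basin("a", c(0, 0), 5, 25)))
#' run <- runParallelTempering(l, buildLadder(290, 10, 3),
#'     SamplerConfig(2000, 20, 20, 400, seed = 1), keepTemperatures = 310)
#' clusterFrames(list(wt = snapshotAt(run, 310)))
#' @export
clusterFrames <- function(x, cutoff = 40, mode = c("angular", "xyz")) {
    mode <- match.arg(mode)
    if (cutoff <= 0) stop("cutoff must be > 0")
    if (mode == "angular") {
        if (!length(x) || !all(vapply(x, is, logical(1), "SnapshotSet")))
            stop("angular mode expects a list of SnapshotSet objects")
        X <- do.call(rbind, lapply(x, frames))
        variant <- rep(vapply(x, variantId, character(1)),
                       vapply(x, function(s) nrow(frames(s)), integer(1)))
        tim <- unlist(lapply(x, frameTimes), use.names = FALSE)
        denom <- ncol(X)
        angular <- TRUE
    } else {
        if (!length(x) || !all(vapply(x, is, logical(1), "StructureFrame")))
            stop("xyz mode expects a list of StructureFrame objects")
        X <- do.call(rbind, lapply(x, function(f) as.numeric(t(f@mobile))))
        variant <- vapply(x, function(f) f@variantId, character(1))
        tim <- vapply(x, function(f) f@time, numeric(1))
        denom <- nrow(x[[1]]@mobile)
        angular <- FALSE
    }
    if (!all(is.finite(X))) stop("non-finite coordinates in frames")
    if (nrow(X) == 0L)
        return(new("ConformerCatalog",
                   centers = matrix(numeric(0), 0, max(1L, ncol(X))),
                   assignment = integer(0), variant = character(0),
                   time = numeric(0), cutoff = cutoff, mode = mode,
                   denom = as.numeric(denom)))

    res <- leader_cluster_cpp(X, cutoff, denom, angular)

    # relabel by descending pooled population, ties by creation order
    sizes <- tabulate(res$assignment, nbins = length(res$centers))
    ord <- order(-sizes, seq_along(sizes))
    relabel <- integer(length(ord))
    relabel[ord] <- seq_along(ord)
    new("ConformerCatalog",
        centers = X[res$centers[ord], , drop = FALSE],
        assignment = relabel[res$assignment],
        variant = as.character(variant), time = as.numeric(tim),
        cutoff = cutoff, mode = mode, denom = as.numeric(denom))
}

# internal: distance between a frame row and a catalog center
catalogDistance <- function(catalog, a, b) {
    dd <- a - b
    if (catalog@mode == "angular") dd <- wrapAngle(dd)
    sqrt(sum(dd^2) / catalog@denom)
}

#' Per-variant conformer assignments
#'
#' @param catalog a \code{\link{ConformerCatalog}}.
#' @param variant variant id.
#' @return Integer vector of conformer labels for that variant's frames, in
#'   time order.
#' @export
variantAssignments <- function(catalog, variant) {
    sel <- catalog@variant == variant
    if (!any(sel)) stop("variant '", variant, "' has no frames in the catalog")
    catalog@assignment[sel][order(catalog@time[sel])]
}
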