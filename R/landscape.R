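#' @include AllClasses.R
NULL

# internal: basin parameters of a landscape as plain matrices/vectors
landscapeParams <- function(landscape) {
    C <- do.call(rbind, lapply(landscape@basins, function(b) b@center))
    list(centers = C,
         depths = unname(effectiveDepths(landscape)),
         widths = vapply(landscape@basins, function(b) b@width, numeric(1)))
}

#' Evaluate the surrogate loop energy
#'
#' The energy at torsion coordinates \code{x} is a sum of negative Gaussian
#' wells over the basins, \code{-sum_b D_b exp(-dist(x, c_b)^2 / (2 w_b^2))},
#' with the angular distance computed on the periodic torus (degrees) and
#' effective depths \code{D_b = depth_b - perturbation_b}. Abolished basins
#' (\code{D_b <= 0}) contribute nothing; wells are truncated beyond six
#' widths, where their contribution is below 1e-7 kcal/mol.
#'
#' @param landscape a \code{\link{VariantLandscape}}.
#' @param x a coordinate vector, or a matrix with one coordinate per row.
#' @return Energy in kcal/mol (vector with one value per row of \code{x}).
#' @examples
#' l <- VariantLandscape("wt", list(Basin("a", c(0, 0), 5, 25)))
#' landscapeEnergy(l, c(0, 0))   # -5
#' @export
landscapeEnergy <- function(landscape, x) {
    p <- landscapeParams(landscape)
    if (is.matrix(x)) {
        if (ncol(x) != ncol(p$centers))
            stop("coordinate dimensionality mismatch")
        e <- numeric(nrow(x))
        for (b in seq_len(nrow(p$centers))) {
            D <- p$depths[b]
            if (D <= 0) next
            w2 <- p$widths[b]^2
            d2 <- rowSums(wrapAngle(sweep(x, 2, p$centers[b, ]))^2)
            inside <- d2 <= 36 * w2
            e[inside] <- e[inside] - D * exp(-d2[inside] / (2 * w2))
        }
        e
    } else {
        if (length(x) != ncol(p$centers))
            stop("coordinate dimensionality mismatch")
        landscape_energy_cpp(as.numeric(x), p$centers, p$depths, p$widths)
    }
}

#' Exact Boltzmann basin populations by grid summation
#'
#' Independent analytic oracle for the sampler: discretizes the torsion
#' torus on a uniform grid, computes Boltzmann weights
#' \code{exp(-E / kT)} at every grid point, assigns each point to the
#' attraction region of the nearest basin center (angular distance, ties to
#' the lower basin index), and reports each basin's share of the total
#' weight. Abolished basins keep their attraction region, so their
#' population is the (small) flat-background share.
#'
#' @param landscape a \code{\link{VariantLandscape}}.
#' @param gridResolution grid spacing in degrees; must divide 360.
#' @param temperature temperature in kelvin; defaults to the landscape's
#'   analysis temperature.
#' @return Named numeric vector of basin populations (fractions summing
#'   to 1).
#' @examples
#' l <- VariantLandscape("wt", list(Basin("a", c(0, 0), 5, 25),
#'                                  Basin("b", c(180, 180), 5, 25)))
#' exactPopulations(l, gridResolution = 5)  # 0.5 / 0.5 by symmetry
#' @export
exactPopulations <- function(landscape, gridResolution = 2,
                             temperature = landscape@temperature) {
    if (360 %% gridResolution != 0)
        stop("gridResolution must divide 360")
    p <- landscapeParams(landscape)
    d <- ncol(p$centers)
    npts <- (360 / gridResolution)^d
    if (npts > 2e7)
        stop("grid too large (", npts, " points); coarsen gridResolution")
    axis <- seq(-180 + gridResolution / 2, 180 - gridResolution / 2,
                by = gridResolution)
    X <- as.matrix(expand.grid(rep(list(axis), d)))
    colnames(X) <- NULL

    e <- landscapeEnergy(landscape, X)
    if (!all(is.finite(e))) stop("non-finite energy on grid")
    w <- exp(-(e - min(e)) / (kBoltzmann * temperature))

    d2 <- vapply(seq_len(nrow(p$centers)), function(b)
        rowSums(wrapAngle(sweep(X, 2, p$centers[b, ]))^2), numeric(nrow(X)))
    nearest <- max.col(-d2, ties.method = "first")

    tot <- vapply(seq_len(nrow(p$centers)),
                  function(b) sum(w[nearest == b]), numeric(1))
    setNames(tot / sum(tot), basinIds(landscape))
}
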