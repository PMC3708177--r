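# Shared fixtures and independent oracles for the test suite.

wrapDeg <- function(a) (a + 180) %% 360 - 180

# a two-basin landscape with wells separated across the torus diagonal
twoBasinLandscape <- function(d1 = 9, d2 = 8.8, w1 = 25, w2 = 25) {
    VariantLandscape("two", list(Basin("a", c(0, 0), d1, w1),
                                 Basin("b", c(180, 180), d2, w2)))
}

threeBasinLandscape <- function(depths = c(9, 8.7, 8.4)) {
    VariantLandscape("three",
        list(Basin("a", c(0, 0), depths[1], 25),
             Basin("b", c(120, 120), depths[2], 25),
             Basin("c", c(-120, -120), depths[3], 25)))
}

# independent straightforward re-implementation of the leader scan,
# kept deliberately naive (plain R loops)
leaderOracle <- function(X, cutoff, denom, angular = TRUE) {
    centers <- integer(0)
    assign_ <- integer(nrow(X))
    for (i in seq_len(nrow(X))) {
        hit <- 0L
        for (ci in seq_along(centers)) {
            dd <- X[i, ] - X[centers[ci], ]
            if (angular) dd <- wrapDeg(dd)
            if (sqrt(sum(dd^2) / denom) <= cutoff) { hit <- ci; break }
        }
        if (hit == 0L) {
            centers <- c(centers, i)
            hit <- length(centers)
        }
        assign_[i] <- hit
    }
    list(assignment = assign_, centers = centers)
}

# relabel a leader result by descending cluster size (ties by creation) so
# it can be compared with a ConformerCatalog
relabelBySize <- function(assignment, nCenters) {
    sizes <- tabulate(assignment, nbins = nCenters)
    ord <- order(-sizes, seq_len(nCenters))
    relabel <- integer(nCenters)
    relabel[ord] <- seq_len(nCenters)
    relabel[assignment]
}

# brute-force rigid-body fit oracle: coarse Euler-angle grid followed by
# Nelder-Mead refinement; independent of the Kabsch path under test
bruteForceFitRMSD <- function(mobile, fixed) {
    rotmat <- function(e) {
        cz <- cos(e[1]); sz <- sin(e[1])
        cy <- cos(e[2]); sy <- sin(e[2])
        cx <- cos(e[3]); sx <- sin(e[3])
        Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
        Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
        Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
        Rz %*% Ry %*% Rx
    }
    mc <- scale(mobile, scale = FALSE)
    fc <- scale(fixed, scale = FALSE)
    obj <- function(e) sqrt(sum((mc %*% t(rotmat(e)) - fc)^2) / nrow(fixed))
    grid <- as.matrix(expand.grid(seq(0, 2 * pi, length.out = 9)[-9],
                                  seq(0, pi, length.out = 5),
                                  seq(0, 2 * pi, length.out = 9)[-9]))
    vals <- apply(grid, 1, obj)
    best <- grid[which.min(vals), ]
    optim(best, obj, method = "Nelder-Mead",
          control = list(reltol = 1e-14, maxit = 5000))$value
}

# small deterministic xyz frames for superposition tests
makeXYZFrame <- function(seed, variant = "v", time = 1, nMobile = 6,
                         nRef = 5) {
    set.seed(seed)
    StructureFrame(variant, time,
                   mobile = matrix(rnorm(nMobile * 3, sd = 3), ncol = 3),
                   reference = matrix(rnorm(nRef * 3, sd = 5), ncol = 3))
}

rigidTransform <- function(M, euler = c(0.4, -0.7, 1.1), shift = c(3, -2, 5)) {
    cz <- cos(euler[1]); sz <- sin(euler[1])
    cy <- cos(euler[2]); sy <- sin(euler[2])
    cx <- cos(euler[3]); sx <- sin(euler[3])
    R <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1)) %*%
         rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy)) %*%
         rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    sweep(M %*% t(R), 2, shift, "+")
}
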