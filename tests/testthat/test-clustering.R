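test_that("superposition removes rigid motion and matches a brute-force fit", {
    f <- makeXYZFrame(1)

    # frame vs itself: zero fit RMSD
    expect_equal(superpose(f, f)$rmsd, 0, tolerance = 1e-10)

    # a rigidly moved copy superposes back exactly
    g <- StructureFrame("v", 2, rigidTransform(f@mobile),
                        rigidTransform(f@reference))
    s <- superpose(g, f)
    expect_equal(s$rmsd, 0, tolerance = 1e-8)
    expect_equal(s$frame@mobile, f@mobile, tolerance = 1e-8)
    expect_equal(loopRMSD(s$frame, f), 0, tolerance = 1e-8)

    # noisy 4-point toy set: Kabsch fit equals an independent rotation-space
    # search to 1e-4
    set.seed(8)
    a <- makeXYZFrame(3, nMobile = 1, nRef = 4)
    noisyRef <- rigidTransform(a@reference) + matrix(rnorm(12, sd = 0.3),
                                                     ncol = 3)
    b <- StructureFrame("v", 2, rigidTransform(a@mobile), noisyRef)
    got <- superpose(b, a)$rmsd
    want <- bruteForceFitRMSD(b@reference, a@reference)
    expect_equal(got, want, tolerance = 1e-4 / max(want, 1e-4))

    # angular mode: identity with zero fit RMSD
    s2 <- superpose(c(10, 20), c(50, 60))
    expect_identical(s2$frame, c(10, 20))
    expect_identical(s2$rmsd, 0)

    tooFew <- StructureFrame("v", 1, matrix(rnorm(9), 3),
                             matrix(rnorm(6), 2))
    expect_error(superpose(tooFew, tooFew), "underdetermined")
})

test_that("loop RMSD follows the closed form in both geometries", {
    # identical frames: 0
    expect_identical(loopRMSD(c(0, 0), c(0, 0)), 0)
    f <- makeXYZFrame(2)
    expect_identical(loopRMSD(f, f), 0)

    # every point displaced by d: RMSD = d
    g <- StructureFrame(f@variantId, 2, f@mobile + 2.5, f@reference)
    expect_equal(loopRMSD(f, g), sqrt(3) * 2.5, tolerance = 1e-12)

    # shortest-arc wrap in angular mode
    expect_equal(loopRMSD(c(170, 0), c(-170, 0)), sqrt(20^2 / 2))

    # random pairs equal an independent direct-formula recomputation
    set.seed(11)
    for (i in 1:20) {
        x <- runif(6, -180, 180); y <- runif(6, -180, 180)
        d <- wrapDeg(x - y)
        expect_equal(loopRMSD(x, y), sqrt(mean(d^2)), tolerance = 1e-10)
    }
    expect_error(loopRMSD(c(1, 2), c(1, 2, 3)), "mismatch")
})

test_that("leader clustering respects the cutoff definition", {
    snap <- function(X, v = "v") new("SnapshotSet", variantId = v,
                                     temperature = 310, frames = X,
                                     times = seq_len(nrow(X)))
    # one frame: one conformer containing it
    cat1 <- clusterFrames(list(snap(matrix(c(0, 0), 1))), cutoff = 40)
    expect_identical(nConformers(cat1), 1L)
    expect_identical(assignments(cat1), 1L)

    # two frames beyond the cutoff: two conformers; within: one
    far <- snap(rbind(c(0, 0), c(90, 90)))
    near <- snap(rbind(c(0, 0), c(20, 20)))
    expect_identical(nConformers(clusterFrames(list(far), cutoff = 40)), 2L)
    expect_identical(nConformers(clusterFrames(list(near), cutoff = 40)), 1L)

    # empty input: empty catalog, not an error
    empty <- clusterFrames(list(snap(matrix(numeric(0), 0, 2))))
    expect_identical(nConformers(empty), 0L)
})

test_that("clustering agrees with an independent leader re-implementation", {
    set.seed(21)
    X <- matrix(runif(400, -180, 180), ncol = 2)
    snap <- new("SnapshotSet", variantId = "v", temperature = 310,
                frames = X, times = seq_len(200))
    cat_ <- clusterFrames(list(snap), cutoff = 40)
    oracle <- leaderOracle(X, 40, denom = 2, angular = TRUE)
    expect_identical(assignments(cat_),
                     relabelBySize(oracle$assignment,
                                   length(oracle$centers)))
    expect_identical(nConformers(cat_), length(oracle$centers))

    # coverage: every frame within the cutoff of its center
    cen <- centers(cat_)
    asg <- assignments(cat_)
    radii <- vapply(seq_len(nrow(X)), function(i)
        loopRMSD(X[i, ], cen[asg[i], ]), numeric(1))
    expect_true(all(radii <= 40))

    # separation: centers pairwise beyond the cutoff
    if (nrow(cen) > 1) {
        seps <- unlist(lapply(seq_len(nrow(cen) - 1), function(i)
            vapply((i + 1):nrow(cen), function(j)
                loopRMSD(cen[i, ], cen[j, ]), numeric(1))))
        expect_true(all(seps > 40))
    }
})

test_that("pooled clustering recovers planted basins across variants", {
    panel <- makeVariantPanel(seed = 5)
    lads <- landscapes(panel)
    cfg <- SamplerConfig(20000, 20, 20, 4000, seed = 100, jumpProb = 0.25)
    lad <- buildLadder(290, 10, 8)
    snaps <- lapply(lads, function(l) {
        cfg@seed <- cfg@seed + 1L
        snapshotAt(runParallelTempering(l, lad, cfg,
                                        keepTemperatures = 310), 310)
    })
    cat_ <- clusterFrames(snaps, cutoff = 40)

    # per-variant conformer counts sum to that variant's frame count
    for (v in names(lads))
        expect_length(variantAssignments(cat_, v), nrow(frames(snaps[[v]])))

    # basins are far beyond the cutoff, so the catalog finds one major
    # conformer per live basin and assignment matches nearest-basin truth
    # for >= 99% of frames
    C <- do.call(rbind, lapply(basins(lads[[1]]), function(b) b@center))
    agree <- 0L; tot <- 0L
    basin2conf <- vapply(seq_len(nrow(C)), function(b) {
        d <- vapply(seq_len(nConformers(cat_)), function(k)
            loopRMSD(C[b, ], centers(cat_)[k, ]), numeric(1))
        which.min(d)
    }, integer(1))
    for (v in names(lads)) {
        X <- frames(snaps[[v]])
        asg <- variantAssignments(cat_, v)
        nb <- max.col(-vapply(seq_len(nrow(C)), function(b)
            rowSums(wrapDeg(sweep(X, 2, C[b, ]))^2),
            numeric(nrow(X))), ties.method = "first")
        agree <- agree + sum(asg == basin2conf[nb])
        tot <- tot + length(asg)
    }
    expect_gte(agree / tot, 0.99)

    # the major conformers are exactly the planted live-basin count
    big <- sum(conformerSizes(cat_) / length(assignments(cat_)) > 0.01)
    expect_identical(big, 5L)
})
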