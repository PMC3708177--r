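test_that("exact populations match symmetry and closed-form two-state limits", {
    # single basin: everything belongs to it
    one <- VariantLandscape("one", list(Basin("a", c(0, 0), 6, 25)))
    expect_equal(unname(exactPopulations(one, 5)), 1)

    # two identical basins: 0.5 / 0.5 by symmetry (up to the documented
    # lower-id tie-break on the measure-near-zero separatrix)
    sym <- twoBasinLandscape(6, 6)
    p <- exactPopulations(sym, 5)
    expect_equal(unname(p), c(0.5, 0.5), tolerance = 2e-3)

    # dE = 1 kcal/mol at 310 K with entropy-matched widths: the two-state
    # ratio exp(-dE/kT)/(1 + exp(-dE/kT)) = 0.1648 up to the small
    # anharmonic correction of the Gaussian wells
    kT <- kBoltzmann * 310
    closed <- exp(-1 / kT) / (1 + exp(-1 / kT))
    lsc <- twoBasinLandscape(9, 8, w1 = 25, w2 = 25 * sqrt(8 / 9))
    expect_lt(abs(exactPopulations(lsc, 2)[["b"]] - closed), 0.005)
})

test_that("exact populations converge under grid refinement and sum to 1", {
    lsc <- threeBasinLandscape()
    p4 <- exactPopulations(lsc, 4)
    p2 <- exactPopulations(lsc, 2)
    expect_equal(sum(p4), 1, tolerance = 1e-9)
    expect_lt(max(abs(p4 - p2)), 1e-3)
    expect_error(exactPopulations(lsc, 7), "divide")
})

test_that("variant panel plants a consistent phenotype and is deterministic", {
    panel <- makeVariantPanel(seed = 42)
    truth <- plantedTruth(panel)
    calls <- phenotypeCalls(panel)

    # phenotype is exactly reproducible from the truth by thresholding
    for (t in names(truth@designated)) {
        b <- truth@designated[[t]]
        for (v in rownames(calls)) {
            p <- truth@populations$population[
                truth@populations$variant == v & truth@populations$basin == b]
            expect_identical(calls[v, t],
                             if (p > truth@threshold) "binds" else "no_binding")
        }
    }
    # Table-I-like design: parent binds all, three binders per target
    expect_true(all(calls["parent", ] == "binds"))
    expect_identical(unname(colSums(calls == "binds")), c(3, 3))

    # planted basins stay distinguishable by the default clustering cutoff
    land <- landscapes(panel)[[1]]
    C <- do.call(rbind, lapply(basins(land), function(b) b@center))
    dmin <- min(vapply(seq_len(nrow(C) - 1), function(i)
        min(vapply((i + 1):nrow(C), function(j)
            sqrt(mean(wrapDeg(C[i, ] - C[j, ])^2)), numeric(1))), numeric(1)))
    expect_gt(dmin, 40)

    # determinism: same seed, same spec => identical panels
    panel2 <- makeVariantPanel(seed = 42)
    expect_identical(plantedTruth(panel2)@populations, truth@populations)
    expect_identical(phenotypeCalls(panel2), calls)
    expect_identical(landscapes(panel2)[["mut3"]]@perturbations,
                     landscapes(panel)[["mut3"]]@perturbations)

    expect_error(makeVariantPanel(nBasins = 1, seed = 1), "invalid config")
    expect_error(makeVariantPanel(variantIds = c("a", "a", "b", "c", "d"),
                                  seed = 1), "duplicate")
})

test_that("minimal two-variant panel forces one binder and one non-binder", {
    panel <- makeVariantPanel(nBasins = 2, targets = "T1", nVariants = 2,
                              seed = 3)
    calls <- phenotypeCalls(panel)
    expect_identical(sort(unname(calls[, "T1"])), c("binds", "no_binding"))
})

test_that("clone library respects the rate profile", {
    sp <- defaultLoopSpec()
    region <- loopRegion(sp)

    # rate 0 everywhere: all clones identical to the parent
    lib0 <- makeCloneLibrary(sp, 5, rep(0, length(region)),
                             scaffoldRate = 0, seed = 1)
    expect_true(all(as.character(cloneSequences(lib0)) == sp@parentSequence))
    expect_identical(vapply(cloneTruth(lib0), nrow, integer(1)),
                     setNames(rep(0L, 5), names(cloneTruth(lib0))))

    # rate 1 at one position only: every clone mutated exactly there
    prof <- rep(0, length(region))
    prof[region == 39] <- 1
    lib1 <- makeCloneLibrary(sp, 8, prof, scaffoldRate = 0, seed = 2)
    for (tr in cloneTruth(lib1)) {
        expect_identical(tr$position, 39L)
        expect_identical(tr$from, "F")
    }

    # default rates: expected in-region clone fraction 1 - 0.9^18 = 0.85,
    # observed within 3 binomial standard errors at n = 1000
    lib <- makeCloneLibrary(sp, 1000, scaffoldRate = 0, seed = 7)
    frac <- mean(vapply(cloneTruth(lib), function(tr)
        any(tr$position %in% region), logical(1)))
    p0 <- 1 - 0.9^length(region)
    expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / 1000))

    expect_error(makeCloneLibrary(sp, 5, rep(0.1, 3), seed = 1), "length")
    expect_error(makeCloneLibrary(sp, 5, rep(1.5, length(region)), seed = 1),
                 "\\[0, 1\\]")
})

test_that("assay readouts carry the requested mean, spread and reference", {
    # noise 0: replicates equal the mean; reference fixed at 100
    tab <- makeAssayReadouts(c(A = 70), sem = 0, nReps = 4, seed = 1)
    expect_identical(tab$score[tab$condition == "A"], rep(70, 4))
    expect_identical(tab$score[tab$condition == "Trx"], rep(100, 4))
    expect_error(makeAssayReadouts(c(A = 70), sem = 1, nReps = 1, seed = 1),
                 "insufficient")

    # same seed, same table
    expect_identical(makeAssayReadouts(c(A = 70, B = 90), 5, 4, seed = 9),
                     makeAssayReadouts(c(A = 70, B = 90), 5, 4, seed = 9))

    # mean 70 with small SEM at n = 4: downstream one-tailed p < 0.05 in
    # >= 95% of 1000 seeded draws (near-certain power for a 6-sigma shift)
    hits <- vapply(1:1000, function(s) {
        tb <- makeAssayReadouts(c(A = 70), sem = 5, nReps = 4, seed = s)
        oneTailedTVsReference(tb$score[tb$condition == "A"])$p < 0.05
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})
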