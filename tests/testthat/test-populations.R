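test_that("the SEM formula matches its hand evaluation and sd/sqrt(n)", {
    # hand evaluation: blocks {10,20,30,40} -> mean 25,
    # SEM = sqrt((225+25+25+225)/(4*3)) = 6.455
    bs <- blockStatistics(c(10, 20, 30, 40))
    expect_equal(bs@mean, 25)
    expect_equal(bs@sem, sqrt(500 / 12), tolerance = 1e-12)
    expect_equal(round(bs@sem, 3), 6.455)

    # textbook identity to machine precision on random inputs
    set.seed(3)
    for (i in 1:25) {
        x <- rnorm(sample(2:12, 1), sd = runif(1, 0.1, 50))
        expect_equal(semOfMean(x), sd(x) / sqrt(length(x)),
                     tolerance = 1e-12)
    }
    expect_identical(semOfMean(c(5, 5, 5)), 0)
    expect_error(semOfMean(3), "two observations")
})

test_that("block populations split the trajectory as specified", {
    # all four blocks at 25%: 96 frames, each 24-frame block holds each
    # conformer exactly 6 times
    asg <- rep(rep(1:4, each = 2), times = 12)
    bp <- blockPopulation(asg, nBlocks = 4)
    expect_equal(bp$stats$mean_pct, rep(25, 4))
    expect_equal(bp$stats$sem_pct, rep(0, 4))

    # canonical schedule: 1e6-unit production in 4 blocks of 2.5e5 units
    # (50,000 frames -> 12,500 per block)
    expect_identical(countSnapshots(1.2e6, 20, 2e5) %/% 4L, 12500L)

    # a remainder is dropped with a message
    expect_message(blockPopulation(rep(1, 103), nBlocks = 4), "remainder")
    expect_error(blockPopulation(rep(1, 100), nBlocks = 1), ">= 2")
    expect_error(blockPopulation(c(1, 2), nBlocks = 4), "fewer frames")

    # hand-checkable block pattern: conformer 1 fills blocks 1-2 only
    asg2 <- c(rep(1, 50), rep(2, 50))
    bp2 <- blockPopulation(asg2, nBlocks = 4)
    expect_equal(bp2$blocks[, "1"], c(100, 100, 0, 0))
    expect_equal(bp2$stats$mean_pct, c(50, 50))
    expect_equal(bp2$stats$sem_pct, rep(100 / sqrt(12), 2))
})

test_that("the populated call uses a strict mean > 2 SEM rule", {
    expect_false(significanceCall(0, 0))          # empty conformer
    expect_true(significanceCall(10, 1))
    expect_false(significanceCall(4, 2))          # boundary: strict
    expect_true(significanceCall(blockStatistics(c(9, 11, 10, 10))))
    expect_false(significanceCall(blockStatistics(c(0, 0, 4, 0))))
})

test_that("free energies follow -kT ln(P_i/P_max)", {
    expect_identical(freeEnergy(0.3, 0.3, 310), 0)
    expect_equal(freeEnergy(0.5, 1, 310), 0.0019872 * 310 * log(2),
                 tolerance = 1e-12)
    expect_equal(round(freeEnergy(0.5, 1, 310), 3), 0.427)
    expect_equal(freeEnergy(exp(-1), 1, 310), 0.0019872 * 310,
                 tolerance = 1e-12)
    expect_equal(round(freeEnergy(exp(-1), 1, 310), 3), 0.616)
    expect_error(freeEnergy(0, 1, 310), "not populated")
    expect_error(freeEnergy(0.6, 0.5, 310), "exceed")

    # strictly decreasing in P_i
    p <- seq(0.05, 1, by = 0.05)
    expect_true(all(diff(freeEnergy(p, 1, 310)) < 0))
})

test_that("population tables are normalized, ordered and exportable", {
    # two-variant toy catalog built by hand: variant v1 sits 3:1 across
    # two conformers in every block, v2 only in conformer 1
    v1asg <- rep(c(1L, 1L, 1L, 2L), times = 40)   # 160 frames, 75/25 split
    cat_ <- new("ConformerCatalog", centers = rbind(c(0, 0), c(120, 120)),
                assignment = c(v1asg, rep(1L, 80)),
                variant = c(rep("v1", 160), rep("v2", 80)),
                time = c(seq_len(160), seq_len(80)),
                cutoff = 40, mode = "angular", denom = 2)
    pop <- buildPopulationTable(cat_, temperature = 310)
    tb <- as.data.frame(pop)

    # normalization before significance filtering
    expect_equal(as.vector(tapply(tb$pop_pct, tb$variant, sum)),
                 c(100, 100), tolerance = 1e-9)

    # v1: 75/25 split, dG = -kT ln(25/75)
    v1 <- tb[tb$variant == "v1", ]
    expect_equal(v1$pop_pct, c(75, 25))
    expect_equal(v1$dG_kcal_mol[2], freeEnergy(25, 75, 310))
    expect_identical(v1$dG_kcal_mol[1], 0)

    # v2: single conformer at 100%, the other not populated with NA dG
    v2 <- tb[tb$variant == "v2", ]
    expect_equal(v2$pop_pct, c(100, 0))
    expect_identical(v2$populated, c(TRUE, FALSE))
    expect_true(is.na(v2$dG_kcal_mol[2]))

    # dG ordering is anti-monotone in population within each variant
    for (v in c("v1", "v2")) {
        sub <- tb[tb$variant == v & tb$populated, ]
        expect_true(all(diff(sub$dG_kcal_mol[order(-sub$pop_pct)]) >= 0))
    }

    # classic layout export: "pct (err) dG" and "n.p."
    fmt <- formatPopulationTable(pop)
    expect_identical(fmt["2", "v2"], "n.p.")
    expect_match(fmt["1", "v1"], "^75.0 \\(0.0\\) 0.0$")

    # TSV export writes n.p. markers
    tsv <- tempfile(fileext = ".tsv")
    writePopulationTable(pop, tsv)
    out <- read.delim(tsv)
    expect_identical(out$dG_kcal_mol[out$variant == "v2" & out$conformer == 2],
                     "n.p.")
})

test_that("quadrupling the trajectory roughly halves the median SEM", {
    # individual 4-block SEM estimates are noisy, so the scaling law is
    # checked on seed-averaged SEMs, with frequent jump proposals so the
    # basin-flip time stays well below one block even at the short length
    lsc <- twoBasinLandscape()
    lad <- buildLadder(290, 10, 8)
    medSEM <- function(total, seed) {
        run <- runParallelTempering(lsc, lad,
            SamplerConfig(total, 20, 20, total / 4, seed = seed,
                          jumpProb = 1), keepTemperatures = 310)
        ss <- snapshotAt(run, 310)
        asg <- max.col(-cbind(
            rowSums(wrapDeg(sweep(frames(ss), 2, c(0, 0)))^2),
            rowSums(wrapDeg(sweep(frames(ss), 2, c(180, 180)))^2)),
            ties.method = "first")
        suppressMessages(
            median(blockPopulation(asg, conformers = 1:2)$stats$sem_pct))
    }
    seeds <- 101:112
    ratio <- mean(vapply(seeds, medSEM, numeric(1), total = 4e4)) /
             mean(vapply(seeds, medSEM, numeric(1), total = 1.6e5))
    expect_gt(ratio, 2 * 0.7)
    expect_lt(ratio, 2 * 1.3)
})
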