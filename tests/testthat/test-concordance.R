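test_that("the five-variant reconstruction yields the known candidate sets", {
    rec <- tableOneReconstruction()

    # CnA: conformer 13 is the only conformer populated in all three
    # binders and absent from both non-binders
    cna <- consensusConformers(rec$populations, rec$phenotype, "CnA")
    expect_identical(candidates(cna), 13L)
    expect_identical(sort(cna@binderSet), sort(c("R5G42", "S35P", "F39I")))

    # NS5A-TP2 step 1: four conformers populated in all three binders
    ns <- consensusConformers(rec$populations, rec$phenotype, "NS5A-TP2")
    expect_identical(ns@considered, c(2L, 4L, 7L, 9L))

    # without annotations the non-binder veto (S35P populates 2 and 7,
    # F39I populates 4 and 9) wipes out the whole set
    expect_identical(candidates(ns), integer(0))
    expect_identical(sort(unique(ns@exclusionLog$conformer)),
                     c(2L, 4L, 7L, 9L))

    # the aromaticity annotation exempts F39I's veto: {4, 9} remain
    ns2 <- consensusConformers(rec$populations, rec$phenotype, "NS5A-TP2",
                               annotations = rec$annotations)
    expect_identical(sort(candidates(ns2)), c(4L, 9L))
    expect_identical(sort(unique(ns2@exclusionLog$conformer)), c(2L, 7L))
    expect_match(paste(ns2@exclusionLog$reason, collapse = " "), "S35P")
})

test_that("accessibility profiles propagate free energies and n.p. markers", {
    rec <- tableOneReconstruction()
    prof <- accessibilityProfile(rec$populations,
                                 c("F39I", "R5G42", "S35P", "S35A"), 13)
    expect_equal(unname(prof[c("F39I", "R5G42", "S35P")]), c(0.2, 2.3, 1.2))
    expect_identical(max(prof, na.rm = TRUE), 2.3)
    # not populated: NA, never zero
    expect_true(is.na(prof[["S35A"]]))
    expect_error(accessibilityProfile(rec$populations, "R5G42", 99),
                 "not in the table")

    # a variant's most populated conformer sits at dG exactly 0
    tb <- data.frame(variant = "v", conformer = 1:2,
                     pop_pct = c(60, 40), sem_pct = c(1, 1),
                     populated = TRUE,
                     dG_kcal_mol = c(0, freeEnergy(40, 60, 310)))
    expect_identical(accessibilityProfile(tb, "v", 1)[["v"]], 0)
})

test_that("the accessibility threshold and degenerate inputs behave", {
    rec <- tableOneReconstruction()
    # dG_max below 2.3 kcal/mol removes conformer 13 for CnA (its max
    # over binders is the 2.3 of the parent)
    strict <- consensusConformers(rec$populations, rec$phenotype, "CnA",
                                  dGmax = 1.2)
    expect_identical(candidates(strict), integer(0))
    expect_match(strict@exclusionLog$reason[1], "accessibility")
    loose <- consensusConformers(rec$populations, rec$phenotype, "CnA",
                                 dGmax = 2.5)
    expect_identical(candidates(loose), 13L)

    # all conformers populated everywhere: empty candidate set after veto
    tb <- expand.grid(variant = c("b1", "b2", "n1"), conformer = 1:3)
    tb$pop_pct <- 100 / 3; tb$sem_pct <- 1; tb$populated <- TRUE
    tb$dG_kcal_mol <- 0.1
    ph <- PhenotypeMatrix(matrix(c("binds", "binds", "no_binding"), 3, 1,
                                 dimnames = list(c("b1", "b2", "n1"), "T")))
    rep_ <- consensusConformers(tb, ph, "T")
    expect_identical(candidates(rep_), integer(0))
    expect_identical(length(rep_@considered), 3L)

    # no binders: warning and empty flagged report
    ph0 <- PhenotypeMatrix(matrix("no_binding", 3, 1,
                                  dimnames = list(c("b1", "b2", "n1"), "T")))
    expect_warning(r0 <- consensusConformers(tb, ph0, "T"), "no binders")
    expect_true(r0@noBinders)
    expect_error(consensusConformers(tb, ph, "nope"), "unknown target")

    # force_exclude removes a conformer with its reason on record
    ann <- data.frame(variant = NA, conformer = 13, target = NA,
                      action = "force_exclude", reason = "surface identical")
    forced <- consensusConformers(rec$populations, rec$phenotype, "CnA",
                                  annotations = ann)
    expect_identical(candidates(forced), integer(0))
    expect_match(forced@exclusionLog$reason[1], "force-excluded")
})

test_that("candidate sets shrink monotonically as evidence accumulates", {
    # random populated patterns: adding a binder or a non-binder can only
    # shrink the candidate set
    set.seed(13)
    for (rep_ in 1:10) {
        variants <- paste0("v", 1:5)
        tb <- expand.grid(variant = variants, conformer = 1:6,
                          stringsAsFactors = FALSE)
        tb$populated <- runif(nrow(tb)) < 0.6
        tb$pop_pct <- ifelse(tb$populated, 10, 0)
        tb$sem_pct <- 1
        tb$dG_kcal_mol <- ifelse(tb$populated, runif(nrow(tb), 0, 2), NA)

        mkPheno <- function(calls) PhenotypeMatrix(
            matrix(calls, length(variants), 1,
                   dimnames = list(variants, "T")))
        base <- c("binds", "binds", "no_binding", "undetermined",
                  "undetermined")
        addBinder <- replace(base, 4, "binds")
        addNonBinder <- replace(base, 4, "no_binding")

        c0 <- candidates(consensusConformers(tb, mkPheno(base), "T"))
        cB <- candidates(consensusConformers(tb, mkPheno(addBinder), "T"))
        cN <- candidates(consensusConformers(tb, mkPheno(addNonBinder), "T"))
        expect_true(all(cB %in% c0))
        expect_true(all(cN %in% c0))

        # determinism: pure function of its inputs
        expect_identical(
            candidates(consensusConformers(tb, mkPheno(base), "T")), c0)
    }
})

test_that("noise-free analytic populations always recover the planted binder", {
    # bypass sampling: feed the exact populations straight into the
    # concordance step
    panel <- makeVariantPanel(seed = 8)
    truth <- plantedTruth(panel)
    tp <- truth@populations
    tb <- do.call(rbind, lapply(unique(tp$variant), function(v) {
        p <- tp$population[tp$variant == v]
        popd <- p > 0.01
        data.frame(variant = v, conformer = as.integer(tp$basin[tp$variant == v]),
                   pop_pct = 100 * p, sem_pct = 0.01, populated = popd,
                   dG_kcal_mol = ifelse(popd,
                       -kBoltzmann * 310 * log(p / max(p[popd])), NA))
    }))
    for (t in names(truth@designated)) {
        rep_ <- consensusConformers(tb, panel@phenotype, t)
        expect_identical(candidates(rep_),
                         as.integer(truth@designated[[t]]))
    }

    # binder basin abolished everywhere: no binders remain for the target,
    # hence an empty flagged report
    land <- landscapes(panel)[[1]]
    allOff <- matrix(FALSE, 5, 2,
                     dimnames = dimnames(phenotypeCalls(panel)))
    ph <- PhenotypeMatrix(ifelse(allOff, "binds", "no_binding"))
    expect_warning(r <- consensusConformers(tb, ph, "CnA"), "no binders")
    expect_identical(candidates(r), integer(0))
})
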