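Package: loopscape
Title: Conformational Dissection of Peptide Aptamer Target Specificity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the target specificity of peptide aptamers
    by conformational analysis of their variable loop. Provides a surrogate
    multi-basin energy model of the loop in torsion space, a replica-exchange
    (parallel tempering) Metropolis sampler with the canonical temperature
    ladder and swap schedule, RMSD-based leader clustering of loop snapshots
    into conformers, block-averaged conformer populations with standard errors
    and relative free energies (-kT ln(P_i/P_max)), and the concordance logic
    that cross-references conformer populations with yeast two-hybrid binding
    phenotypes to nominate target-specific binding conformers by
    conformational selection. Also includes mutant-library screen
    bookkeeping (per-position mutation frequency profiles, binding-phenotype
    cross-tabulations) and cell-assay statistics (CMTMR proliferation scores,
    one-tailed t tests versus a reference condition, NFAT nuclear-signal
    summaries), plus synthetic-data generators with planted ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    Biostrings,
    bio3d
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'loopscape-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'landscape.R'
    'sampler.R'
    'clustering.R'
    'populations.R'
    'concordance.R'
    'synthetic.R'
    'screen.R'
    'assay.R'
    'io.R'
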