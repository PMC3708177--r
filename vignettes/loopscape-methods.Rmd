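---
title: "Dissecting peptide-aptamer target specificity from loop conformer populations"
author: "loopscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting peptide-aptamer target specificity from loop conformer populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopscape)
```

## The problem

A peptide aptamer displays a variable peptide loop (here residues 35--44 of
a thioredoxin scaffold, plus four flanking residues on each side) that can
bind unrelated targets -- in the motivating system, the phosphatase subunit
calcineurin A (CnA) and the HD-domain protein NS5A-TP2/HDDC2. Single point
mutations in the loop (S35A, S35P, F39I, F39Y) switch binding on or off per
target. Under a conformational-selection model, each target recognizes a
particular loop conformer that pre-exists in the unbound ensemble; a
mutation that abolishes binding does so either by depopulating that
conformer or by destroying a chemical contact while leaving the conformer
intact. loopscape implements the computational chain that turns this model
into a testable inference:

1. sample the loop's conformational ensemble per variant
   (`runParallelTempering`),
2. pool all variants' snapshots and group them into conformers by RMSD
   leader clustering (`clusterFrames`),
3. convert per-variant conformer counts into block-averaged populations
   with errors and relative free energies (`buildPopulationTable`),
4. cross-reference populations with yeast two-hybrid (Y2H) binding
   phenotypes to nominate, per target, the conformers consistent with
   binding by conformational selection (`consensusConformers`).

Companion modules cover the mutagenesis-screen bookkeeping
(`classifyClone`, `mutationProfile`, `phenotypeCrosstab`) and the cell
assay statistics (`proliferationScore`, `oneTailedTVsReference`,
`nfatSummary`).

## The surrogate loop model

All-atom simulation of the aptamer is out of scope here; the sampling and
inference machinery instead operates on a surrogate energy model that
preserves the features the downstream statistics depend on -- multiple
metastable conformers with tunable populations -- while remaining
analytically integrable, so every stage can be validated against exact
ground truth.

The loop is described by collective pseudo-torsion coordinates on a
periodic torus (degrees). By default one torsion pair (a two-dimensional
torus) stands in for the loop's essential degrees of freedom; the
dimension is configurable (`nTorsionPairs`), but it is deliberately kept
low because the analytic oracle -- Boltzmann summation over a discretized
grid (`exactPopulations`) -- must stay tractable. A per-residue torsion
description of the ten-residue loop would give a 20-dimensional torus on
which no grid oracle is possible; the low-dimensional collective
description is the package's accuracy-for-verifiability trade.

The energy is a sum of negative Gaussian wells, one per conformational
basin:

$$ E(\theta) = -\sum_b D_b \exp\!\left(-\frac{d(\theta, c_b)^2}{2 w_b^2}\right), $$

with $d$ the wrapped Euclidean distance in degrees, depth $D_b$ in
kcal/mol and width $w_b$ in degrees. A mutation is encoded as a per-basin
perturbation subtracted from the depth; a perturbation reaching the depth
abolishes the basin. Wells are truncated beyond six widths, where their
contribution falls below $10^{-7}$ kcal/mol, so the compiled sampler and
the R energy agree to rounding. Throughout, $k = 0.0019872$
kcal mol$^{-1}$ K$^{-1}$.

Two numerical consequences of this geometry shaped the defaults:

* **Depths are 8--9 kcal/mol.** The torus has a large flat region between
  wells whose Boltzmann weight scales as $e^{-D/kT}$ relative to the well
  bottoms. The populated-call of the analysis (mean population strictly
  above twice its block SEM) can detect populations down to roughly one
  frame per block, i.e. $\sim 10^{-4}$; wells of 8--9 kcal/mol push the
  flat background one order of magnitude below that, so an abolished
  conformer is genuinely called "not populated" rather than being
  resurrected by background frames.
* **Well entropy depends on depth.** For Gaussian wells the local
  partition function carries a Laplace prefactor $2\pi w^2 kT / D$ per
  torsion pair, so two wells differing by $\Delta E$ in depth do *not*
  split populations exactly as $e^{-\Delta E / kT}$ unless their widths
  are scaled as $w \propto \sqrt{D}$. The two-state validation landscape
  in the test suite does exactly that, and the residual anharmonic
  correction (about 1% relative at 8--9 kcal/mol depths) sets its
  tolerance.

## Replica-exchange sampler

`runParallelTempering` simulates all heat baths of an arithmetic ladder
$T_n = T_0 + n\,\Delta T$ (default 24 baths, 290--520 K). Within each bath
one time unit is one Metropolis sweep: a single-coordinate proposal of
half-width `stepSize` (default 30 degrees) per torsion, plus, with
probability `jumpProb`, one whole-torus uniform jump proposal. The jump is
a symmetric independence proposal, so the kernel remains plain Metropolis;
it is what carries replicas between wells that are deep enough to defeat
stepwise diffusion even at 520 K. The default `jumpProb = 0.5` was chosen
so that the basin-flip time at 310 K (on default panels, order $10^3$
sweeps) sits far below one analysis block; with rare jumps the block means
are correlated and the 4-block SEM underestimates the true error.

Every `swapInterval` units (default 20) one parity of adjacent-bath pairs
-- even pairs $(T_{2i}, T_{2i+1})$ or odd pairs $(T_{2i+1}, T_{2i+2})$,
chosen by fair coin -- is exchanged under the Metropolis criterion
$\min\{1, \exp[(\beta_i - \beta_j)(E_i - E_j)]\}$. The acceptance rule is
the canonical replica-exchange choice. Snapshots are recorded every
`snapshotInterval` units (default 20) after the swap attempt, once the
equilibration span (default $2 \times 10^5$ of $1.2 \times 10^6$ total
units) has passed: 50,000 production frames per bath under the default
schedule, with 60,000 swap attempts. All baths can be stored; analyses
use the 310 K bath.

Replicas start at the deepest live basin center (deterministically), and
the whole run is a pure function of the configuration seed.

## Clustering and populations

Frames pooled across variants -- variants in declared order, frames in
time order -- are grouped by the leader (first-fit) scan: a frame joins
the first existing center within the cutoff (centers scanned in creation
order) or founds a new center. Pooling across variants is what makes
conformer labels comparable between variants: a conformer is one region
of loop-conformation space regardless of which variant visits it. The
distance is the shortest-arc angular RMS over torsions (default cutoff
40 degrees, the surrogate counterpart of a 2 Å heavy-atom RMSD cutoff);
a Cartesian mode with Kabsch superposition on the rigid scaffold atoms
(via `bio3d::fit.xyz`) and RMSD over loop pseudo-atoms is available
behind the same interface for 3-D frames. Leader clustering guarantees
the two properties the downstream table relies on: every frame lies
within the cutoff of its center, and centers are pairwise farther apart
than the cutoff. Conformers are relabelled by descending pooled
population, ties by creation order.

Per variant, the time-ordered assignments are split into four contiguous
blocks (the canonical error protocol; a trailing remainder is dropped with
a message). Per conformer, the block percentages give the mean population,
its SEM $\sqrt{\sum_i (x_i - \bar x)^2 / (n(n-1))}$, and the populated
call: populated if and only if the mean strictly exceeds twice the SEM.
The strictness is a deliberate boundary convention (a conformer at exactly
twice its SEM is *not* populated); an empty conformer has SEM 0 and is not
populated. For populated conformers the free energy relative to the
variant's most populated conformer is $-kT \ln(P_i / P_\mathrm{max})$ at
310 K, with $P_\mathrm{max}$ taken over populated conformers only;
not-populated entries export as `n.p.`. Percentages are carried at full
precision and rounded only on export.

## Concordance inference

For a target, `consensusConformers` applies three steps: (1) keep
conformers populated in *every* binder; (2) optionally require the
maximum free energy over binders to stay below `dGmax` -- the
accessibility threshold is a parameter, not a constant, because moderate
accessibility bounds between roughly 1.2 and 2.5 kcal/mol are all
defensible; (3) exclude conformers populated in *any* non-binder, since
such a conformer cannot by itself discriminate binding from non-binding.
Undetermined phenotypes are ignored on both sides. The plain veto of step
3 is deliberately overridable by explicit annotations: a `veto_exempt`
record encodes expert chemical reasoning (e.g. a mutation that keeps the
conformer populated but destroys an aromatic stacking contact, so its
non-binding says nothing about the conformer), and `force_exclude`
removes a conformer with a recorded reason (e.g. electrostatic surfaces
identical across variants with opposite phenotypes). Annotations are
inputs, never inferred -- the algorithm stays honest about where expert
judgement enters, and every excluded conformer carries its reason in the
report. Candidates are ordered by accessibility cost (maximum
free-energy penalty across binders).

The packaged worked example (`tableOneReconstruction()`) encodes the
five-variant panel pattern: for CnA (binders R5G42, S35P, F39I) a single
candidate survives, conformer 13; for NS5A-TP2 (binders R5G42, S35A,
F39Y) four conformers pass step 1 ({2, 4, 7, 9}) and, after the
non-binder veto with F39I's aromaticity exemption, {4, 9} remain.

## Synthetic panels and what passing tests show

`makeVariantPanel` builds the validation universe: well-separated basins
(fixed torus layouts with pairwise angular RMS separation of at least 90
degrees, randomly shifted and jittered per seed), depths evenly spaced
over 8.2--9.0 kcal/mol, one designated binder basin per target, and
binder/non-binder variants realized by leaving that basin intact or
abolishing it. Non-designated basins of mutant variants get small random
depth perturbations (±0.2 kcal/mol) so populations vary across variants.
Ground truth is computed by grid summation at 2-degree resolution, and
the phenotype matrix is derived from the truth by thresholding the
designated basin's population at `popThreshold` (default 0.05). The
threshold is a generator parameter standing in for an unknown Y2H
detection limit, not an inferred biological constant. By default the
panel mirrors the classic design: a parent binding both targets and four
single-phenotype mutants, three binders and two non-binders per target.

`recoverPlantedBinder` runs the full pipeline on such a panel and checks
(i) that each target's candidate set is exactly the conformer of its
designated basin and (ii) per-cell population recovery,
$|\hat p - p_\mathrm{true}| \le 3\,\mathrm{SEM} + 0.05$ percentage
points, where the absolute floor covers the grid discretization of the
truth and the degenerate cells whose SEM is exactly zero (abolished
basins sampled with zero frames against a truth background of order
$10^{-5}$). Two statistical facts temper the interpretation: with four
blocks the deviation-to-SEM ratio of a perfectly mixed sampler is
$t_3$-distributed, so even ideal sampling keeps only about 94% of live
cells within three SEM; and the binder identification additionally
requires every designated-basin population to clear the significance
call in all binders simultaneously. Recovery rates near 95% are
therefore the theoretical ceiling of this design, not a deficiency of
the sampler.

What the synthetic panel does *not* emulate: atomic interactions,
side-chain packing, solvent, induced fit, or any coupling between
sequence and energy beyond the planted per-basin offsets. Passing the
recovery tests demonstrates that the sampling, clustering, error and
inference machinery is correct on a landscape with known answers -- it
says nothing about the fidelity of any particular force field or about
real aptamer thermodynamics.

## Screen and assay statistics

Clone classification is positional and substitution-only; a clone of the
wrong length is rejected loudly rather than aligned, because the
generator (emulating biased-dNTP PCR) produces substitutions only. Region
labels follow the loop specification (loop 35--44, flanks 31--34 and
45--48 by default). Because the natural denominator of "fraction of
clones mutated in the targeted region" is ambiguous, `mutationProfile`
reports both candidate denominators (all clones, and clones carrying at
least one mutation). Cross-tab percentages are truncated toward zero --
the convention that reproduces the classic printed breakdown
64/9/8/11/6 from counts (145, 21, 19, 26, 14) of 225, which
nearest-integer rounding does not (26/225 = 11.56% would print as 12) --
with full-precision values retained alongside.

The proliferation score is $100 \times \Delta_\mathrm{condition} /
\Delta_\mathrm{reference}$ over the 48-hour CMTMR window, so the
reference (inactive scaffold) maps to 100 and an unchanged signal to 0;
the score is invariant to rescaling the fluorescence units. The one-sided
test of "condition proliferates less than the reference" uses
$t = (100 - \bar x)/\mathrm{SEM}$ with $n - 1$ degrees of freedom (the
one-sample convention; replicates are independent experiments), upper-tail
$p$, and the 0.05 decision level; a zero SEM is reported as degenerate
rather than silently infinite. Outlier removal is supported only as an
explicit exclusion, never automated, because no outlier criterion is part
of the protocol. One SEM formula serves the population blocks, the t test
and the NFAT summaries, and the test suite pins their agreement to
machine precision.

## Problem sizes and numerical choices

The default sampler schedule ($1.2 \times 10^6$ units, 24 baths, 50,000
production frames per bath) runs in seconds per variant thanks to the
compiled core, and the validation harness uses it unchanged. Unit tests
that only probe schedule mechanics use shorter runs (a few thousand
units, 3--8 baths). The SEM-scaling check compares seed-averaged SEMs at
$4 \times 10^4$ versus $1.6 \times 10^5$ units with jumps every sweep,
because individual 4-block SEM estimates carry ~40% relative noise and
shorter runs leave the block length inside the mixing time, outside the
$1/\sqrt{T}$ regime. Grid oracles use 2-degree resolution (halving the
resolution moves no population by more than $10^{-3}$). Ties in
nearest-center assignment break toward the lower basin index; ties in
leader clustering toward the earlier center; both are deterministic.

## Known limitations

* The surrogate is low-dimensional by construction; conclusions about
  real loops require real sampling engines upstream, with this package
  supplying the clustering, population and concordance analysis.
* Leader clustering depends on frame order (documented and fixed); other
  cutoff-respecting cluster algorithms could relabel boundary frames.
* The concordance veto is binary; it has no notion of "largely populated"
  versus "barely populated" non-binder evidence beyond the significance
  call, and conflicting expert overrides are surfaced, not resolved.
* With four blocks, population errors are $t_3$-scale; the populated
  call and the 3-SEM recovery criterion inherit that heaviness.
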