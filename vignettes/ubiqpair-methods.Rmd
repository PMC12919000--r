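---
title: "ubiqpair: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ubiqpair: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

RING and U-box E3 ubiquitin ligases activate ubiquitin transfer by stabilising
the *Closed* conformation of the ubiquitin~E2 conjugate, in which the
hydrophobic patch of ubiquitin centred on Ile44 docks against the E2 crossover
(alpha-2) helix and the ubiquitin C-terminal tail points toward the E2
catalytic cysteine. Which of the ~40 human E2s work with which of the hundreds
of E3s is largely unmapped. `ubiqpair` implements a structure-guided pipeline
for this question: it classifies ternary ubiquitin-E2-E3 complex structures
(experimental or predicted) as Closed or Open, extracts interface and
confidence features, assembles labelled pair/non-pair datasets from a
physical-interaction edge table, and trains a gradient-boosted tree classifier
that predicts functional E2-E3 partners.

## Conformation model

Two diagnostic distances define the conformational call:

* `d_Ile44` — minimum distance from the ubiquitin residue-44 Calpha to any
  crossover-helix Calpha. Cutoff **10 A** (default, `cutoff_params()`).
* `d_tail` — distance from the ubiquitin residue-76 carbonyl carbon to the
  catalytic-cysteine Calpha. Cutoff **12 A**.

A complex is Closed iff `d_Ile44 < 10` and — for *predicted* structures only —
`d_tail < 12`. Experimental conjugates carry a thioester bond that anchors the
tail, so only the Ile44 criterion applies there
(`apply_tail_criterion = FALSE`). Distances are averaged over all copies in an
asymmetric unit before thresholding. E2s without a catalytic cysteine (the
UBE2V family) are labelled Open whenever the tail criterion applies.

Two numerical choices deserve note. First, boundary-equal distances are Open:
the cutoffs are strict inequalities, fixed here because the source material
does not state the boundary behaviour. Second, when residue 76 is unresolved
the C-terminal-most resolved tail residue is used and the result flagged.
There is an internal inconsistency in the source description of the tail
distance (one passage swaps which atom comes from which residue); we implement
the Methods-style definition (ubiquitin carbonyl carbon to cysteine Calpha).

## Secondary structure and the crossover helix

Helix detection is Calpha-geometry based: a five-residue window is helical
when d(i, i+3) lies in [4.5, 6.0] A and d(i, i+4) in [5.8, 7.1] A; strand
windows require d(i, i+2) >= 6.2 A and d(i, i+3) >= 9.0 A. Windows spanning a
chain break (consecutive Calpha gap > 4.5 A) are ignored. This is deliberately
not DSSP: no hydrogens or angle terms, just enough to find the crossover helix
and to separate E3 loops from helices/strands. Curated registry spans always
take precedence over detection, mirroring manual annotation practice.

The E2's E3-binding loop is the coil immediately N-terminal of the crossover
helix, bounded by the nearest upstream secondary-structure element or 12
residues, whichever is shorter. The 12-residue cap is an artifact decision
(the source relied on per-structure annotation and does not bound the coil);
it is flagged in output by construction of the span.

## Interfaces, hydrogen bonds and linchpins

Interface residues are those with a Calpha within **8 A** of a partner-chain
Calpha (symmetric). Hydrogen bonds are detected as inter-chain N/O heavy-atom
pairs within **3.5 A** — distance-only, matching the fidelity of the source
procedure; no hydrogen placement, no angles, sulfur excluded. A *linchpin* is
an E3 residue inside the E2-interaction region (E3 residues with any heavy
atom within 8 A of the E2 binding loop) that hydrogen-bonds both the ubiquitin
tail (canonical residues 71-76) and the E2. A structure is linchpin-positive
when at least half of its copies have one; ties for the reported residue break
to the lowest residue number.

Interface RMSD superposes the model on the reference with a Kabsch fit
computed from paired crossover-helix Calpha atoms only (paired by offset from
the helix start), then evaluates Calpha RMSD over interface residues present
in both structures, per interface and over their union. Ubiquitin residues are
matched by canonical 1-76 position after fusion-window normalisation.

## Confidence scores

From a predicted-aligned-error (PAE) matrix, per-residue pLDDT and chain
spans, the package computes:

* **mean interface PAE** — both matrix orientations averaged over inter-chain
  interface residue pairs; absent for empty interfaces (and therefore *not* a
  model feature);
* **ipSAE** — per alignment direction, the mean of `1/(1+(PAE/d0)^2)` over
  inter-chain pairs with PAE < 10 A, `d0` from the TM-score size law
  `1.24 (n-15)^(1/3) - 1.8` clamped at 1.0, with `n` the number of scored-chain
  residues in at least one qualifying pair; the reported value is the max of
  the two directions. The source defers the exact `d0` law to its reference
  implementation; this contract (qualifying-count law, floor 1.0, max
  aggregation) is fixed here and locked by brute-force oracle tests;
* **pDockQ2** — `1.31/(1+exp(-0.075 (x - 84.733))) + 0.005` with
  `x = mean interface pLDDT x mean 1/(1+(PAE/10)^2)`; constants transcribed
  from the reference implementation into `R/constants.R`;
* **pDockQ** (v1) — `0.724/(1+exp(-0.052 (x - 152.611))) + 0.018` with
  `x = mean interface pLDDT x log(n contacts)`; contacts use the package's
  8 A Calpha rule (the original uses Cbeta; Calpha keeps one interface
  definition throughout);
* **ipTM** — stored chain-pair values pass through; otherwise a pTM-style
  score is computed from the PAE matrix (max over aligned residues of the mean
  transform, both directions, `d0` from the chain-pair size).

All scores are invariant to chain relabeling and monotone non-increasing under
uniform PAE inflation; both properties are tested.

## Dataset construction

E3s are classified from domain content: HECT -> HECT, U-box -> UBOX,
RING+IBR -> RBR, RING alone -> RING, RING+HECT -> ATYPICAL, none -> NONE
(precedence ATYPICAL > HECT > UBOX > RBR > RING). RING/U-box truncation spans
take `[min start, max end]` over ECOD RING/U-box domains, each expanded to the
union with overlapping TED domains, falling back to PROSITE spans; intervening
sequence between multiple domains is deliberately retained.

Pair labels come from a STRING-style physical-subnetwork edge table: edges
with experimental evidence score >= 400 (inclusive) are pairs. The non-pair
candidate pool is the Cartesian product of the pair set's unique E2s and E3s,
minus every combination with any evidence (combined score > 0) and minus the
pair set; sampling is uniform under an explicit recorded seed. The default
exclusion policy drops HECT/RBR-specific (UBE2L3/6/5), catalytically inactive
(UBE2V1/2) and SUMO-specific (UBE2I) E2s, and RBR-class E3s.

## The classifier

Features are 3 interfaces x 11 per-interface quantities (ipSAE, ipTM, pDockQ,
pDockQ2, dG, dSASA total/polar/nonpolar, hydrogen bonds total/unsatisfied,
interface residue count) plus 5 complex-level quantities (the two diagnostic
distances, linchpin flag, E3 loop and loop-residue counts) — 38 columns.
Non-Closed complexes are removed before training; a feature with more than
20% missingness is a schema error.

No gradient-boosted-tree package is available in the target environment, so
the engine is implemented in the package (src/gbt.cpp): second-order gradient
boosting with logistic loss, exact greedy splits, depth-limited trees, L2 leaf
regularisation and deterministic per-tree column subsampling
(`colsample_bytree = 0.7` by default, xorshift sampler independent of R's
RNG). It is the same algorithm family as the XGBoost classifier the source
used, and fully deterministic for fixed inputs and seeds.

Evaluation is nested stratified cross-validation (5 outer folds default):
hyperparameters (a small grid over depth, learning rate, tree count — the
source reports tuning without values) and importance-threshold feature
selection (keep features with gain >= the mean gain of a preliminary fit; the
source names an automated selector without its threshold) are chosen strictly
inside inner folds. The preliminary fit uses aggressive column subsampling
(0.3) so that gain importance spreads across all informative features — a
saturating booster otherwise piles its gain onto one dominant column and the
mean-importance rule would discard genuinely informative features. The decision threshold maximises the F(0.75) score over
unique out-of-fold probabilities, ties to the lower threshold. Partner
prediction prefilters candidates: Closed conformation, E2 engagement of the
RING/U-box truncation span, and pTM/ipTM >= 0.5; E3s with exactly one
surviving predicted E2 are flagged as uniquely predicted.

## Synthetic fixtures: what they emulate and what they do not

`make_complex()` builds three-chain toys with idealized backbones: a real
76-residue ubiquitin sequence, a synthetic E2 (crossover helix 39-54, Cys25),
and a synthetic E3 with an E2-binding loop and an optional arginine whose
guanidinium nitrogens satisfy the double hydrogen-bond linchpin geometry. The
Ile44-helix and tail-cysteine distances are placed exactly (construction
re-measures and aborts beyond 0.1 A). Defaults encode the stated world:
closed targets 7.0/4.0 A (near the observed pair medians 6.86/4.18 A), open
15/20 A; feature-table class sizes 294/273 (the Closed pair/non-pair table);
linchpin rates 0.612/0.399 (the observed pair/non-pair proportions). Where the
sources state no value, realistic choices were fixed once: feature-family base
means and dispersions in `.FEATURE_PARAMS`, a standardized effect size of 0.8
as a "moderate" planted signal, noise multiplier 1.

These toys are not proteins: side chains are minimal, energetics tables are
Gaussian draws, and PAE matrices are block-structured. A green test therefore
establishes that the *measurement and learning machinery* is correct and
deterministic — not that any biological claim about real E2-E3 pairs is
reproduced. In particular, the classifier-recovery tests show parameter
recovery on planted signal, not the source's cross-validated AUC, which would
require the original AlphaFold-derived feature tables.

## Known limitations

* The experimental PDB conformation census needs deposited structures and a
  curated registry of real E2 annotations; both are external inputs
  (`conformation_census()` runs on any directory of files plus a registry,
  and the accession list ships in `inst/extdata`), so the corresponding
  acceptance check stays red in an offline build.
* Hydrogen bonds are distance-only; angle-dependent criteria, salt bridges
  and buried-surface-area terms are out of scope (energetics arrive from an
  external tool's TSV).
* Helix/strand detection is heuristic; heavily distorted or very short
  crossover helices should be curated in the registry.
* `seq_identity` counts identity over locally aligned columns and requires
  the alignment to cover at least half of the registry entry before a role is
  claimed — short coincidental matches cannot assign a role.
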