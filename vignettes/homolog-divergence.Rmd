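---
title: "Quantifying sequence and conformational divergence across protein homolog families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sequence and conformational divergence across protein homolog families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confdiv)
```

# The problem

Bacterial effector proteins such as the *Wolbachia* Wmk family — candidate
male-killing factors built from two cro/CI-type helix-turn-helix (HTH)
domains joined by an inter-domain linker (IDL) — diverge along two axes at
once. At the sequence level, a family typically contains a tight "type-I"
cluster (72–100% identity to a reference) plus highly divergent members
(~26–48% identity) that carry large deletions in the linker and short
insertions downstream of the C-terminal domain. At the structural level,
molecular-dynamics (MD) ensembles of each homolog reveal hinge-like
anti-correlated motion of the two domains, so that any two conformations —
even of the same protein — can differ substantially, and comparing homologs
requires separating conformational spread from genuine fold divergence.

`confdiv` implements this comparative analysis as a reusable pipeline:

* **sequence divergence** — global-alignment identity, group classification,
  Shannon-entropy conservation differentials, indel blocks, HTH motif and
  charge scans, domain arithmetic;
* **per-ensemble descriptors** — equilibration offset, frame sampling,
  RMSD/radius-of-gyration series, robust median/MAD summaries, pairwise
  Wilcoxon tests;
* **within-ensemble dynamics** — dynamic cross-correlation matrices (DCCM)
  and Cartesian PCA with principal-motion interpolation;
* **cross-homolog structure** — MSA-guided TM-scores, exhaustive pairwise
  conformation tables, iterative core-residue finding, joint PCA, outlier
  ranking and progressive outlier removal;
* **a seeded synthetic-family generator** that plants every quantity the
  pipeline is supposed to recover.

# Models and procedures

## Geometry

All analyses are C-alpha based. Rigid-body superposition uses the Kabsch
algorithm (SVD of the weighted cross-covariance with the reflection branch
corrected, so the rotation always has determinant +1); degenerate
(collinear) inputs raise an error rather than returning an arbitrary
rotation. `rmsd()` performs no superposition of its own, so best-fit RMSD is
the explicit composition `rmsd(apply_superposition(kabsch_superpose(...)))`.
The radius of gyration is the unweighted root-mean-square distance of
C-alpha atoms from their centroid, reported in nanometres. Because a
C-alpha-only Rg is not numerically comparable to all-atom, mass-weighted
values from MD packages, only *relative* Rg comparisons between homologs are
meaningful here; absolute parity with all-atom tools is not claimed.

## Ensemble summaries and tests

Trajectories are preprocessed by an equilibration offset (default 20 ns;
frames at exactly the boundary are kept) and, for cross-homolog comparison,
by sampling one frame per grid time (default 25–95 ns every 10 ns, eight
conformations; the nearest frame within half a step is accepted). Summaries
are median and **unscaled** median absolute deviation — no 1.4826
consistency factor, and the even-length median is the mean of the two
central order statistics. The Wilcoxon rank-sum test is exact (full
enumeration) when the pooled sample has at most 12 tie-free observations
and otherwise uses the normal approximation with tie and continuity
corrections; pairwise testing across homologs applies Holm adjustment by
default (configurable: none, Holm, Bonferroni, BH). Whether testing should
be one- or two-sided is not dictated by the scientific question here, so
two-sided is the default and an argument exposes the alternatives.

## DCCM and trajectory PCA

The DCCM uses the isotropic scalar-product estimator
`C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` over superposed frames;
residues with zero fluctuation are flagged and their correlations set to 0
rather than dividing by zero. Negative blocks between the two domains are
the signature of hinge-like anti-correlated motion;
`inter_set_correlation()` reduces a domain pair to the mean off-diagonal
correlation.

Cartesian PCA decomposes the 3N-dimensional covariance of superposed frame
coordinates (1/(F−1) normalisation) via SVD of the centred frame matrix.
Eigenvector signs are fixed so the largest-magnitude loading is positive —
an arbitrary but reproducible convention, which is why tests compare
|Spearman rho| between PC1 projections and planted hinge angles.
`pc_interpolate()` renders a component as structures `mean + t * sigma * PC`
for `t` in ±3 standard deviations (the range is a display choice).
By default frames are superposed on a user-chosen representative
conformation; fit-to-mean iteration (until the mean shifts < 1e-6 Å, at
most 20 rounds) is available and is what the higher-level stages use.

## MSA-guided TM-score

Cross-homolog conformation pairs are scored with the TM-score
`(1/L) * sum 1/(1+(d_i/d0)^2)`, `d0 = max(1.24 (L-15)^(1/3) - 1.8, 0.5)`,
with the residue correspondence taken from the MSA columns where neither
sequence is gapped and L the shorter chain by default. The correspondence is
*not* searched: scores are therefore not numerically interchangeable with
tools that optimise the alignment, and the analysis surface is orderings and
group contrasts, not absolute score parity. The superposition maximising the
score is found deterministically: fragment seeds (full run, central half,
central quarter; for ≤10 pairs every 3-pair subset, making the search
exhaustive at oracle scale), each followed by up to 20 rounds of iteratively
reweighted fitting with weights `1/(1+(d_i/d0)^2)^2` — the derivative of the
score term, so each re-fit is a majorize-minimize ascent step. The d0 floor
of 0.5 Å covers chains shorter than 22 residues where the formula is small
or undefined.

## Core-residue finding

Starting from all MSA columns shared across homologs with ensembles, the
finder repeatedly superposes every conformation onto the running mean,
measures each position's variance about the across-conformation mean, and
removes the most variable position; the removal trace is the "core residue
identification graph". Two numerical choices matter:

* **Anchoring.** A plain unweighted fit is a compromise dragged toward
  whichever rigid block holds more residues, which can trap the greedy
  removal in the wrong basin. The first fit is therefore anchored by a
  superposition-free rigidity ranking — the lower-quartile variance of each
  position's internal distances across conformations (a rigid-core position
  keeps fixed distances to at least a quarter of the structure, and the
  lower quartile makes the ranking insensitive to relative block sizes) —
  and every subsequent fit weights positions by the inverse of their
  previously measured variance.
* **Stopping.** The default cut is the knee of the trace: the largest second
  difference of the lightly median-smoothed `log10` max-variance curve.
  The log scale matters because the trace spans orders of magnitude between
  mobile positions and the noise floor; on the raw scale the second
  difference fires on early noise. A fixed `target_count` is available when
  the core size is known.

Joint PCA then superposes all conformations on the core and decomposes the
coordinates of every shared column; projections carry homolog and group
labels, feeding outlier ranking (centroid distance from the medoid homolog
in the first three PCs, with within-homolog spread as tie-break) and greedy
progressive removal (each step removes the homolog whose removal maximises
the median of the remaining between-homolog scores; ties break
lexicographically).

## Sequence divergence

Pairwise identity is computed from a BLOSUM62 global alignment (gap opening
11, extension 1) as identical columns over alignment columns; a pairwise
alignment has no double-gap columns, so the denominator is simply the
alignment length. Different alignment tools count identity slightly
differently, so parity with any particular tool's printed percentages is not
claimed — classification thresholds, not absolute values, are the contract.
Classification: identity to the reference ≥ 0.72 is type-I; otherwise best
identity to any seed distant homolog ≥ 0.35 is distant; otherwise
unassigned.

Conservation is `1 − H/log2(20)` per column with H the Shannon entropy of
non-gap residue frequencies (gaps excluded, not a 21st symbol); columns
with gap fraction > 0.5 are flagged. The conservation differential maps the
full-alignment and subset-alignment tracks onto the reference's ungapped
positions and reports their difference inside a window (default 10–268,
chosen to exclude alignment-end ambiguities).

Motif scans classify 3-mers against residue classes: small {G,A,S,C,T},
hydrophobic {A,V,L,I,M,F,W,Y,C}, polar {S,T,N,Q,H,K,R,D,E,Y,W}. Naturally
occurring HTH motifs violate strict class membership (an "shs" instance may
carry a glutamate in a small slot), so one violation is tolerated by
default and both the classes and the tolerance are arguments. The charge
profile is a sliding-window sum with K/R = +1, D/E = −1 and histidine 0 — a
deliberate sequence-level proxy for surface electrostatics, not a
structure-based calculation.

# What the synthetic generator emulates

`make_family()` builds a reference two-HTH architecture (20-residue N
extension, 55-residue domain A at 21–75, 62-residue linker, 55-residue
domain B at 138–192, 67-residue C extension; 259 residues in total) and
plants every ground truth the pipeline is tested against:

* **Identity bands.** Type-I homologs are gapless BLOSUM62-biased mutants
  with targets drawn in (0.72, 1.0); distant homologs target (0.26, 0.50)
  to the reference and ~0.44–0.50 to each other (the second distant member
  is derived from the first). Achieved identities are measured with
  `pairwise_identity()` and must land within 0.03 of target.
* **Indels.** Distant members delete 32–36 linker residues adjacent to
  domain B and insert 7–9 residues immediately downstream of it; the MSA is
  built by construction, so recovery of the planted blocks is exact or the
  test fails.
* **Conserved domains, divergent linkers.** The HTH domains and extensions
  keep the reference's block geometry in every homolog; type-I linkers have
  four helices, distant linkers two (rebuilt, shared among the distant
  members). Per-homolog static fold noise is 0.25 Å on the stable side and
  three times that beyond the hinge: structural heterogeneity in the
  emulated system concentrates around the C-terminal domain, which is what
  makes the N-side block the unique family-wide core.
* **Hinge motion.** Every homolog's ensemble rotates the chain beyond
  residue 100 about an axis through the hinge by
  `amplitude * sin(2*pi*t/period)` with per-homolog amplitudes of 15–30°, a
  400 ns period over the 0–100 ns trajectory (a slow opening, so every
  retained frame has a distinct true angle), and Gaussian jitter of 0.3 Å —
  tripled on the mobile side, the lever-arm elevation of fluctuation that a
  swinging domain shows in MD. Frame times run 0–100 ns every 5 ns so the
  20 ns offset and the 25–95/10 sampling grid both apply cleanly.

What the generator does **not** emulate: force-field physics, side chains,
correlated (non-Gaussian) loop motions, alignment uncertainty (the MSA is
exact by construction), and sequence–structure coupling (mutations do not
bend the backbone). Passing recovery tests therefore demonstrates that the
analysis code recovers planted signals through the full pipeline — not that
the pipeline is robust to misalignment or to force-field artefacts in real
MD data.

# Degenerate inputs and numerical conventions

Parsers reject malformed input loudly: multi-model PDB files are pre-scanned
so that a residue without a CA atom, or models with inconsistent residue
sets, fail with the offending residue named (the underlying coordinate
reader would otherwise recycle coordinates silently). Ensembles emptied by
an equilibration offset, sampling grids with no frame within tolerance,
collinear superposition inputs, zero-eigenvalue components in
`pc_interpolate()`, and overlapping domain annotations all raise errors.
Ties in PCA eigenvalues keep first-occurrence order; Wilcoxon groups with
fewer than two values are skipped with a warning; TM-score inputs with
fewer than three corresponded pairs are rejected.

# Problem sizes

The default validation family is 1 reference + 5 type-I + 2 distant
homologs with 21-frame ensembles, sampled to 8 conformations each for
cross-homolog work: 224 within-homolog and 1,792 between-homolog TM
comparisons, a ~220-step core-finding trace over ~224 shared columns, and a
56-conformation joint PCA. The Wilcoxon null calibration uses 1,000
two-sample draws of size 30+30. These sizes keep a full pipeline run in the
low minutes on a single CPU while leaving every statistic far from its
small-sample regime.

# Known limitations

* TM-scores use MSA-derived correspondences; against a structure-alignment
  search they are systematically conservative for divergent pairs.
* The core finder's greedy removal is path-dependent in principle; the
  rigidity-ranked initialisation removes the failure mode we could
  construct, but pathological families with several equally quiet rigid
  blocks may still yield an ambiguous core (inspect the trace plot).
* The charge profile and motif scans are sequence-level screens, not
  electrostatics or structure-based motif detection.
* Rg values are C-alpha-only and in nm; compare them between homologs, not
  against all-atom literature values.
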