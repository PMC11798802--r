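---
title: "Ensemble pharmacophore models with majority-vote feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble pharmacophore models with majority-vote feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ph4ensemble)
```

## The problem and the model

Proteins — GPCRs prominently among them — are conformational ensembles,
and ligands bind by conformational selection: they pick out pre-existing
conformations rather than inducing new ones. A pharmacophore model built
from a single crystal structure sees one conformation's interaction
pattern; a model built from a molecular-dynamics ensemble sees them all,
but drowns in hundreds of candidate features. This package implements a
workflow that turns that cloud of features into a small, screening-ready
model:

1. **Superpose** all frames onto the first on the heavy atoms of the
   binding-site residues (least-squares rigid fit; hydrogens never
   influence the fit).
2. **Perceive** pharmacophore features per frame inside the site region:
   hydrogen-bond donors (Don) and acceptors (Acc), cations (Cat), anions
   (Ani), aromatic/π-ring centers (Aro), and hydrophobic atoms and
   centroids (Hyd), as spheres of radius 1.2 Å (Don/Acc/Cat/Ani), 1.4 Å
   (Aro) and 1.6 Å (Hyd). Hydrophobic points within 1 Å merge
   transitively into one sphere capped at 3 Å; a donor and acceptor (or
   donor and cation) closer than 0.5 Å collapse to the combined classes
   Don|Acc and Don|Cat.
3. **Cluster** all per-frame features of one class into *consensus
   features* (greedy leader clustering, 1.5 Å default radius), each
   carrying the fraction of frames in which it occurs.
4. **Encode** the ensemble as a binary conformations × features
   occurrence matrix; by construction each column mean equals its
   consensus frequency. Optionally retain only features inside a
   frequency band (e.g. 1 %–25 %): features present in most frames are
   unlikely to distinguish the minority of binding-selected
   conformations.
5. **Rank** every column against a per-frame binary label (1 = frame
   preferentially selected by ligands in prior ensemble docking; the
   label is an input here) with four statistics — one-way ANOVA F,
   mutual information, recurrence-plot diagonal-line entropy, and
   absolute Spearman correlation — and retain features in all four
   top-*k* sets (voting score 4).
6. **Screen**: the selected features form a query; every conformer of
   every library molecule is matched by least-squares rigid
   superposition of its class-compatible annotation points onto the
   query centers, accepted only if every point lands inside its feature
   sphere, and each molecule keeps its minimum-RMSD conformer. Screening
   quality is the hit-ratio enrichment factor

   EF = (active hits / decoy hits) / (actives in library / decoys in library),

   which is 1 when hits mirror the library composition.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| site cutoff (proximity mode) | 6.5 | Å | conventional pocket radius around a reference ligand |
| feature radii | 1.2 / 1.4 / 1.6 | Å | polar / aromatic / hydrophobic sphere sizes |
| Hyd merge distance, cap | 1.0, 3.0 | Å | hydrophobic patches act as one feature |
| Don–Acc overlap tolerance | 0.5 | Å | collapses hydroxyl-type sites to Don\|Acc |
| `cluster_radius` | 1.5 | Å | consensus join distance; of the order of the feature radii and above the coordinate jitter between frames |
| band (`low`, `high`) | none; banded runs start at 1 % | fraction | drops near-ubiquitous features that cannot discriminate a 10 % minority |
| `k` | required | features | per-method cut before voting; the selected set is the intersection, so \|selected\| ≤ k |
| match `tolerance` | 0 | Å | extra slack beyond feature radii at acceptance |

## Numerical conventions and edge cases

* **ANOVA F** uses the textbook between/within decomposition. A column
  that separates the label groups perfectly has zero within-group
  variance; it is returned as `+Inf` and ranks above every finite value
  — perfect separators are exactly what the ranking seeks, so erroring
  would be wrong.
* **Mutual information** is the plug-in estimate from the empirical 2×2
  table, reported in bits so a balanced column identical to the label
  scores exactly 1; a normalized variant (divide by the smaller marginal
  entropy) is available as an option.
* **RQA entropy** treats each feature column as a time series in frame
  order (frame order is therefore authoritative throughout). Recurrence
  is exact match; maximal diagonal lines of length ≥ 2 from off-identity
  diagonals enter a length histogram whose Shannon entropy (nats) is the
  score. A line spanning its *entire* diagonal is border-censored into
  one shared "maximal" bin, since the plot cannot reveal its true
  length; the constant series thus collapses to a single bin and scores
  exactly 0 rather than an artifactual ln(n−2). No embedding or delay
  reconstruction is attempted — these are presence/absence series, not
  phase-space observables.
* **Spearman** on a constant column is undefined; it scores 0 with a
  `degenerate` attribute instead of aborting a whole sweep.
* **Ties** in every ranking break by ascending feature id, and feature
  ids are assigned deterministically (descending frequency, then class,
  then center), so the entire pipeline is bit-reproducible: the same
  config and inputs give byte-identical artifacts.
* **Matcher**: correspondences are enumerated with pairwise-distance
  pruning (|d_query − d_points| ≤ r_i + r_j + 2·tolerance) before the
  Kabsch fit, which makes the search exact but fast; reflections are
  rejected (rotation determinant +1), so chiral arrangements cannot
  match their mirror image. Combined classes (Don|Acc, Aro|PiR,
  Hyd|HydA) are satisfied by either member class, on both the query and
  the point side.
* **EF edge cases** are flags, never silent numbers: no decoy hits →
  `Inf` sentinel with `"no-decoy-hits"`; no active hits → 0; empty hit
  list → `NA`. A decoy-free screen cannot define the baseline ratio and
  reports the sentinel directly.

## Design choices where the design was open

* **Site definition.** Automatic pocket detection (alpha-shape style) is
  deliberately out of scope; the site arrives as a residue list or as
  proximity to reference coordinates. The downstream method is agnostic
  to how the site was found, and explicit definitions are reproducible.
* **Typing rules.** Protein feature perception is template-driven — an
  explicit, versioned residue/atom-name table covering the 20 standard
  amino acids (see `typing_rules()`), plus single-atom probe residues
  (DON, ACC, …) used by the synthetic generator. The table documents its
  own choices (e.g. histidine Nδ/Nε are typed both donor and acceptor
  and so emerge as Don|Acc) and does not claim equivalence to any
  proprietary perception scheme. Ligand perception is light bond-graph
  heuristics, with an explicit per-atom class tag (`FEATURE_CLASSES`)
  taking precedence when present. Protonation states are taken as given.
* **Consensus clustering** is greedy leader clustering per class in
  frame order (O(N·K), deterministic, ties to the first-founded
  cluster) rather than hierarchical clustering, which would be quadratic
  in the number of features across thousands of frames. Re-clustering
  the consensus centroids at the same radius is a fixed point. Frequency
  counts distinct frames, not member instances — this is what makes the
  binary encoding's column means equal the frequencies exactly. The
  consensus radius is the mean of its members' radii (members differ
  only when merged hydrophobics joined).
* **Voting cut.** How many features each method passes to the vote is a
  single top-*k* with *k* a required, sweepable parameter; nothing in
  the procedure fixes it intrinsically, and the sweep
  (`band_sweep()`) makes its effect visible.
* **Manual curation** is supported (`feature_ids` override in
  `build_query()` and the config): selection occasionally needs a human
  override, and the pipeline should reproduce such curated models.
* **Command line.** `run_all()`/`band_sweep()` are the package surface;
  a thin Rscript (`inst/scripts/ph4ensemble`) exposes `simulate`,
  `superpose`, `run-all`, `sweep`, `rank` and `search`. The remaining
  stages are exported functions whose artifacts `run-all` always
  materializes (aligned ensemble, per-frame feature JSON, occurrence
  CSV, votes CSV, query JSON, hit SDF/CSV, report JSON), so every stage
  is independently auditable without a dedicated shell verb.

## What the synthetic generator emulates — and what it does not

`make_ensemble()` builds a pocket of inert pseudo-atoms jittered
i.i.d. per frame (σ = 0.1 Å default), plants features whose occurrence
is label-conditional (defaults: 4 planted features at 90 % occupancy in
the 10 % binding-selected frames and 5 % elsewhere), and surrounds them
with nuisance features at frequencies from 2 % to 95 %. Feature on/off
is realized by displacing the probe atom far outside the proximity site
(multi-model PDB requires a constant atom count), and the exact
Bernoulli draws are recorded so downstream frequencies are checkable
bit-exactly. `make_library()` builds actives guaranteed (one conformer
within `active_jitter` of the query after a random rigid motion) and
drop-one decoys guaranteed impossible under all-features matching,
with ground-truth hit labels.

This validates the *machinery*: statistic correctness against
brute-force oracles, exact recovery of planted signal, exact
ground-truth hit sets, determinism. It does not validate transfer to
real systems: real pockets flex anisotropically rather than jitter
isotropically, real feature occurrences are temporally autocorrelated
within an MD trajectory rather than i.i.d. across frames, real decoys
are property-matched molecules rather than constructs missing exactly
one feature, and real binding labels are themselves noisy. Passing
tests therefore demonstrate that the pipeline computes what it claims,
not that a given protein's model will enrich a given screening
database.

## Problem sizes

The shipped validation runs use ensembles of 50–1,000 frames with ~30
site atoms and 10 features, and libraries of up to 50 actives / 500
decoys with 3–5 conformers per molecule; the planted-recovery property
is checked across 20 seeds at 200–1,000 frames. These sizes were chosen
so the whole suite documents the method's behavior in minutes while
remaining comfortably above the regime where the statistics degenerate
(a 10 % binding fraction needs a few hundred frames for stable group
statistics).

## Known limitations

* Protein typing covers the 20 standard residues and the synthetic
  probes; modified residues, cofactors, and waters are untyped unless
  added to the rule table.
* No directional (vector) donor/acceptor constraints and no
  excluded-volume features — point features only.
* No conformer generation: ligand libraries arrive multi-conformer.
* No docking or pose rescoring downstream of the pharmacophore filter.
* Trajectory formats that need a topology (XTC/DCD) must be converted
  to multi-model PDB upstream.
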