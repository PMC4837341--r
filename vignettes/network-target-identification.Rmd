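---
title: "Network analysis for drug target identification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network analysis for drug target identification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpminet)
```

## The problem and the model

Multi-component preparations — herbal formulas being the prototypical
case — act through many small molecules binding many proteins at once.
Network pharmacology (molecular docking plus literature text mining)
over-generates candidate targets; metabolomics reports biomarkers that sit
downstream of the true targets but identifies no target by itself. The
method implemented here integrates the two evidence streams and keeps a
candidate target only when it lies on a path from an active component to a
metabolite biomarker.

The shared data structure is a layered, undirected network
(`cpmi_network`) whose nodes carry role sets drawn from {component,
target, pathway_protein, metabolite} and whose edges are typed
(component–target, protein–protein, pathway–metabolite) and
provenance-tagged ({dock, text, curated}). The modelling assumptions are:

* **Docking cutoff.** The score of a protein's co-crystallized ligand is a
  per-protein positive control; a component is a plausible binder only if
  it *strictly* beats that score in the engine's favorable direction.
  Engines disagree on whether higher or lower is better, so an orientation
  must be declared per engine tag — there is no default.
* **Interaction confidence.** Protein–protein edges come with a combined
  confidence score; only edges strictly above the threshold (default 0.8,
  the conventional "high confidence" level for STRING exports) are
  trusted.
* **Pathway bridge.** A metabolite biomarker is connected to proteins via
  its enriched pathways (strictly p < 0.05): member proteins of a
  surviving pathway link directly to the metabolite, and are extended by
  their PPI neighbors (1 hop by default, matching the "add interactors"
  convention; the depth is a parameter).
* **Layered traversal.** Retention paths run component → target →
  proteins → metabolite. Components never appear as intermediate nodes;
  the protein stretch may only visit nodes holding the target or
  pathway_protein role. A target that is itself a pathway protein with a
  direct metabolite edge satisfies the condition with a length-1 path.
  Paths through *other* target-role proteins are allowed (both hold
  protein roles) and flagged in the evidence record (`path_via_target`).

Retention is a reachability question, not a path-enumeration question: on
realistic networks (hundreds of edges) the set of simple paths explodes,
while reachability is linear-time. One witness path per retained target is
still reported for explainability, computed by breadth-first search with
lexicographically ordered neighbor expansion, so results are fully
deterministic; the anchor protein found first at the shallowest depth is
used, and the lexicographically smallest adjacent metabolite terminates
the path. The property suite checks that reachability agrees exactly with
a brute-force simple-path oracle on hundreds of random small networks.

## Parameters that matter

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `orientation` | `apply_dock_cutoff()` | — (required) | per-engine score direction |
| `tolerance` | `apply_dock_cutoff()` | 0 | slack for coarse score grids; 0 keeps the strict reading |
| `min_conf` | `filter_ppi()` | 0.8 | strict PPI confidence threshold |
| `alpha` | `build_mppi()`, enrichment | 0.05 | strict pathway/term significance threshold |
| `neighbor_depth` | `build_mppi()` | 1 | PPI hops in the MPPI extension |
| `threshold` | `tanimoto_screen()` | 0.85 | *inclusive* similarity threshold |
| `fp_type` | `tanimoto_screen()` | `"ECFP4"` | circular fingerprint, radius 2 (Open Babel) |

All threshold comparisons follow the strict/inclusive readings stated
above; the filters are monotone in their thresholds (tightening never adds
nodes or edges), which the tests verify.

Degree stratification classifies targets by their number of distinct
interacting components: 1–9 low, 10–19 middle, ≥ 20 high. The upper
stratum is open-ended: the 20–41 range seen in the motivating study
reflects its observed maximum, not a cap.

## Statistical components

* **Over-representation.** Term enrichment uses the upper-tail
  hypergeometric probability with the background defaulting to all genes
  in the annotation table (configurable). Raw p < 0.05 flags "key" terms,
  mirroring common STRING-style practice; Benjamini–Hochberg adjustment is
  available behind an explicit flag and is labeled an extension.
* **Drug-likeness comparison.** Per descriptor, a two-sided two-sample
  Kolmogorov–Smirnov test (distribution shape) and a two-sided Wilcoxon
  rank-sum test (location). The rank-sum form is used because the two
  compound sets are independent samples; the paired signed-rank variant
  would be wrong. Exact p-values are computed for small tie-free samples
  and the standard asymptotic approximations otherwise (the defaults of
  R's `stats` implementations).
* **Chemical-space PCA.** Descriptors have incommensurate units, so
  columns are centered and scaled to unit variance by default (a
  `scale = FALSE` escape hatch exists because some chemometrics software
  defaults differ); zero-variance columns are centered but not scaled.
  Missing values are rejected with a row/column report — silent imputation
  would quietly distort the map. Loading signs are fixed by orienting each
  loading vector so its largest-magnitude entry is positive.
* **Descriptors.** Molecular weight, aromatic ring count, H-bond donors,
  H-bond acceptors (N+O definition), topological polar surface area,
  rotatable bonds, and log P, computed with Open Babel via
  ChemmineOB/ChemmineR. Octanol–water partition parameterizations differ
  across toolkits, so the `alogp` column is explicitly the Open Babel
  log P; descriptor tables computed elsewhere can be ingested as plain
  data frames wherever a descriptor table is accepted.

## The 1:1 binding fit

Equilibrium SPR responses are reduced with the steady-state Langmuir
isotherm R(C) = R~max~·C/(K~D~ + C), fitted by Levenberg–Marquardt least
squares to a relative parameter tolerance of 1e-8. Starting values come
from the Hanes–Woolf linearization C/R = C/R~max~ + K~D~/R~max~, which is
exact on clean data and robust across the 2-fold dilution designs typical
of SPR; when the linearization is inadmissible (non-positive slope or
intercept, e.g. under heavy noise) the fallback start is R~max,0~ = max
response and K~D,0~ = the concentration nearest half-max. Replicates are
fitted as individual points by default (`average = TRUE` pre-averages).
Degenerate inputs — fewer than three distinct concentrations, all-zero
responses — raise errors rather than returning boundary estimates. The
tests verify recovery of (K~D~, R~max~) to ≤ 1e-6 relative error on
noise-free data for true K~D~ across 1–1000 on the 6.25–400 two-fold
series (seven concentrations), and < 5% median relative error under 1%
multiplicative Gaussian noise.

Percentage inhibition of TNF-α-mediated cytotoxicity is the linear OD
normalization 100·(OD~actD+TNF+compound~ − OD~actD+TNF~)/(OD~actD~ −
OD~actD+TNF~); it is invariant under a common OD offset, is not clamped,
and refuses degenerate controls (equal denominator ODs).

## What the synthetic generator emulates — and what it does not

`generate_fixture()` produces a complete input bundle whose default sizes
mirror the motivating study: 48 components, 61 candidate targets of which
25 are genuinely connected, 44 pathway proteins, 13 metabolite biomarkers.
Ground truth is enforced *constructively*: every planted-connected target
receives both a component edge and a high-confidence backbone edge into a
member protein of a significant pathway; decoy targets receive only one of
the two, and their high-confidence wiring is restricted to other decoys so
no accidental path can arise, while sub-threshold "temptation" edges
toward the backbone exercise the confidence filter. An internal
reachability check re-verifies the planted truth before the bundle is
returned, and the generator is a pure function of its config (seed
included). Choices not fixed by the study were made once on plausibility
grounds: positive-control dock scores U(40, 60) with passing margins
U(1, 10) (a LibDock-like scale), extra dock/text hit rates 0.08/0.06,
backbone confidences U(0.85, 0.99), noise-edge density 0.03.

The generator emulates the *combinatorial* structure of the inputs, not
their biology: docking scores are not drawn from realistic per-family
score distributions, PPI topology is Erdős–Rényi-like rather than
scale-free, pathway memberships are near-uniform, and synthetic component
structures are drawn from a small pool of real, parseable molecules merely
to keep the cheminformatics paths exercised. Passing the planted-truth
suites therefore demonstrates that the *integration semantics* are
implemented correctly — it says nothing about how the method performs on
real docking or STRING data, where edge quality, identifier hygiene and
database versions dominate.

The packaged 48-component catalog carries no structures (the published
table lists name, formula and serial number only); descriptor functions
skip structure-less rows with a warning, and the network modules never
need structures.

## Numerical and design notes

* Node ids are opaque, case-sensitive strings; no gene-symbol
  normalization is attempted (a mapping table can be applied upstream).
* Networks are stored undirected; direction is imposed only at traversal
  time by the role layering. Edges deduplicate on (unordered endpoints,
  type), unioning provenance and keeping the maximum confidence.
* `union_networks()` is associative and commutative with the empty network
  as identity, so NATPI/CPMI assembly order is immaterial.
* PPI scores are auto-detected: any value > 1 switches the whole column to
  the 0–1000 reading and divides by 1000, with a message.
* Ties everywhere break lexicographically (retained-target order, witness
  BFS expansion, enrichment results at equal p), making all outputs
  byte-reproducible.
* The interval arithmetic of the strata (1–9, 10–19, ≥ 20) partitions all
  positive degrees; degree-0 targets are excluded with a warning rather
  than silently dropped.
* Two reported counts in the motivating study disagree (25 connected
  targets in one place, 26 in another); the package does not adjudicate —
  the generator's default plants 25, matching the figure the network
  composition is reported with.

## Problem sizes used by the test suite

The suites run at sizes chosen to make the oracles airtight yet cheap: the
brute-force path-enumeration comparison uses 200 random networks of at
most 40 nodes; hypergeometric agreement is checked exhaustively for all
backgrounds N ≤ 12; KS/rank-sum enumeration covers samples of at most 6;
planted-truth recovery runs 50 seeds at the full study-scale
configuration; the noisy-fit property uses 200 replicates. The whole
suite finishes in well under two minutes on one core.

## Known limitations

* No edge-weight propagation, random-walk or diffusion scoring: the
  retention criterion is plain connectivity, as the method defines it.
* No GO DAG propagation or ontology fetching; annotation tables are taken
  as given, so enriched-term lists depend entirely on the supplied
  annotation universe.
* Kinetic (k~on~/k~off~) fitting of full sensorgrams is out of scope; only
  the steady-state K~D~ is estimated, and no confidence interval method is
  prescribed for it (the residual SSE is reported).
* Text mining itself, docking execution, and live database access
  (STRING, MetaboAnalyst, TTD, DrugBank) are deliberately outside the
  package: curated tables are the interface.
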