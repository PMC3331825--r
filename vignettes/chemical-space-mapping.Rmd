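---
title: "Mapping small-molecule datasets into 3D chemical space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping small-molecule datasets into 3D chemical space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chesmapr)
```

## The problem

Structure–activity analysis lives on the interplay between what a compound
*is* (its structure and derived features) and what it *does* (a measured
endpoint such as permeability or vapor pressure). chesmapr turns a
small-molecule dataset into an explorable 3D arrangement: compounds with
similar feature values end up close together, clusters of similar compounds
are detected and can be superimposed on a shared substructure, and the
resulting scene — positions, cluster labels, highlight colors — is exported
as JSON and as an annotated SD-file for any downstream viewer. Similarity
is *user-defined*: whichever feature columns are selected (measured
properties, computed descriptors, structural fragments) drive both the
clustering and the embedding.

The pipeline has six stages, each independently usable:

1. **Load** — SD-files (V2000, property tags become feature columns),
   SMILES lists, CSV tables keyed to compounds.
2. **Structures** — a pluggable coordinate provider fills in 3D
   coordinates when the input has none.
3. **Features** — dataset columns, built-in descriptors, mined linear
   fragments, and user SMARTS files.
4. **Cluster** — cascade k-means with Calinski–Harabasz selection (plus
   k-means, hierarchical, farthest-first, or none).
5. **Embed** — PCA, Sammon mapping, SMACOF, or random placement into 3D.
6. **Align** — per-cluster maximum common subgraph (or largest shared
   fragment) with Kabsch superposition.

## Feature extraction

### Feature typing

Features are **numeric** or **nominal**. Raw values are typed
automatically: numeric iff everything parses as a real number and the
distinct values are not all in {0, 1}; any parse failure makes the column
nominal; an all-{0, 1} column is *ambiguous* and defaults to nominal (the
user can override, since a 0/1 column may equally be a count or a flag).
Empty strings and `"NA"` are missing markers and are never silently turned
into zeros.

### Linear fragments

The structural-feature engine enumerates **linear fragments**: simple
paths (no repeated atoms) of 1–`max_atoms` atoms in the molecular graph,
atoms labelled by element + aromaticity, bonds by order/aromaticity. The
default `max_atoms = 7` matches the classic linear-fingerprint
convention. Each path is canonicalised as the lexicographically smaller of
its two directional string encodings, so a path and its reverse count
once. Ring-closure fragments are deliberately out of scope — "linear"
means paths, and rings contribute their linear sub-paths.

Each fragment becomes a binary nominal feature: 1 if the compound
contains the fragment, 0 otherwise. Incidence is compound-level (how
*often* a fragment occurs in one molecule does not matter). Two filters
shape the final feature set: `min_frequency` (default 2) drops rare
fragments, and `skip_omnipresent` (default on) drops fragments present in
every compound, which carry no contrast. Both defaults mirror the typical
use on structurally homogeneous series, where the shared scaffold is
omnipresent and only the substitution pattern is informative.

The SMARTS emitted for mined fragments writes aromatic atoms lowercase
with `:` bonds and aliphatic single bonds explicitly as `-`, so any
standard matcher reads them unambiguously. The built-in matcher is a
backtracking subgraph matcher over a practical SMARTS subset: element
symbols, `[#n]`, `*`/`a`/`A`, bond primitives `- = # : ~` and the
single-or-aromatic default, branches and ring closures. Charges and
H-counts inside brackets are parsed but ignored for matching — fragment
features operate at element + aromaticity granularity. Recursive SMARTS
and logical operators are rejected with an error naming the pattern. The
test suite cross-checks this matcher against Open Babel on a probe set
and against an exhaustive path oracle on random molecules.

### Descriptors

Built-ins are the simple, unambiguous counts: molecular weight (standard
atomic masses, implicit hydrogens completed from standard valences),
heavy atoms, rings (cycle rank, equal to the SSSR cardinality), rotatable
bonds (single, non-ring, non-aromatic bonds whose both atoms have at
least two heavy neighbours) and halogens. Anything requiring a
parameterised model (LogP, van der Waals volume, ...) is delegate-only:
`register_descriptor_provider()` plugs in an external calculator, and a
per-molecule failure produces a missing value plus a warning rather than
an abort. No in-house approximations of sophisticated chemistry are
provided, deliberately.

## Preprocessing and clustering

Selected columns are assembled into a numeric matrix. Numeric features
are median-imputed and z-scored with the *population* standard
deviation; zero-variance columns are dropped with a warning. Nominal
features are mode-imputed and one-hot encoded; the 0/1 dummy block is
then multiplied by \(1/\sqrt{\sum_l \mathrm{Var}(d_l)}\) so each original
feature contributes total variance 1 — comparable to one z-scored
numeric column — while the dummies remain proportional to a 0/1
indicator. All centring/scaling is recorded in the returned object.
Distances are Euclidean throughout the package, for coherence between
clustering and embedding.

**Cascade k-means** runs restarted Lloyd k-means for each k in
`[k_min, k_max]` and scores each partition with the Calinski–Harabasz
criterion

\[ CH(k) = \frac{B/(k-1)}{W/(n-k)} \]

with \(B\) the between-cluster and \(W\) the within-cluster sum of
squares. The k with maximal score wins; ties break toward smaller k; all
scores are reported so weak structure stays visible. CH is undefined at
k = 1, so the cascade starts at 2 — when no features are selected,
clustering is switched off entirely rather than forced. A perfect
partition with \(W = 0\) returns `Inf` as an explicit sentinel. The
k-means core is plain Lloyd iteration, best-of-`restarts` by
within-cluster sum of squares, deterministic given its seed; an empty
cluster is re-seeded at the point farthest from its assigned centroid.
The default range `2..min(10, ceil(n/2), n-1)` with 10 restarts is the
package's own choice — wide enough to bracket small-dataset structure,
cheap enough to run interactively.

Hierarchical clustering delegates to `stats::hclust` (single, complete,
average, Ward linkage) and cuts the tree at k; farthest-first traversal
seeds on a random point and greedily picks the point farthest from the
chosen centres.

## 3D embedding

* **PCA** projects the centred matrix onto its top three principal
  components. When the data's intrinsic dimension is at most 3, pairwise
  distances are preserved exactly; per-component variance fractions are
  reported.
* **Sammon mapping** minimises
  \(E = \frac{1}{\sum_{i<j} d^*_{ij}} \sum_{i<j} (d^*_{ij} - d_{ij})^2 / d^*_{ij}\)
  by the classic step-halving descent (via `MASS::sammon`), started from
  the PCA solution. The stress is undefined at zero input distance, so
  exact duplicate points are jittered by ~1e-6 (seeded). The descent
  does not expose an iteration count, so `iterations_run` is `NA` for
  this method.
* **SMACOF** minimises the raw stress
  \(\sigma(Y) = \sum_{i<j} (D_{ij} - d_{ij}(Y))^2\) (unit weights) by
  iterated Guttman transforms from a classical-scaling start.
  Majorization guarantees a monotone non-increasing stress sequence;
  the implementation *asserts* this at every iteration and records the
  full trace. Iteration stops at `max_iter` or when the relative
  improvement drops below `tol` (default 1e-6).
* **Random** placement in the unit cube is the fallback when no features
  exist.

Embedders return raw coordinates. The scene then centres them at the
origin and scales the bounding-box diagonal to 1; the viewer-side
"space size" control becomes a single `space_scale` multiplier applied
at export. This split keeps the embedders exactly faithful to their
objective (the tests rely on distance preservation) while giving the
scene a normalised canvas.

## Alignment

For each cluster the aligner needs one substructure that matches every
member. Two sources exist:

* **MCS**: all connected common subgraphs of the first molecule pair are
  enumerated by backtracking (atoms compared on element + aromaticity,
  bonds on order/aromaticity), then the candidate list is checked
  against each remaining member from the largest candidate down; the
  first candidate contained in all members wins. Every visited common
  subgraph is kept as a candidate, not only maximal ones — the largest
  subgraph shared by the *whole* cluster may be non-maximal for the
  first pair. Connectedness is required because a disconnected
  "substructure" cannot fix an orientation. The search carries a
  node-expansion budget (default 2e5); on overflow a warning is raised
  and the aligner degrades to the largest shared mined fragment, if
  available, else to no alignment.
* **MSF**: the largest mined/loaded fragment whose incidence is 1 for
  every cluster member (ties: lexicographically smallest SMARTS). It
  requires structural features and is much cheaper than MCS.

Substructures of fewer than 3 atoms cannot determine a rotation, so
`min_atoms = 3` by default; below it, no alignment is performed (1–2
matched atoms degrade to a translation-only fit with a warning).

Superposition is least-squares (Kabsch): SVD of the covariance of the
matched coordinates, with the determinant correction that forbids
reflections (`det(R) = +1` always). When a substructure embeds multiple
ways into either molecule (ring symmetry), the embedding pair with the
smallest RMSD is chosen — the original's behaviour is unstated, and
minimising is the deterministic choice that never worsens the fit. The
first cluster member in dataset order is the fixed reference. The
transform applies to all atoms; the reported RMSD is over matched atoms.

## The scene

`superimpose()` moves every compound to its cluster centroid (and
toggles back exactly). Numeric highlights use a two-segment linear
blue–white–red gradient (minimum → blue, midpoint → white, maximum →
red); missing values map to neutral gray, constant columns to white.
Nominal highlights draw from a fixed 12-color qualitative palette in
first-occurrence order, cycling with a warning beyond 12 values. Cluster
representatives for the superimposed view follow the maximum / median /
minimum of a selected feature (lower median on even counts, a documented
tie rule), with the member ordering attached. Histograms use equal-width
bins over the observed range, left-closed with the rightmost bin closed,
so counts conserve the number of non-missing values. `scene_remove()` is
a view-level filter — the dataset object is never modified, and export
honours the filter. Scene JSON round-trips byte-identically
(serialize → parse → serialize).

## Synthetic data

The fixture generators define the test conditions:

* `generate_scaffold_series()` builds structurally homogeneous series by
  string-level SMILES surgery: substituents drawn per attachment point
  (seeded) become branches on a fixed scaffold. The default series —
  diphenyl ether, biphenyl and benzophenone scaffolds decorated with
  Br/Cl at ring positions, 10 molecules each — emulates a halogenated
  congeneric series such as polybrominated diphenyl ethers, where the
  informative fragments all involve the halogen/ether substitution
  pattern. The generators do **not** produce realistic conformers: the
  built-in "topological" coordinate provider lays molecules out by
  classical scaling of graph distances at 1.5 Å per bond. That geometry
  is deterministic and consistent across copies of a scaffold, which is
  what alignment-recovery tests need, but it is not a force-field
  structure — conclusions about real conformers do not follow from it,
  and a real force-field provider can be registered through the same
  interface.
* `generate_gaussian_features()` places cluster centres at pairwise
  distance ≥ `separation` (rejection sampling in a cube) and draws
  isotropic Gaussian points around them. The recovery suite uses σ = 0.1
  and separation 10 — blobs two orders of magnitude tighter than their
  spacing — with 15 points per cluster in 4 dimensions; under these
  conditions cascade k-means is expected to find the generative k
  essentially always, and the suite requires ≥ 95/100 seeded successes
  for 2–4 clusters.
* `generate_planted_endpoint()` produces `y = Xw + noise`: an endpoint
  linearly driven by the features but never handed to the embedding.
  The end-to-end check verifies that such an endpoint varies smoothly
  over the 3D arrangement — the mean endpoint gap between 3D
  nearest-neighbour pairs is significantly smaller than between random
  pairs across 20 seeded runs (n = 24 compounds per run, mined fragment
  features, PCA embedding). What passing shows is that the pipeline
  transports feature similarity into spatial proximity; it does not show
  that any *real* endpoint correlates with any particular feature set.

## Numerical choices and degenerate inputs

* Euclidean distances everywhere; z-scoring uses the population standard
  deviation (the closed-form used by the tests).
* k-means convergence: centroid shift < 1e-9 (squared 1e-18) or
  no relative WSS change below 1e-12; the WSS is asserted non-increasing
  across Lloyd iterations except immediately after an empty-cluster
  re-seed.
* SMACOF stops on relative improvement < `tol`; an increase of the
  stress sequence beyond rounding error is treated as an internal error,
  not a warning.
* Aromaticity: aromatic flags in the input notation are trusted and
  frozen. Kekulized SD-file input is perceived once at parse time with a
  deliberately simple model — rings of size 5–6 over C/N/O/S with
  alternating single/double bonds (or explicit order-4 bonds) become
  aromatic. This covers benzenoid and pyridine-like systems; exotic
  aromaticity is out of scope and documented as such.
* Compound ids: SD title line, else a `_Name`-like tag, else the 1-based
  record index; duplicate ids are suffixed (`x`, `x_1`, ...) with a
  warning rather than guessing intent.
* Histogram bin edges: the left-closed convention with a closed right
  end was chosen over the right-closed alternative; with values
  {0, 0.5, 1} and two bins the counts are (1, 2).
* Atom indices and cluster labels are 1-based throughout, following the
  language's convention; the SDF bond block is written 1-based as the
  V2000 format requires.

## Problem sizes

The shipped tests and the acceptance script run on deliberately small
instances chosen to finish interactively while still separating correct
from incorrect behaviour: random molecules of ≤ 12 atoms for oracle
equivalence (50 for the acceptance run), 100 seeded cascade recoveries
per cluster count, 24–30 compound scaffold series for the end-to-end
checks, and 20 seeds for the neighbourhood-consistency measure. All
sizes are parameters of the fixture generators and scale up directly.

## Known limitations

* The SMARTS subset excludes recursive patterns, logical operators and
  ring-membership primitives; structural-alert files using those need an
  external matcher plugged in behind the same interface.
* MCS search is exponential in the worst case; the budget guard keeps it
  bounded but can return a suboptimal substructure on large, highly
  symmetric molecules (a warning is emitted).
* The topological coordinate provider gives toy geometry, not
  conformers.
* t-SNE embedding and model-based/conceptual clustering (EM, Cobweb,
  dynamic tree cuts) are extension points, not implementations.
* Formal charges are parsed from SMILES but not round-tripped through
  SD-files.
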