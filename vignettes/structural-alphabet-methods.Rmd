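---
title: "Density-based structural alphabets: models, parameters and design choices"
author: "safrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-based structural alphabets: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safrag)
```

## The fragment model

safrag describes local protein backbone structure through four-residue
C-alpha fragments.  A fragment of four atoms has `3*4 - 6 - 3 = 3` internal
degrees of freedom once rigid-body motion and the three (almost constant)
virtual C-alpha--C-alpha bonds are removed, and those three degrees of
freedom are exactly the two pseudo-bond angles `phi1` (atoms 1-2-3) and
`phi2` (atoms 2-3-4) and the pseudo-torsion `theta` (atoms 1-2-3-4).  Every
local conformation is a point in this three-dimensional angle space; the
conformations that proteins actually adopt concentrate at a modest number of
high-density attractors (helical, extended, loop and turn geometries).  A
Structural Alphabet is a lettered set of representative fragments placed at
those attractors, which turns a backbone of N residues into a string of
N-3 letters and, conversely, lets a backbone be rebuilt from its string.

Two conventions pin the geometry down:

* **Torsion sign.** `theta` follows the right-hand (IUPAC) dihedral
  convention via the atan2 formulation, with cis = 0 and the value
  normalised to `(-180, 180]` (exactly -180 maps to +180).  Round trips
  through `build_fragment()`/`fragment_angles()` agree with this convention
  to well below 1e-6 degrees over the whole angle space.
* **Virtual bond.** Canonical fragment coordinates are materialised at a
  uniform 3.8 Angstrom bond, the trans-peptide C-alpha spacing.  Alphabets
  store angles only, so a bond convention is required to obtain coordinates;
  it is configurable per alphabet, and cRMSD-based results shift by a few
  hundredths of an Angstrom if representatives with native spacings are
  used instead.

Distances are measured two ways: in angle space as the aRMSD
`sqrt((dphi1^2 + dphi2^2 + dtheta^2)/3)` with the theta difference taken on
its period (so it never exceeds 180), and in coordinate space as the cRMSD
after optimal proper superposition (closed-form Kabsch/singular-value
solution; reflections are explicitly excluded).  Angles are deliberately
not normalised or standardised: the variance ratio between the torsion and
the planar angles carries the secondary-structure signal.

## Deriving alphabets from density

`derive_alphabet()` composes four steps.

1. **Grid prefilter** (`grid_prefilter()`): a cubic 2-degree grid over the
   angle space (theta binned on its periodic range); cells holding fewer
   than 10 points are discarded.  This removes sparse, uninformative
   regions before the quadratic-cost ordering.  Note that a cluster sitting
   on a cell corner loses a larger fraction of its tail than one centred in
   a cell; the filter bounds work, it does not guarantee a fixed recovery
   rate.
2. **OPTICS ordering** (`optics_order()`): a nearest-neighbour walk that
   records, per point, the core distance (radius of the smallest
   neighbourhood containing `min_pts` points, the point itself included —
   the self-inclusion convention is stated because the literature varies)
   and the reachability distance from the walk.  The neighbourhood radius
   defaults to 200 degrees; since no aRMSD in this space approaches that
   value, every point is reachable, nothing is labelled noise, and the
   parameter is inert.  The walk starts at the first point of the input
   rather than a random one, making derivations deterministic; the letter
   *order* of a derived alphabet depends on this choice, its content does
   not (up to exact ties, which break by lowest index).
3. **Drop-Down extraction** (`dropdown_extract()`): the reachability
   profile is carved by a density threshold descending through the sorted
   reachability values.  A candidate cluster is a maximal run of ordered
   points below the threshold, enclosed by two threshold-exceeding
   positions more than `min_pts` apart, and is accepted if it is at least
   `min_pts` smaller than its parent; the whole profile is scanned first,
   then accepted clusters are processed breadth-first.  Extraction order
   therefore runs from the most to the least populated attractor.
4. **Representatives and redundancy** (`select_representatives()`,
   `redundancy_filter()`): each cluster is represented by its
   lowest-core-distance member (ties to the earliest walk position), and a
   greedy keep-first pass in extraction order removes representatives
   whose canonical-coordinate cRMSD to an already accepted one falls below
   0.307 Angstrom.  That constant is the one-sigma log-space quantile
   `exp(meanlog + sdlog)` of a log-normal fitted to the sub-1.0-Angstrom
   (intra-cluster) peak of pairwise fragment distances, below which about
   84% of intra-cluster pairs fall; `fit_redundancy_cutoff()` reproduces
   the fit (maximum likelihood via MASS) on any distance sample, while the
   filter default stays at the published constant.

Surviving representatives are lettered `A, B, C, ...` by reachability-walk
position and the alphabet is named `M<min_pts>K<size>`.  `min_pts` is the
single tuning parameter of the whole derivation: raising it coarsens the
density estimate and never increases the number of extracted leaf clusters.

The bundled `m32k25()` alphabet (25 letters, derived at `min_pts = 32` from
a large high-quality domain corpus) ships as package data at 0.1-degree
precision.  Letters A-I cover extended conformations, J-R loops, S-X
helical geometries, Y turns; `annotate_letters()` exposes that coarse map
for reporting only — letters are conformational states, not
secondary-structure assignments, and several letters deliberately fit both
structured and unstructured environments.

## Encoding and reconstruction

**Local fit** (`encode_local()`): every window of the template is overlaid
independently with each letter's canonical fragment and takes the letter of
minimal cRMSD; the per-position error is that cRMSD and the protein-level
local fit pools the squared errors over all overlapping windows
(`sqrt(mean(error^2))`).  Per-window argmin ties break to the earlier
letter.  Windows spanning a chain break (consecutive C-alpha distance
outside 2--6 Angstrom; configurable, or disabled with
`break_range = NULL`) carry the gap character `-`.

**Global fit** (`reconstruct_global()`): the backbone is rebuilt as a
seamless head-to-tail chain of fragments.  Appending letter `l` to a
partial chain adds exactly one atom, placed from internal coordinates: the
virtual bond plus `l`'s `phi2` and `theta` relative to the chain's last
three atoms.  This is the natural generative reading of fragment overlap —
three shared atoms leave one new atom and two free angles per step, while
the new window's `phi1` is inherited from the previous letter's `phi2`.
The same rule drives the synthetic generator, which makes noise-free
generated chains exactly reconstructable and gives the search a
well-defined optimum.  (The alternative rule — least-squares overlay of a
letter's first three canonical atoms onto the chain end — spreads the
`phi1` mismatch over the window instead; it is not used because generator
and reconstructor would then disagree about what "exact" means.)

The search over letter sequences is a bounded beam: all letters seed the
first window, each partial chain is re-scored after every extension by the
cRMSD of its optimally superposed prefix against the template prefix, and
the best `heap` partials survive.  `heap = 2000` makes the search
effectively exhaustive on typical chains; the examples and tests in this
package use widths between 4 and 64, which on chains up to ~60 residues
changes global cRMSDs by far less than the coordinate noise they carry.
Prefix scores are maintained incrementally (running sums plus a
closed-form symmetric 3x3 eigenvalue solution for the rotation part),
which keeps each extension O(1); the closed form ranks candidates at about
1e-8 accuracy, so all error values that are reported — per-position errors
and final cRMSDs — are re-evaluated through the exact SVD route.

Two error measures coexist for a reconstruction and they answer different
questions.  The *global fit cRMSD* is the whole-chain cRMSD between the
rebuilt and the template backbone — the headline reconstruction quality,
and the quantity summarised (median and interquartile distance) by
`rank_alphabets()`.  The *global encoding error* stored per position is
the fit cRMSD of the assembly-assigned letter on each template window, the
same functional the local encoder minimises.  On that shared functional
the inequality local <= global holds for every input by construction,
because the global assignment is a constrained choice of the same
per-window fit; no such inequality holds against the whole-chain cRMSD
(a whole-chain superposition can absorb noise that 4-point window fits
cannot, and on noise-free generated chains the whole-chain error is zero
while the local one is not).

A caveat that follows directly from the overlap geometry: a letter string
is *not* in general recoverable by local encoding of its generated chain.
Each window realises its letter's `(phi2, theta)` exactly but inherits
`phi1`, so the window geometry differs from the letter's canonical
fragment, and the per-window argmin frequently prefers a neighbouring
letter (measured at roughly 40% of letter pairs of the bundled alphabet).
The *global* encoder does recover generating strings exactly — the
`(phi2, theta)` pairs of the bundled letters are mutually distinct, so the
generating path is the unique zero-error assembly.

**Model selection.** `aic_score()` implements the Gaussian-residual Akaike
Information Criterion `2k + n log(RSS/n)` (base 2 by default, reported
/1000 as kbit) on pooled per-fragment local-fit residuals, with the
alphabet size as the parameter count: enlarging an alphabet keeps
improving the residuals until new letters stop paying for their own
complexity.  `ga_optimize()` provides an extraction-bias check: a genetic
algorithm (binary inclusion genomes repaired to a fixed popcount, elitism
plus uniform crossover among the fittest 5%) selects a fixed-size subset
of a candidate pool by mean local fit on a fitness corpus.

## Dynamics validation

`gnm()` builds the isotropic elastic-network (Gaussian Network) model on
C-alpha nodes: Kirchhoff matrix with -1 off-diagonals for pairs within the
7 Angstrom contact cutoff, pseudo-inverse by eigendecomposition with the
single zero mode removed (eigenvalues below 1e-10 of the largest are
treated as zero; more than one such mode means a disconnected contact
graph and is an error that names the component sizes).  The spring
constant and temperature prefactor is set to 1, so fluctuation magnitudes
are in arbitrary units; every downstream quantity — the Pearson
correlation of RMSF profiles and the overlap of cross-correlation
matrices in `flexibility_fidelity()` — is scale-free, which is why the
choice is harmless.  Cross-correlations are normalised to unit diagonal
before comparison by default (the raw covariance option is retained, as
the normalisation choice in the literature is not always recoverable).
The overlap measure `1 - tr((A-B)'(A-B)) / (tr(A'A) + tr(B'B))` is adopted
as the Frobenius-difference form satisfying the defining properties of a
matrix overlap: 1 exactly for identical matrices, 0 for orthogonal ones,
symmetric, bounded above by 1.  RMSF (the square root of the mean-square
fluctuation) is correlated rather than the mean-square itself; with
GNM-scale differences between native and rebuilt structures the two
choices give nearly identical correlations.

For conformational ensembles, `ensemble_profile()` couples two per-window
tracks over the N-3 sliding windows: the geometric flexibility
(`fragment_rmsf_profile()`: each frame's window superposed onto the
reference frame's window to remove roto-translation, per-atom RMSF about
the mean, quadratic mean over the four atoms) and the encoding variability
(`entropy_profile()`: Shannon entropy in bits of the letter distribution
across frames, bounded by `log2 k`).  A robust alphabet spends letters
only where the backbone genuinely moves, so the Pearson correlation
between the tracks is the headline robustness statistic; it is reported
undefined (with a warning) when either track has zero variance.  Local-fit
encodings correlate at least as strongly as global-fit ones on graded
synthetic ensembles in the large majority of seeds, because seamless
assembly introduces letter changes unrelated to real flexibility.

## What the synthetic generator does and does not emulate

The package is exercised entirely on synthetic data built by three
generators, in place of curated domain corpora and constraint-based
ensemble generation, which require external downloads and software:

* `chain_from_letters()` grows exact, noise-free backbones from letter
  strings (the generative form of the assembly rule above).
* `make_ensemble()` perturbs such a chain: isotropic Cartesian noise
  (slightly breaking virtual bonds, like coordinate error), internal-angle
  noise (bond-preserving), or graded Cartesian noise interpolating the
  per-atom standard deviation linearly along the chain to create a known
  flexibility gradient.  Frame 1 is always the noise-free reference.
  Ensemble tests use 150--200 frames of a 13-residue chain with graded
  noise from 0.05 to 0.5 Angstrom — amplitudes chosen to match the scale
  of coordinate uncertainty and loop mobility in real structures.
* `make_angle_cloud()` samples labelled wrapped/reflected Gaussians around
  given centres in angle space (theta wraps on its period; phi reflects at
  the (0, 180] boundaries rather than clipping, to avoid boundary density
  spikes).  Cluster-recovery tests use three centres at least 40 degrees
  apart (sigma 1 degree, 200 points each), and a corpus-scaled
  self-consistency test samples 300 points at sigma 1.5 degrees around
  each of the 25 bundled letters (7500 points, `min_pts = 32`) and
  requires at least 22 of the 25 attractors back within 3 degrees — a
  deliberate scale-down of a corpus-level derivation by a factor of
  roughly twenty.

Passing these tests shows that the pipeline recovers known density
structure, that encoders invert the generator, and that entropy tracks
imposed flexibility.  It does not show corpus-level performance on real
proteins: real fragment clouds have strongly unequal cluster populations,
anisotropic and heavy-tailed attractors, and correlated noise along the
chain, none of which the isotropic generators produce.  Quantities that
depend on those properties (absolute fit medians, AIC values of real
corpora) are therefore outside what the test suite certifies.

## Numerical choices and degenerate inputs

* Collinear atom triples make the torsion undefined: rejected when the
  cross-product norm falls below 1e-10 of the squared coordinate scale;
  coincident points are rejected at 1e-8 of scale.
* Superposition warns when a point set is nearly collinear (second
  singular value below 1e-8 of the first): the optimal rotation is then
  ill-determined although the cRMSD itself remains well-defined.
* `phi = 0` is excluded by mapping to the smallest positive double;
  `theta = -180` maps to +180.
* Exact ties — in beam scoring, letter argmins, reachability sorting and
  core-distance minima — always break deterministically (letter order,
  then parent rank; lowest index elsewhere), so every pipeline is
  reproducible bit-for-bit given its inputs and seed.
* The stochastic accuracy statement for cluster representatives (within
  0.5 degrees of a true centre at sigma 1, n 200) sits at the noise level
  of the densest-point estimator; tests therefore evaluate it over a fixed
  seed sequence and require a majority, while structural statements
  (exactly three letters; distinct letters per centre) must hold in every
  run.

## Known limitations

* The per-window local encoder is lossy on assembled chains by
  construction (inherited `phi1`); only the global encoder inverts the
  generator.
* OPTICS is the exact quadratic algorithm; clouds beyond ~1e4 points are
  slow in pure R.  The published corpus-scale derivation (>1e5 fragments)
  is out of scope here.
* Reproducing published corpus statistics (fit medians over hundreds of
  domains, AIC rankings of alphabet families, ensemble entropy tables)
  requires the external structure corpora and ensemble generators those
  numbers were computed on; the package implements the measures, not the
  corpora.
* GNM fluctuations are relative; no attempt is made to calibrate them
  against experimental B-factors.
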