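---
title: "Feature-similarity gradients and the Vogt-Bailey index: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-similarity gradients and the Vogt-Bailey index: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vogtbailey)
```

## The model

Every discrete point of an imaged structure — a cortical surface vertex, or
a pixel — carries a feature vector: an fMRI time series, a tractography
profile, the HSV colour of a pixel.  The package represents the pairwise
similarity of these feature vectors as a weighted, undirected graph with a
symmetric, non-negative affinity matrix $W$ (zero diagonal: self-similarity
is always maximal and carries no information).  With degree matrix
$D = \mathrm{diag}(W\mathbf{1})$ and Laplacian $L = D - W$, the embedding
that places strongly similar nodes close together minimises

$$U(x) = \sum_{i<j} W_{ij}\,(x_i - x_j)^2 = x^\top L x$$

subject to a normalisation constraint.  Under $x^\top x = 1$ this is the
standard eigenvalue problem $Lx = \lambda x$; under the degree-weighted
constraint $x^\top D x = 1$, which compensates the tendency of high-degree
nodes to dominate the embedding, it is the generalized problem
$Lx = \lambda D x$.  The generalized problem is the package default
everywhere.  The symmetric normalized Laplacian $D^{-1/2} L D^{-1/2}$ and
the random-walk form $D^{-1} L$ are available as alternatives; the
random-walk and generalized spectra coincide.

Because $L$ is positive semi-definite with $L\mathbf{1} = 0$, the smallest
eigenvalue is always $0$ with a constant eigenvector.  The useful solution
is the second eigenpair: $\lambda_2$ is the *algebraic connectivity* (zero
if and only if the graph is disconnected) and its eigenvector, the *Fiedler
vector*, is the principal feature gradient.  Higher eigenvectors extend the
embedding to more dimensions (`eigenmapCoords()`), the rank order of the
Fiedler vector gives the spectral reordering, and the first three embedding
dimensions can be rendered as an RGB map (`rgbMap()`).

### The Vogt-Bailey index

The VB index is the normalised algebraic connectivity

$$\mathrm{VB} = \frac{\lambda_2}{\operatorname{mean}(\lambda_2, \ldots, \lambda_n)},$$

i.e. $\lambda_2$ divided by the mean of all eigenvalues save the first.
The denominator is what $\lambda_2$ becomes when the affinity matrix is all
ones, so $\mathrm{VB} \in [0, 1]$: 1 for a perfectly homogeneous region, 0
when a complete split exists.  The normalisation always uses the
eigenvalues of the *same* eigenproblem that produced $\lambda_2$; this is
the only convention under which the $[0,1]$ bound holds for every variant
(closed forms: the uniform complete graph has standard spectrum
$\{0, n, \ldots, n\}$ and generalized spectrum
$\{0, n/(n-1), \ldots, n/(n-1)\}$ — the ratio is exactly 1 in both).

Three analysis modes share this definition and differ only in which nodes
enter the graph:

* **full** (`fullAnalysis()`): all nodes, one gradient map, one VB value;
* **clustered** (`clusteredAnalysis()`): the graph is restricted to each
  labelled region in turn (clusters below 3 members are reported missing
  with a warning);
* **searchlight** (`searchlightAnalysis()`, `imageVbMap()`): per vertex,
  using the vertex plus its one-ring mesh neighbours (or 4/8-connected
  pixels).  With 5–6 neighbours the index answers a local question — is
  there a feature edge at this vertex? — which makes the map an edge
  detector on surfaces and images alike.

## Building the affinity

The similarity ladder is: dot product (confounds magnitude and angle),
cosine (scale-invariant), Pearson correlation (additionally
shift-invariant), and the angular measures

$$\mathrm{normAngle} = \frac{\arccos(\mathrm{corr})}{90^\circ} \in [0,2],
\qquad \mathrm{AngSim} = 1 - \mathrm{normAngle} \in [-1, 1].$$

AngSim is linear in the centred angle, so $+0.5$ means exactly half way
between orthogonal and collinear — an interpretation the raw correlation
does not have.

Spectral methods need $W \ge 0$.  The default policy
(`affinityPolicy()`) computes Pearson correlations, clamps negative values
to zero, and maps the retained values through
$r \mapsto 1 - \arccos(r)\,2/\pi$.  Because the angular transform is
strictly increasing and fixes 0 and 1, clamping before or after the
transform is equivalent; the result lies in $[0,1]$ with no shift constant.
Alternatives — adding a user-chosen shift constant (no default is imposed;
no principled value exists), an $\varepsilon$-threshold, union-symmetrised
$k$-nearest-neighbour sparsification, and binarisation — are all exposed
through the same policy object.  Thresholding is a real analytic choice:
keeping only the strongest weights ignores moderately connected nodes,
while keeping everything (the default) is more sensitive to spurious
similarity; both are available.

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `metric` | `affinityPolicy()` | `ang_sim` | pairwise similarity (dimensionless) |
| `negativity` | `affinityPolicy()` | `zero_negatives` | how non-negativity is enforced |
| `shift` | `affinityPolicy()` | 0 | additive constant under `shift_constant` |
| `thresholdEps` / `knnK` | `affinityPolicy()` | off | sparsification (mutually exclusive) |
| `problem` | all analyses | `generalized` | eigenproblem variant |
| `d` | `fullAnalysis()` | 3 | embedding dimensions (3 enables RGB) |
| `isolated` | graph/VB functions | `error` (`drop` in searchlights) | degree-0 node policy |
| `connectivity` | `imageVbMap()` | 8 | pixel lattice neighbourhood |
| `jobs` | searchlights | 1 | fork workers; results identical to serial |

## Numerical choices

* **Solver.**  All four problems reduce to one dense symmetric
  eigendecomposition (LAPACK via `eigen(symmetric = TRUE)`).  The
  degree-normalised problems are solved on $D^{-1/2} L D^{-1/2}$ and
  back-transformed ($x = D^{-1/2} y$ preserves $x^\top D x = 1$), which is
  stable whenever all degrees are positive.
* **Sign convention.**  Eigenvectors are only defined up to sign; each is
  flipped so its largest-magnitude component (first such component on ties)
  is positive, making gradient maps reproducible rather than defined up to
  reflection.
* **Degeneracy.**  If $\lambda_2$ is numerically repeated on either side —
  including a second zero eigenvalue, i.e. a disconnected graph — the
  solution carries a `degenerate` flag and `fiedlerPair()` warns: the
  Fiedler vector is then one member of an arbitrary basis.  Tolerance:
  gap $< 10^{-10} \max|\lambda|$.
* **Isolated nodes.**  Degree 0 makes $D$ singular.  The default policy is
  to stop; searchlights use `drop`, under which the VB index is reported as
  0 — an isolated node *is* a complete split, the singular degree matrix
  merely prevents the solver from saying so itself.  Negative VB values of
  floating-point size are clamped to 0.
* **Correlation clamping.**  Correlations are clamped to $[-1, 1]$
  (tolerance $10^{-12}$) before `arccos`.
* **Degenerate features.**  Constant feature vectors have no correlation;
  they are excluded (with an index map in the `dropped` slot) or isolated,
  per the `degenerate` argument of `buildAffinity()`.
* **Rank ties.**  `spectralReorder()` uses stable ordinal ranking, ties
  broken by node index.
* **Asymmetric input** (beyond $10^{-10}$) is rejected, not symmetrised:
  silent symmetrisation hides upstream bugs.
* **Indexing.**  Vertices and triangles are 1-based inside the package (the
  R convention); GIFTI's 0-based indices are converted at the I/O boundary.

## The synthetic generator

`makeIcosphere()` + `parcellateMesh()` + `parcelTimeseries()` generate the
fully controlled experiment the package validates itself on: a closed
surface is split into contiguous parcels (farthest-point seeds, multi-source
breadth-first growth, so regions are connected by construction), each parcel
receives one base time series, and every vertex carries its parcel's series
plus optional i.i.d. Gaussian noise.

Base series are constructed inside the mean-centred subspace as
$b_k = a_k q_0 + \sqrt{1 - a_k^2}\, q_k$ with orthonormal $q_i$, so the
sample correlation between parcels $j$ and $k$ is *exactly* $a_j a_k$.  The
loadings are jittered around $\sqrt{\rho}$ (default cross-correlation
$\rho = 0.3$, kept positive so the zero-negatives policy cannot disconnect
the whole-surface graph; pairwise correlations stay within $\pm 0.05$ of
$\rho$).  The jitter matters: perfectly equal cross-correlations combined
with equal parcel sizes make the affinity invariant under exchanging
parcels, which forces degenerate, symmetric eigenvectors — a pathology that
time series which merely "differ by parcel" do not have.

With zero noise the pipeline's expected behaviour is exact and is asserted
in the tests: the full-surface Fiedler vector is piecewise constant with
exactly one value per parcel; the searchlight map is 1 at every
parcel-interior vertex and drops below 1 exactly at vertices with a
cross-parcel neighbour; added noise strictly lowers the interior mean.

What the generator does **not** emulate: fMRI autocorrelation and
physiological noise, spatial smoothness of real acquisitions, folded
(non-spherical) cortical geometry, and subject variability.  Passing tests
therefore demonstrate the correctness of the machinery on data with known
ground truth, not the behaviour of the method under realistic MRI noise —
on real data the VB map is best read as a relative measure within or
between comparable acquisitions.

## Problem sizes

The validation suite runs at deliberately small scale, chosen so every
quantity has a known closed form or an exactly computable ground truth:
toy graphs of 3–10 nodes, icospheres at subdivisions 1–3 (42–642 vertices),
6 parcels with 200 timepoints for the main synthetic experiment, and
8–16 pixel test images with per-pixel brute-force oracles.  The dense
solver handles the tens of thousands of vertices of standard cortical
meshes in a full analysis, but no sparse/iterative path is provided for
substantially larger graphs (see limitations).

## Known limitations

* Dense eigendecomposition throughout: memory grows as $n^2$; very large
  meshes need more RAM than a laptop (a full analysis of a standard ~32k
  cortical mesh is feasible on workstation-class memory, larger graphs are
  out of scope).
* No statistical inference on VB or gradient maps (null models separating
  MR noise and intrinsic smoothness from real gradation are an open
  research question); the package computes the maps only.
* Surface and image grids only; no volumetric (voxel-lattice) searchlight,
  no CIFTI grayordinates, no mesh repair.
* The searchlight neighbourhood is strictly the one-ring (`kRing()` with
  $k \ge 2$ exists but is flagged non-canonical); no geodesic-distance
  neighbourhoods.

## A worked run

```{r example, eval = FALSE}
mesh <- makeIcosphere(3)                              # 642-vertex sphere
labels <- parcellateMesh(mesh, 6, seed = 42)          # contiguous parcels
f <- parcelTimeseries(labels, 200, crossCorr = 0.3,
                      noiseSd = 0, seed = 1)
full <- fullAnalysis(f, d = 3)                        # gradient + VB
sl <- searchlightAnalysis(f, mesh)                    # per-vertex VB
```

On this noise-free input the Fiedler vector of `full` takes exactly 6
distinct values (one per parcel) and `vbValues(sl)` equals 1 at every
parcel-interior vertex — the searchlight recovers the parcel borders with
no tuning.
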