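---
title: "Structured sparse representation of deformable organ surfaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured sparse representation of deformable organ surfaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srds)
```

## The model

A closed genus-0 surface sampled at a spherical parameterization
$(\theta_k, \phi_k)_{k=1..N}$ has coordinate functions that expand in
spherical harmonics. `srds` works with the *real* orthonormal (tesseral)
harmonics with Condon–Shortley phase: the cosine combination for $m > 0$,
the sine combination for $m < 0$, and the zonal harmonic for $m = 0$. Real
harmonics keep every downstream object — coefficient matrices,
dictionaries, codes — in real linear algebra while spanning the same
degree-$L$ space of dimension $(L+1)^2$; a complex decomposition of the
same real coordinate data differs only by a fixed unitary change of basis,
to which all the error metrics used here are invariant.

The modelling assumption is that deformation, not shape in general, is
low-dimensional: across a cohort of deformations of one organ, the per-axis
harmonic coefficient vectors lie (approximately) in a **union of a few
low-dimensional subspaces** of $\mathbb{R}^{(L+1)^2}$. Fitting that union
from training data, and coding any new deformation inside a single subspace
of it, is the whole pipeline:

$$ X = Y F, \qquad F = D C, \qquad \hat h = G_i c, \quad G = Y D . $$

The three coordinate axes are processed independently throughout — the
deformation structure of an organ need not couple axes, and per-axis
processing keeps every block well-conditioned.

## Tunable parameters

| parameter | meaning | default | units/scale |
|---|---|---|---|
| `L` | maximum harmonic degree | 10 (data-dependent) | — |
| `frequency` | icosphere subdivision; $N = 10f^2+2$ vertices | 20 | — |
| `epsilon` | pursuit stopping residual | 0.005 | unit-norm coefficient scale |
| `eta` | clustering residual threshold | 0.01 | unit-norm coefficient scale |
| `e_max` | pursuit iteration cap (max block dimension) | 50 | atoms |
| `delta` | code truncation threshold | 0.005 | normalized code scale |
| `min_cluster_size` | pruning population threshold | 2 | members |

`epsilon` controls how large each learned subspace grows (smaller
`epsilon`, more atoms per block); `eta` controls how aggressively training
vectors are absorbed into an existing block. `epsilon <= eta` is enforced:
a subspace built to tolerance `epsilon` should at least absorb its own
seed. `delta` trades sparsity for accuracy after coding; its natural range
is visible in the truncation sweep of `scripts/acceptance.R`. `L` should
satisfy $(L+1)^2 \le N$ with margin; degree 10 on a frequency-8 icosphere
(121 coefficients, 642 samples) is the configuration used in the package's
own experiments, and degree 20 on frequency 20 (441 of 4002) is typical
for kidney-sized organs at MRI resolution.

## Numerical choices

* **Least squares, not normal equations.** All SHD fits go through QR
  factorization (`qr.coef`), never through forming
  $(Y^\top Y)^{-1} Y^\top$ explicitly; a rank check rejects degenerate
  parameterizations (e.g. coincident sample directions) with an error that
  names the numerical rank.
* **Associated Legendre evaluation.** Fully normalized recurrence
  ($\bar P_{mm} \to \bar P_{m+1,m} \to \bar P_{lm}$), stable to high
  degree; the factorial-scaled textbook form overflows near $l = 30$ with
  large $m$, which the recurrence avoids.
* **Subspace dimension by numerical rank.** After pursuit, the selected
  atoms are orthonormalized by SVD and the block dimension is the rank at
  relative tolerance $10^{-10}$, so collinear atoms cannot inflate a
  block.
* **Tie-breaking.** Greedy atom selection breaks correlation ties toward
  the lowest column index; best-fit block selection breaks residual ties
  toward the lowest block index. During pruning re-partition, residual
  ties within $10^{-9}$ go to the *larger* block: a subspace nested inside
  another represents exactly the same vectors, and without this rule the
  nested block would retain its own atoms by first-index ties and survive
  population pruning, defeating the redundancy-removal step.
* **Scales.** Training columns are unit-normalized before learning (their
  norms are recorded and restored at reconstruction); residual thresholds
  `epsilon` and `eta` therefore act on a scale-free residual. Test-time
  coding uses the relative residual $\|h - \hat h\| / \|h\|$ for the same
  reason. Truncation compares $|c_j|$ against `delta` times the code's
  normalized scale, so `delta` means the same thing for training and test
  codes.
* **Degenerate inputs.** Zero training columns, empty pools, zero-area
  faces, non-unit icosphere vertices, rays with no intersection, and
  vertex-count mismatches all raise errors naming the offending column,
  ray or surface rather than propagating NaNs.

## Correspondence by ray casting

Meshes segmented independently from different scans have no common vertex
indexing. For star-shaped surfaces, the package resamples each centered
mesh along the vertex directions of a Class-I geodesic icosphere
(Möller–Trumbore ray–triangle intersection, watertight within a barycentric
slack of $10^{-9}$ so rays through shared edges are not lost). The
icosphere is built by frequency subdivision — each icosahedron edge split
into $f$ segments — because only that construction reaches the standard
vertex counts $10f^2+2$ (e.g. 4002 at $f = 20$). Multiple intersections
(non-star-shaped geometry) are an error in `strict` mode; by default the
outermost intersection is taken and a warning names the affected rays. The
mesh center is the unweighted vertex centroid by default (an area-weighted
option exists): the choice only shifts the ray origin slightly and any
consistent choice yields a valid correspondence.

## What the synthetic generator emulates — and what it does not

`planted_model()` + `sample_planted_cohort()` realize the union-of-subspaces
assumption *exactly*: per-axis coefficient vectors are
`base + A_j w + noise` with known orthonormal `A_j` (pairwise principal
angles forced above 10° so the planted union is identifiable) and Gaussian
weights. This provides ground truth for recovery tests that no real organ
cohort can provide. The generator's study conditions, chosen once:

* planted recovery experiments use J = 3 disjoint 5-dim subspaces in
  ambient dimension 441 with 20 unit-norm training vectors each, noiseless
  — the regime where exact recovery (projector distance $< 10^{-6}$) is
  the correct expectation;
* mesh-level cohorts use a unit-sphere base with deformation amplitude
  0.03 (about 1.5 % of the coefficient norm per subspace direction),
  K = 30 training and M = 10 test surfaces on a frequency-8 icosphere at
  L = 10 — sizes that keep the full test suite in seconds while leaving
  every matrix comfortably overdetermined;
* sensitivity cohorts add coefficient noise with sd $5\times10^{-4}$
  (deformation-to-noise ≈ 60:1), a realistic surface-extraction error
  level. This places the pursuit's residual floor inside the studied
  `epsilon` range, which is precisely the regime where `epsilon` trades
  dictionary size against accuracy.

What the generator does **not** emulate: tissue mechanics (deformations are
drawn in coefficient space, not simulated), segmentation artifacts,
topology changes, or rigid misalignment (cohorts are emitted centered and
corresponded). Passing tests therefore certify the algorithmic chain —
decomposition, learning, coding, metrics — under the model's own
assumption, not the fidelity of that assumption for any particular organ.
`apply_bump_deformation()` additionally provides localized "poke/grasp"
Gaussian dents for qualitative experiments outside the planted model.

## Design decisions on open points

* **Pursuit pool.** Atoms for a seed are drawn from the full training set
  minus the seed (not merely the not-yet-clustered remainder): already
  clustered vectors remain legitimate atoms for describing later seeds.
* **Seed policy.** Deterministic first-remaining-column (a seeded random
  policy is available); reproducibility outweighs any benefit of
  randomized seeding at these cohort sizes.
* **Threshold coding order.** The `threshold` strategy scans blocks in
  ascending index order and falls back to best-fit with a warning when no
  block meets `eta`; failing outright would make the strategy unusable on
  borderline surfaces.
* **Re-pursuit baseline.** Coding by greedy pursuit directly over all raw
  training columns (the natural non-structured competitor) is implemented
  as `repursuit_code()` and compared in the acceptance script; structured
  coding matches it to well within a factor of two in mean EOF on the
  study cohorts while never mixing blocks.
* **Pruning re-partition** assigns by nearest subspace (no `eta` gate) and
  reports columns whose final residual exceeds `eta` as `uncovered`
  rather than failing — with real cohorts a handful of outliers is normal
  and the caller should see them.
* **Sparsity accounting.** `l0` is reported both before and after
  `delta`-truncation (`l0_raw` vs `l0` in predictions), since either
  convention is defensible.
* **EOF convention.** Stacked over the three axes by default (one number
  per surface); a per-axis variant is exposed. Hausdorff distance is
  point-to-vertex-set, exactly as defined; point-to-triangle would be
  smaller on coarse meshes but is not the reported quantity.
* **Subspace-level optimization during pruning** (joint re-optimization of
  block bases) is out of scope; pruning is re-partition + population
  threshold + re-partition.

## Known limitations

* Ray-casting correspondence requires star-shaped geometry; deeply folded
  surfaces (cortex) need an external correspondence method, after which
  the rest of the pipeline applies unchanged.
* With `epsilon` in the transition regime, greedy pursuit can
  occasionally stop one atom early on a near-degenerate cohort draw and
  fragment a cluster; across random cohorts the dictionary size is
  therefore not strictly monotone in `epsilon`, although the trend on a
  fixed cohort is (and is what the tests assert). Medians over replicate
  cohorts are the robust summary, and `scripts/acceptance.R` reports them
  for the recovery experiment.
* The dual-layer path assumes per-layer vertex counts are constant across
  the cohort and both layers share the harmonic degree.
* Binary PLY/STL variants are not read; meshes must be ASCII.

## Problem sizes

The test suite and acceptance script run on frequency-8 icospheres
(642 vertices, L = 10, K = 30, M = 10) and 441-dimensional planted
recovery problems (K = 60, M = 20), which exercise every code path at a
few seconds total; the same code runs unchanged at frequency 20 / L = 20
organ scale.
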