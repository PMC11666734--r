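---
title: "Statistical shape model reconstruction of fractured hemipelves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape model reconstruction of fractured hemipelves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Displaced acetabular fractures are planned virtually before open reduction and
internal fixation: a model of the *intact* hemipelvis is needed as a template
against which reduction can be judged and osteosynthesis plates pre-contoured.
When the contralateral hemipelvis is unavailable as a mirror template
(bilateral fracture, in-situ implants, marked asymmetry), a statistical shape
model (SSM) of intact anatomy can supply the template instead: the fractured
bone's fragment surfaces are fitted by the model, and the fitted instance is
the estimate of the pre-injury shape.

`ssmrec` implements that workflow end to end: surface-mesh preprocessing,
dense correspondence by non-rigid registration, a PCA point-distribution
model, subspace fitting of fragmented surfaces, and an evaluation layer that
reports whole-surface and plate-fitting-region errors together with six
clinical parameters (iliopectineal line length and curvature radius, ischial
body line length and radius, acetabular diameter, quadrilateral-plate slope).

## The shape model

Let $x_1,\dots,x_n \in \mathbb{R}^{3V}$ be intact training shapes in dense
point-to-point correspondence (vertex $i$ is the same anatomical location in
every shape). The model is the usual point-distribution model:

$$\bar{x} = \tfrac1n \sum_k x_k, \qquad
  S = \tfrac{1}{n-1}\sum_k (x_k-\bar x)(x_k-\bar x)^\top,$$

with principal components $P = [p_1 \dots p_K]$ and variances
$\lambda_1 \ge \dots \ge \lambda_K$ the leading eigenpairs of $S$. A shape is
synthesised as $x(b) = \bar x + P b$. The decomposition runs as a thin SVD of
the centred $n \times 3V$ data matrix — the $3V \times 3V$ covariance is never
formed ($V \sim 10^3$–$10^5$). We retain $K = 15$ components by default, the
choice used for hemipelvis reconstruction models built from 200 intact left
hemipelves. No Procrustes size normalisation is applied: plate fitting needs
absolute millimetre dimensions, so alignment is rigid only. During fitting,
scores are clamped to $\pm 3\sqrt{\lambda_k}$ (disable with `clamp = FALSE`);
this standard plausibility constraint also silences the directions with
numerically zero variance when $K$ exceeds the number of informative modes.
All shapes in a model are expressed as one side (left); opposite-side meshes
are mirrored (`mirror_sagittal()`) before registration, and a pooled
(sex-unstratified) mean is used as the single template.

## Correspondence: non-rigid ICP

`nonrigid_icp()` deforms the template onto a target surface. Writing $v$ for
the rest positions and $D$ for the per-vertex displacement field, each round
finds gated closest points $c_i$ (rejected beyond `max_corr_dist`, default
10 mm — displaced fragments should not drag the template — or when the local
normals disagree by more than `max_normal_angle`, default 60°) and solves

$$\Bigl(\underbrace{M}_{\text{data}} + \alpha\, L \otimes I_3\Bigr)\,D
  = M\,(c - v),$$

where $L$ is the symmetrically normalised graph Laplacian of the template and
$\alpha$ anneals down the stiffness schedule (default
$[100, 50, 20, 10, 5, 2]$, scaled by `smoothing_weight`). Three design points
matter and were each verified on known-deformation phantoms during
development:

* **Total-displacement regularisation.** The Laplacian penalises the *total*
  field $D$, not per-round increments. With incremental smoothing,
  unsupported vertices (those with no valid correspondence — e.g. over a
  fracture defect) creep onto the wrong surface over many rounds; with total
  regularisation they stay on the smooth extension of their neighbours'
  motion. On a half-deleted surface, the fraction of defect vertices
  correctly flagged invalid equals the geometric bound (the fraction farther
  than the gate from the remaining surface).
* **Point-to-plane data term.** $M$ blends a point-to-point and a
  point-to-plane term, $w_i[\beta I + (1-\beta)\,\hat n \hat n^\top]$ with
  `point_weight` $\beta = 0.1$. Closest-point matching determines the normal
  offset of a surface reliably, but its tangential component is almost
  unconstrained.
* **Tangential anchor.** On a closed surface, tangential motion is *invisible*
  to geometric matching: any smooth tangential reparametrisation fits the
  target equally well, and the fixed-point iteration otherwise drifts along
  the surface. A weak anchor `tangential_weight` $(I - \hat n \hat n^\top)$
  toward the rest position selects the minimal-tangential-motion
  correspondence. The default 0.1 removes the drift while keeping the bias
  acceptable for deformations several millimetres in amplitude; larger values
  suppress drift harder but under-recover large shape differences.

The solver is deterministic (grid-accelerated closest-point queries and
sparse supernodal Cholesky with a single symbolic analysis; weights are
lagged within a stiffness level so each level factors once). Rigid
pre-alignment registers the *target onto the template* with trimmed ICP and
applies the inverse — the well-posed direction when the target is partial.

A consequence of the tangential ambiguity is worth stating plainly: for
targets whose true deformation has a large tangential component, the
registration recovers the *surface* but not the exact parametrisation. The
synthetic population generator therefore uses surface-normal displacement
fields — the observable component of shape change — and the recovery tests
quantify exactly that setting.

## Fitting a fracture

`reconstruct_fracture()` estimates the intact shape from the merged fragment
surfaces. Each outer round:

1. re-estimates the fragments' rigid pose by trimmed ICP against the
   *current* model instance (aligning against the mean alone would absorb
   genuine shape difference into a spurious rigid motion);
2. iterates, to a fixed point: gated closest-point correspondence of the
   instance to the fragments, then a *plane-weighted* masked projection
   $\min_b \sum_i w_i\,[\hat n_i^\top(\bar x_i + (Pb)_i - c_i)]^2$ with the
   3-sigma clamp, then synthesis of the new instance.

The plane weighting is the load-bearing choice. An early design projected
free-form registration output with an ordinary masked least squares; its
tangential correspondence error (invisible to surface matching, see above)
contaminated the coefficients by tens of percent. Constraining the fit only
along the local surface normal uses precisely the information closest-point
matching gets right, and the model subspace itself supplies the deformation
prior — recovering generator coefficients to a few percent from fragments
with 10 % of the surface deleted. The free-form `nonrigid_icp()` remains the
correspondence engine where a dense, model-free correspondence is the point:
registering the mirrored contralateral hemipelvis as the ground-truth
comparator (`reconstruct_from_contralateral()`), which is deliberately *not*
projected into the subspace. That route is model-assisted: the SSM is first
fitted to the complete intact surface and the free-form registration refines
from the fitted instance — starting free-form from the mean leaves several
millimetres of correspondence error on shapes far from the mean, while from
the fitted instance the residual deformation is small and accurately
recovered, without constraining the result to the subspace.

Fragments are used where they lie; automatic repositioning of displaced
fragments is out of scope. When less than 25 % of the template finds fragment
support the result carries a warning — reconstructions beyond that
missing-data level are known to degrade appreciably.

Defaults: `max_outer = 5` with convergence tolerance `tol = 0.1` mm on the
instance's mean coordinate change (typically 2–4 rounds are used), up to 12
correspondence/projection rounds per outer.

## Preprocessing

* `remesh_isotropic()` — incremental remeshing (edge split/collapse at
  $4/3$ and $4/5$ of the target, valence-equalising flips, tangential
  relaxation with back-projection onto the input surface), 4 sweeps by
  default. The pipeline convention is a 1.5 mm isotropic edge length, giving
  the uniform vertex distribution PCA assumes. Deterministic; watertight
  inputs stay watertight; projection bounds the deviation from the input
  surface.
* `make_watertight()` / `wrap_surface()` — boundary-loop detection, centroid
  fans for holes up to a perimeter bound, largest-component selection and
  optional Taubin smoothing ($\lambda = 0.5$, $\mu = -0.53$, 10 iterations).
  This is a hole-filling closure, an *approximation* of the proprietary
  shrink-wrap used by clinical segmentation suites; it is not claimed
  equivalent, and the fill report flags boundaries left open.
* Units are millimetres everywhere; mesh files carry no unit metadata, and
  `units_scale` rescales on read.

## Evaluation

RMSE between corresponded shapes is
$\sqrt{\text{mean}_i\, \lVert a_i - b_i \rVert^2}$, over all vertices
(whole-surface) or over the 66 landmark coordinates of the five
plate-fitting regions (12 iliopectineal, 12 quadrilateral plate, 8 ischial
body, 4 acetabular rim, 30 weight-bearing dome). The regional RMSE pools all
66 coordinates into one number per case; per-region values are available for
diagnostics. Landmarks are template vertex *indices*, so they transfer to any
corresponded shape for free.

The six clinical parameters: line lengths are polyline lengths over the
ordered landmarks; a line's "radius" is the curvature radius of the best-fit
circle through its landmarks (total-least-squares plane projection, algebraic
Kåsa fit, geometric Gauss–Newton refinement); the acetabular diameter is
twice the fitted circle radius of the four rim points; the quadrilateral
slope is the dihedral angle between the landmark plane and the plane
orthogonal to the template's superior–inferior axis, in $[0°, 90°]$ (coplanar
landmarks whose normal is parallel to the axis score 0°). The precise
clinical conventions behind radius and slope are not standardised; these
definitions are constructed to be exactly testable and are invariant under
rigid motion, point order, and axis negation.

Group summaries are median and IQR (25th/75th percentile, linear
interpolation between order statistics, quantile type 7), and two-group
comparisons use the Mann-Whitney U test — exact (via the null distribution of
U, equivalent to full enumeration) when the pooled sample is at most 12
without ties, otherwise the normal approximation with tie and continuity
corrections. No multiple-testing correction is applied, matching the single
planned comparisons of the evaluation design.

## Synthetic validation data

No patient data ships with the package. `make_template()` builds a
deterministic, closed, stylised left hemipelvis — a flanged (iliac wing),
dented (acetabular cup), twisted ellipsoid, ~80 mm across, from a subdivided
icosahedron — with the five landmark regions placed on *constructed*
geometry: the line landmarks lie on exact circular arcs through exact surface
points, the rim landmarks on an exact circle, the plate landmarks in a plane
of exactly 55° inclination. The generator stores those constructed values, so
the clinical-parameter operators are testable to numerical precision. The
anatomy is deliberately stylised, not patient-derived; landmark-carrying
vertices are snapped onto the constructed primitives (sub-millimetre to
few-millimetre moves).

`generate_population()` draws training shapes
$x_k = \text{template} + \sum_j c_{kj} f_j$ with $c_{kj} \sim N(0,\sigma_j^2)$
and smooth, band-limited (default 60 mm wavelength), mutually orthogonal
surface-normal displacement fields normalised to unit RMS per-vertex
displacement — so $\sigma_j$ is in millimetres and the implied PCA
eigenvalues are $\sigma_j^2 V$, both returned for recovery tests. The default
population (modes 6/3/1.5 mm) represents realistic inter-individual pelvic
variation of a few millimetres RMS.

`simulate_fracture()` partitions the surface by random planes through the
interior (fragments), deletes a contiguous region grown from a random seed
face to a target area fraction (lost comminution), and rigidly displaces
every fragment but the largest within set bounds. The input shape is the
ground truth; the achieved deletion fraction is reported.

What passing on this synthetic data does *not* show: robustness to
segmentation noise, holes and thin-plate artefacts of real CT surfaces, to
true anatomical asymmetry (the contralateral route assumes left–right
symmetry), or to fracture patterns whose fragments are displaced beyond the
correspondence gate. Those require clinical data the package does not ship.

## Problem sizes and numerical choices

The validation experiments use the template at subdivision 3 (V = 2562,
~2.5 mm edges), populations of 40 shapes (200 for the subspace-recovery
check, mirroring the size of the cohort such models are built from), K = 15,
20 fracture seeds per deletion level (0/10/25/40 %, zero displacement to
isolate the missing-data effect), and a 20-case two-group cohort (10 % vs
35 % deletion with 3 mm / 3° fragment displacement) for the end-to-end run.
These sizes were chosen as the smallest that make the statistical checks
stable.

Ties and degeneracies: duplicate mesh vertices are welded at 1e-9 mm on
read; collinear landmark sets raise errors rather than returning infinite
radii; a zero Mann-Whitney variance (all values tied) reports p = 1; PCA on
fewer informative modes than K yields zero variances, handled by the clamp.
All randomness flows through explicit seeds (`population_spec`,
`fracture_spec`); the registration and reconstruction path is free of random
choices, so identical inputs give byte-identical outputs.

## Known limitations

* Correspondence is defined by the registration, not by anatomy: tangential
  placement is conventional (minimal tangential motion), which is the right
  convention for comparing two shapes registered the same way but is not a
  biological homology claim.
* The hole-filling "wrap" differs from proprietary shrink-wraps; heavily
  fragmented, overlapping segmentations may close differently.
* Fragment displacement beyond `max_corr_dist` leaves fragments unused
  (masked out) rather than repositioned.
* Clinical parameter conventions (radius, slope) are the package's own
  constructions; absolute values should not be compared against other
  software without checking conventions, though *differences* between a
  reconstruction and its ground truth are convention-stable.
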