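---
title: "Multi-atlas segmentation with graph cuts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-atlas segmentation with graph cuts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`atlascut` segments a single anatomical structure in a 3-D scalar volume by
combining three ingredients that share one spatial-normalisation scheme and
one segmentation engine:

1. a **probabilistic atlas** — voxelwise appearance statistics and a voting
   label prior built from moment-aligned training atlases;
2. a **conditional random field (CRF)** whose exact global minimiser is found
   by min-cut/max-flow;
3. a **multi-atlas refinement** — ranking the atlases against a coarse mask,
   nonrigidly warping the best few onto the target, and fusing their labels
   with one more graph cut.

This vignette explains the models, the tunable parameters and their units,
what the synthetic phantoms do and do not emulate, and the numerical design
choices a maintainer would want to know about.

## The segmentation model

A binary labelling $S : \Omega \to \{0,1\}$ of the target image $I$ is found
by minimising

$$E(S) \;=\; \sum_{x} \psi_x(S(x)) \;+\; \sum_{(x,y)} \psi_{xy}(S(x),S(y)),$$

where the sum over $(x,y)$ runs over *ordered* pairs of 6-neighbours.

**Unary terms.** Each voxel pays the negative log of its posterior factor:
the appearance likelihood times the spatial prior. The appearance model is a
voxelwise Gaussian per label: at voxel $x$ with aligned atlas set
$\{\tilde I_i, \tilde S_i\}$, the mean $\mu_l(x)$ and unbiased variance
$\sigma_l^2(x)$ are estimated over the atlases whose label at $x$ is $l$,
then both maps are smoothed at scale $\sigma_s$ voxels with a normalised
Gaussian under reflective boundaries (the discrete counterpart of linear
diffusion with Neumann conditions, so constants are fixed points and the
mean map's volume mean is conserved). The smoothing diffuses the
*sufficient statistics*: the smoothed variance is
$\widetilde{\sigma^2} = h_{\sigma_s}*(\sigma^2+\mu^2) - (h_{\sigma_s}*\mu)^2$,
the law of total variance under the smoothing kernel. Where the mean map is
locally flat this coincides with smoothing the variance map itself; where
the mean varies it additionally absorbs that local dispersion, which keeps
the Gaussian likelihood calibrated — smoothing mean and variance
independently makes the model arbitrarily overconfident next to intensity
structure in the mean map (with near-zero empirical variances, z-scores of
tens appear and the unary term hallucinates labels along such rims). The
label prior is the voting fraction
$p(S(x)=1) = \#Q_1(x)/N$, clamped to $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 1/(2N)$ so that no voxel is infinitely expensive.

Two degenerate-input rules are needed that the unbiased estimator leaves
open: a voxel where *no* atlas carries label $l$ takes the global mean of
that label, and a voxel where fewer than two atlases carry $l$ takes the
global variance. The single observed sample *is* kept as the mean when
$\#Q_l = 1$: discarding it would erase the spatial appearance model exactly
in the single-atlas fusion case, where it carries all the information.
Variances are floored at $(0.01 \cdot \text{intensity range})^2$.

**Pairwise terms (Finsler regulariser).** For the ordered pair $(x,y)$,

$$\psi_{xy}(0,1) = \lambda_1\,\omega^R_x(y) - \lambda_2\,\omega^f_x(y),
\qquad \psi_{xy}(1,0) = \lambda_2\,\omega^f_x(y),$$

with $\omega^R_x(y) = g(\|\nabla I(x)\|)/\|x-y\|$,
$g(t) = \exp(-t/\gamma)^{1/3}$, and $\omega^f_x(y)$ the dot product of
$\nabla I(x)$ with the unit vector from $x$ to $y$ (all distances in mm;
gradients by Gaussian derivatives at scale 1 voxel, converted to per-mm).
$\gamma$ defaults to the mean gradient magnitude over the region of
interest. Because the gradient is evaluated at $x$, the flow weight is not
antisymmetric under swapping the roles of $x$ and $y$; the graph therefore
carries both orderings as directed terms. Summed over the two orderings of
a pair, the flow contributions cancel and the remaining cut cost is
$\lambda_1(\omega^R_x(y) + \omega^R_y(x)) \ge 0$ — the energy is submodular
whenever $\lambda_1 \ge 0$, which the configuration enforces, and the min
cut is the exact global minimiser. Negative per-ordering costs are folded
into the unaries by the standard reparameterisation before max-flow. The
flow problem itself is solved by the package's own Dinic implementation
(compiled, residual-reachability cut recovery); general-purpose graph
libraries proved orders of magnitude slower on these grid graphs, and the
solver's exactness is pinned by property tests against exhaustive
enumeration on small instances.

A unit subtlety worth recording: $\omega^R$ is dimensionless in intensity
(normalised by $\gamma$) and the unaries are log-probabilities, but
$\omega^f$ is a *raw* gradient and scales with the intensity units of the
data. The weights $\lambda_1 = 10$, $\lambda_2 = 4$ therefore implicitly
assume an intensity regime; with the package's default phantom intensities
(order 1) the flow term is a mild orientation preference, which matches its
documented role as the least influential term. Rescaling the intensities by
a large factor silently rescales the flow term with them.

**Tunable parameters.**

| parameter | default | units | role |
|---|---|---|---|
| `lambda1` | 10 | — | Riemannian (surface-area) weight; must be $\ge 0$ |
| `lambda2` | 4 | per intensity unit | flow/orientation weight; may be negative |
| `sigma_s` | 2 | voxels | smoothing of the statistical maps |
| `k_iters` | 4 | — | coarse registration/segmentation iterations (1–10) |
| `gradient_scale` | 1 | voxels | Gaussian-derivative scale |
| `n_atlases` | 6 | — | atlases fused in the multi-atlas stage |

## The coarse stage

Starting from an imperfect initial mask $S^0$, the loop alternates: (i)
moment-align the current mask to the atlas reference frame — centroid,
principal axes from second-moment eigenvectors, and per-axis anisotropic
scaling; (ii) resample the target image into that frame; (iii) segment by
graph cut against the probabilistic atlas; (iv) map the result back to the
native grid. With smoothing on ($\sigma_s > 0$) the alternation settles in
a few iterations. The working image is subsampled by two per axis; the
evolving mask itself stays at native resolution, which costs nothing and
avoids an avoidable resolution ceiling in the output.

Two numerical stabilisers were found necessary at phantom scale and are
deliberate design choices rather than part of the model:

* **Under-relaxation.** The affine update is averaged 50/50 with the
  previous transform. The raw alternation is a discrete fixed-point
  iteration whose feedback gain is close to one when the mask holds only a
  few thousand voxels — a few tens of flipped boundary voxels move the
  moments enough to flip a similar number on the next pass, and the
  iteration settles into a period-2 cycle. Damping restores contraction.
* **Minimum meaningful update.** An affine update that displaces the
  reference frame by less than half a working voxel is not applied. Updates
  below the working resolution carry no information, and freezing them
  gives the discrete iteration an exactly reproducible fixed point, so the
  DICE-based early stop (threshold 0.999 between consecutive masks) can
  actually fire. Both devices are the registration analogue of the
  minimum-step stopping rules in standard registration toolkits.

## The multi-atlas stage

Atlases are ranked by the DICE overlap between the moment-aligned coarse
mask and each aligned atlas label map (alternatives: mutual information of
the aligned images over the reference region of interest, or a seeded
random order — both kept for comparison experiments). The top $n$ atlases
are affinely aligned to the target using the coarse mask, then refined by
masked multiresolution cubic-B-spline registration driven by mutual
information: at each iteration a fresh random subset of voxels inside the
dilated coarse mask is drawn, a Parzen-window joint histogram (linear window
on the fixed intensity, cubic B-spline window on the moving intensity, 32
bins) yields the MI and its analytic gradient with respect to the
control-point displacements, and a gradient step with decay $a/(t+A)$ is
taken. Control points whose support does not touch the dilated mask are
frozen at zero, so the displacement vanishes identically away from the
mask. Lattice spacings default to 64/32/16/8 mm and are scaled down by the
ratio of the field of view to a 400 mm abdomen, keeping at least four
control intervals per axis at the finest level; each level smooths both
images with a Gaussian matched to a quarter of its control spacing. The
optimiser's step scale is normalised on the first iteration of each level
(step of an eighth of the control spacing at unit decayed rate), which
makes the schedule dimensionless; iterations per level (200) and the decay
offset ($A = 20$) are declared defaults of this implementation.

The warped (image, label) pairs then play the role of a small atlas set on
the target grid: the same statistical maps are rebuilt from them
($N = n$, same $\sigma_s$ smoothing, exposed in the configuration) and one
graph cut over the dilated coarse region yields the consensus — no further
iterations are needed at this stage.

## The synthetic phantoms

The generator emulates the statistical structure the method assumes,
without claiming CT realism: a base organ (superellipsoid of exponent 2.5
with sign-asymmetric semi-axes, extents 80/64/48 mm) deformed per subject
by a smooth random warp (Gaussian-filtered white noise, filter scale 8
voxels, RMS amplitude `deform_sd` = 3 mm) and a random affine (rotations up
to 8°, per-axis scales 0.92–1.08, translations up to 6 mm); piecewise
constant intensities (organ 1.2, background 0.7) with i.i.d. Gaussian noise
(0.08); and an adjacent confounder blob at intensity 1.16 — within one
noise standard deviation of the organ — touching the organ's bounding box
but never its support, emulating an adjacent structure that intensity alone
cannot separate. Grids are 64×64×48 voxels at 2×2×3 mm, anisotropic like
abdominal CT. Target initial masks are built from the truth by a smooth
boundary warp plus a random erosion or dilation of about two voxels, with
the amplitude adapted deterministically until the initial overlap lands in
the 0.85–0.97 DICE band.

Three generator choices deserve their rationale on record. The principal
extents are clearly separated because second-moment eigenvectors — and with
them the whole moment alignment — become ill-conditioned when two
eigenvalues nearly coincide; the anatomy this method addresses has distinct
axes, and a generator that randomly produced degenerate ones would test
numerical noise rather than the method. The intensities are of order one so
that the default pairwise weights sit in their intended regime (see the
unit note above). And the organ occupies a few thousand half-resolution
voxels, roughly a hundred times fewer than a clinical liver; boundary
effects are correspondingly harsher on every overlap score, which is why
the phantom-scale accuracy targets are lower than typical
clinical-scale figures.

What passing the phantom suite does *not* show: robustness to CT
artefacts, tumours and vessels, intensity inhomogeneity, or the low-level
initial-solution pipeline of the clinical application (lung-based
separation surfaces, nonlinear diffusion, edge detection) — the phantom
initial mask replaces all of that by construction.

## Numerical choices and degenerate inputs

* Eigenvector sign ambiguity in the moment alignment is resolved by the
  third-moment (skewness) direction only when the standardized skewness is
  decisive (|g1| > 0.2); otherwise the sign closest to the canonical axis
  is taken, and the basis is forced to determinant +1. A sign tied to a
  near-zero skewness flips between near-identical masks and destabilises
  the iterated registration; the coarse threshold trades a little
  generality (masks rotated far from axis-alignment) for stability in the
  regime the method actually operates in.
* Probabilities are floored at $10^{-12}$ before logs; unary ties resolve
  to background; DICE ranking ties break by atlas index; label resampling
  is always nearest-neighbour; downsampling ties (4 of 8 foreground voxels)
  resolve to foreground, preferring not to lose thin structures.
* The graph is restricted to the dilated bounding box of the region of
  interest (8 voxels for the coarse stage, 2 voxels around the already
  dilated coarse mask at fusion); voxels outside are fixed to background
  and cross-boundary pairwise terms are dropped.
* Mask morphology (dilation/erosion by a metric radius) is computed through
  exact Euclidean distance transforms, so structuring elements are true
  spheres under anisotropic spacing.

## Problem sizes used by the test suite

The automated suite exercises the full pipeline on one 10-atlas database
and twenty seeded targets at the default 64×64×48 phantom scale, with the
fusion-stage registration run at two levels (32/16 mm control spacing
before field-of-view scaling, 40 iterations of 1000 samples per level) and
six fused atlases — sizes chosen so the whole study remains a desk-scale
computation while every stage still runs end to end. The registration
quality criteria (landmark-error halving, MI improvement) use a
three-level schedule on a single target. All randomness descends from
fixed seeds; rerunning the suite reproduces every number exactly.

## Known limitations

* Binary labels only; multi-label fusion (α-expansion) is out of scope.
* The moment alignment has no shear component — shear is unidentifiable
  from second moments — and assumes distinct principal axes.
* The flow term's intensity-unit dependence (above) means `lambda2` must be
  re-examined whenever data with a different intensity scale is used.
* The B-spline registration offers no diffeomorphic guarantee and no
  bending-energy penalty; large warps can fold.
* MetaImage support covers the common axis-aligned, uncompressed or
  gzip-raw cases; oblique direction matrices and DICOM series are not read.
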