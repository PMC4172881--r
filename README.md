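# atlascut

Atlas-based binary segmentation of 3-D scalar volumes, built around one
segmentation engine — exact minimisation of a conditional random field
energy by graph cuts — used twice: once with a **probabilistic atlas** to
obtain a coarse mask through an iterative affine-registration/segmentation
loop, and once to **fuse** the labels of nonrigidly warped, similarity-ranked
atlases into the final consensus. The design targets organ segmentation in
CT-like volumes (the motivating case is the liver, whose neighbouring heart
has nearly the same intensity), but every stage is generic: it needs only an
intensity image per atlas, a binary label map, and an imperfect initial mask
for the target.

## The model

A labelling $S:\Omega\to\{0,1\}$ minimises

$$E(S)=\sum_x \psi_x(S(x)) + \sum_{(x,y)}\psi_{xy}(S(x),S(y)),$$

* $\psi_x(l) = -\log\big(p(I(x)\mid l)\,p_l(x)\big)$ — a voxelwise Gaussian
  appearance model $p(I\mid l)\propto e^{-(I-\mu_l(x))^2/2\sigma_l^2(x)}/\sigma_l(x)$
  with means/variances estimated from coregistered atlases and smoothed at
  scale $\sigma_s$, times a voting prior $p_1(x)=\#\{i: \tilde S_i(x)=1\}/N$;
* $\psi_{xy}$ — a Finsler regulariser: a Riemannian surface term weighted by
  the edge-stopping function $g(\|\nabla I\|)=\exp(-\|\nabla I\|/\gamma)^{1/3}$
  (weight $\lambda_1=10$) plus an antisymmetric flow term given by the
  gradient/edge dot product (weight $\lambda_2=4$), assembled over directed
  6-neighbour pairs. The energy is submodular for $\lambda_1\ge 0$, so
  min-cut/max-flow returns the exact global minimiser.

The pipeline is: initial mask → iterative moment-based affine registration +
graph cut against the probabilistic atlas (subsampled by two, $k=4$
iterations) → DICE-based atlas ranking with the coarse mask → masked
multiresolution cubic-B-spline registration of the top $n=6$ atlases driven
by stochastic-gradient mutual information → statistical maps rebuilt from
the warped atlases → one final graph cut.

Segmentations are scored with the standard five benchmark error measures
(volumetric overlap error %, signed relative volume difference %, and
average / RMS / maximum symmetric surface distance in mm), each converted to
a 0–100 scale by $\alpha_j = \max(100 - 25\,m_j/\tilde m_j,\,0)$ and
averaged; 100 is a perfect match and about 75 corresponds to human-expert
performance.

## Worked example

No external data is needed: the package ships a phantom generator that
reproduces the statistical structure the method assumes (shape variability
across subjects, organ/background contrast, an adjacent equal-intensity
confounder, noise).

```r
library(atlascut)

atlases <- generate_atlas_set(10, phantom_spec(seed = 100))
pa      <- build_probabilistic_atlas(atlases, sigma_s = 2)

target  <- generate_target(phantom_spec(seed = 203))
coarse  <- coarse_segment(target$image, target$initial, pa$maps, pa$aligned,
                          coarse_config(k_iters = 4))

ranking <- rank_atlases(coarse$mask, pa$aligned, "dice")
fused   <- fuse_atlases(target$image, coarse$mask, atlases, ranking,
                        fusion_config(n_atlases = 6,
                                      ffd = ffd_config(levels = 2,
                                                       grid_spacings = c(32, 16),
                                                       iters_per_level = 40,
                                                       samples_per_iter = 1000)))

round(c(initial = dice(target$initial, target$truth),
        coarse  = dice(coarse$mask,   target$truth),
        fused   = dice(fused$mask,    target$truth)), 3)
#> initial  coarse   fused
#>   0.859   0.939   0.999

ev <- evaluate_segmentation(target$truth, fused$mask)
round(unlist(ev[c("m1", "m2", "m3", "alpha", "dice")]), 2)
#>    m1    m2    m3 alpha  dice
#>  0.15 -0.13  0.01 98.68  1.00
```

The three DICE values show the pipeline doing its job: the imperfect initial
mask (0.86) is improved by the probabilistic-atlas loop (0.94) and the
multi-atlas fusion recovers the ground truth almost exactly (0.999). In the
evaluation report, `m1` is the volumetric overlap error in percent, `m2` the
signed relative volume difference in percent, `m3` the average symmetric
surface distance in mm, and `alpha` the aggregate 0–100 score.

A command-line interface covering the same steps (`simulate`, `build-atlas`,
`coarse`, `rank`, `fuse`, `evaluate`, `sweep-n`) is installed at
`inst/cli/atlascut.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/atlascut.R", package="atlascut"))')" \
    simulate --n 10 --seed 1 --out phantoms/
```

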