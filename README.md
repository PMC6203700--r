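# rabatlas

Multi-atlas segmentation tools for the neonatal rabbit brain.

The newborn rabbit is an increasingly popular model for perinatal brain
injury: its white-matter maturation timing is close to the human one,
but — unlike for rodents — no digital neonatal brain atlas ecosystem
exists around it. `rabatlas` implements the computational machinery a
micro-MRI rabbit multi-atlas needs, end to end:

* **Stereotaxic reorientation** from bicommissural landmarks. The rodent
  convention (bicommissural plane horizontal) does not suit the rabbit
  brain; here the rigid reorientation places the mid-sagittal plane at
  `x = 0`, the anterior commissure (AC) at the origin, and the AC→PC
  direction at 45° below the horizontal plane, PC posterior-inferior.
* **A hierarchical taxonomy** of 89 delineated regions with left/right
  odd/even id convention and explicit contralateral pairing, plus the
  16 macro-region grouping used for validation, ITK-SNAP label-file
  export, and JSON descriptors.
* **Diffeomorphic segmentation propagation**: transforms are rigid /
  affine matrices or stationary velocity fields (SVF) exponentiated by
  scaling and squaring (`exp(v)`, with `exp(v)∘exp(−v) ≈ id`), with a
  builtin moments-initialized, multiresolution demons-style registration
  and an external-command escape hatch.
* **Label fusion**: majority voting; multi-label STAPLE, the EM
  algorithm estimating the hidden true segmentation together with each
  atlas's confusion matrix `θ_i(true, observed)`; and STEPS, which ranks
  atlases per voxel by local normalized cross-correlation (LNCC) of
  their warped images against the target and fuses only the best `k`.
* **Four similarity metrics** with per-label and macro-region reports:
  Dice `2|A∩B|/(|A|+|B|)`; covariance distance
  `α(1 − Tr(c₁c₂)/(‖c₁‖‖c₂‖))` comparing region second moments (cap
  `α = 10`); symmetric Hausdorff distance; and the normalized symmetric
  contour distance `NSCD = (S(A₁,A₂)+S(A₂,A₁))/(|∂A₁|+|∂A₂|)`, all
  contour distances in world mm between internal contours.
* **Pipeline harnesses**: automatic segmentation of a new subject,
  iterative propagate→fuse→refine rounds with versioned layers,
  leave-one-out cross-validation, unbiased group-wise template
  construction and probabilistic (subject-fraction) label maps.
* **A seeded synthetic phantom cohort** — midline-symmetric nested
  parcellation, random smooth diffeomorphisms, rigid pose jitter,
  multi-modal intensities with noise and bias fields, and simulated
  raters with known sensitivity/specificity — so the whole pipeline is
  testable without scanner data.

## Worked example

Simulate five raters of known reliability on a phantom parcellation,
recover their performance with STAPLE, and score the fused result:

```r
library(rabatlas)

tax <- load_taxonomy("neonatal_rabbit")
tax
#> taxonomy 'neonatal_rabbit': 89 regions (76 paired, 13 median)

cfg  <- phantom_config(n_subjects = 4, seed = 17)
base <- make_base_phantom(cfg)
raters <- simulate_raters(base$segmentation, sensitivity = 0.9,
                          specificity = 0.95, n_raters = 5, seed = 11)
fit <- staple(propagated_stack(raters))
fit
#> staple_fit: 5 atlases, 16 labels, 8 EM iterations (converged)
fit$performance[[1]]
#> rater_performance: mean sensitivity 0.901, mean specificity 0.995

per_label_report(fit$fused, base$segmentation,
                 macro_map = phantom_macro_map(base$taxonomy))
#>   label_id   label_name  dice  covdist hausdorff     nscd
#> 1        1 Wedge pair 1 0.988 3.15e-02    10.024 0.112034
#> 2        2 Wedge pair 2 0.999 1.16e-05     0.894 0.000950
#> 3        3 Wedge pair 3 1.000 3.03e-06     0.400 0.000202
#> ...
```

The recovered mean sensitivity (0.901) matches the simulated 0.90, and
the fused parcellation agrees with the hidden truth at Dice ≥ 0.99 in
every macro-region; `covdist` is bounded by 10, and `hausdorff`/`nscd`
are millimetres between region contours.

Automatic segmentation of a new subject from a multi-atlas:

```r
pop <- make_population(base, cfg)                # 4 synthetic subjects
target <- pop$subjects[[1]]
atlas  <- multi_atlas(pop$subjects[-1], pop$taxonomy)
res <- segment_new_subject(target, atlas, pipeline_config())
res$segmentation                                 # fused label volume
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/rba` (subcommands `phantom`, `evaluate`, `fuse`, `reorient`,
`flipseg`).

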