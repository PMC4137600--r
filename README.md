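# mpsl

Automatic, contour-free segmentation of a gross target volume (GTV)
across the breathing phases of a 4D CT series, with motion and overlap
quantification and a synthetic 4D chest phantom for validation.

Planning lung radiotherapy on 4DCT requires the GTV on all ~10 breathing
phases. Manual contouring is slow and observer-dependent; deformable
registration automates the propagation but still needs a manual contour
on one phase. This package implements morphological processing and
successive localization (MPSL), which needs no prior contour: it
segments each phase from intensity and size priors alone and tracks the
target's center of geometry (COG) across phases.

## Method

With $A$ a voxel set and $B$ a structuring element (offset set
containing the origin):

$$A \oplus B = \{c \mid c = a + b,\ a \in A,\ b \in B\}, \qquad
A \ominus B = \{x \mid x + b \in A\ \forall b \in B\}$$

Per phase the pipeline is: **(1)** binary mask of voxels inside either of
two HU ranges (tumor, surrounding tissue) → **(2)** erosion $\ominus B$
to disconnect the tumor from same-intensity structures → **(3)**
union-find connected-component labeling with per-region volumes →
**(4)** a `[min, max]` tumor-volume window filter → **(5)** candidate
selection → **(6)** dilation $\oplus B$ with the same element →
**(7)** intersection with the stage-1 mask, restoring the target without
annexing background. Across phases, candidate selection is restricted to
the previous phase's bounding box expanded by a localization margin. The
segmented masks yield the COG/volume trajectory; Dice, sensitivity and
PPV quantify overlap against ground truth. See the methods vignette
(`vignettes/mpsl-methods.Rmd`) for the full account.

## Worked example

Generate the moving-sphere phantom (6-cm water-HU sphere in a lung-HU
cavity, 10 phases, 10 mm sinusoidal z-motion, 20 HU noise), segment all
phases, and compare against the generator's ground truth:

```r
library(mpsl)

ph  <- generate_phantom(phantom_spec(rng_seed = 1))
res <- segment_series(ph$series, mpsl_config())
res[[1]]
#> <mpsl_result> phase 0%, gtv 11208 voxels (112.08 cc); stages: mask 118752
#>   -> eroded 57968 -> 2 region(s), 1 survivor(s) -> dilated 11208 -> gtv 11208

traj <- compute_trajectory(res)
head(as.data.frame(traj), 3)
#>   phase cog_x_mm cog_y_mm cog_z_mm volume_cc
#> 1     0       63       63    78.75     112.1
#> 2    10       63       63    76.78     113.0
#> 3    20       63       63    71.78     113.0

te <- trajectory_error(traj, ph$truth_trajectory)
100 * max(te$rel_vol_err)                 # max phase volume error, %
#> [1] 0.85
100 * max(te$rel_disp_err, na.rm = TRUE)  # max COG-displacement error, %
#> [1] 0.90

overlap_metrics(ph$truth_masks[[1]], res[[1]]$gtv_mask)
#> <overlap_metrics> dice 0.996, sensitivity 0.992, ppv 1.000
#>   (|truth| 11304, |test| 11208, |intersect| 11208)
```

The diagnostics line reads as the pipeline's stage counts: 118,752
voxels pass the intensity ranges (tumor **and** body shell — they
overlap in HU, which is the hard part), erosion disconnects them into 2
regions, the volume window keeps one (the tumor), and dilation restores
it to 112 cc against a 113 cc ground truth. The recovered per-phase
volumes and COG displacements stay within 1% of truth, and the Dice
overlap is 0.996.

The same workflows are scriptable from a shell via the thin launcher in
`inst/cli/`:

```sh
Rscript inst/cli/mpsl.R phantom  --spec baseline --seed 1 --out ph/
Rscript inst/cli/mpsl.R segment  --input ph/ --out seg/
Rscript inst/cli/mpsl.R evaluate --truth ph/ --test seg/ \
    --truth-traj ph/truth_trajectory.csv --test-traj seg/trajectory.csv --out eval/
```

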