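# meniscusmotion

Quantifies in-vivo motion of the medial (MM) and lateral (LM) meniscus
between knee positions — e.g. maximal internal vs external tibial rotation
under load — from 3D MR volumes and their segmentation masks.

The menisci glide on the tibial plateau by several millimetres as the knee
rotates, and the direction and magnitude of that gliding is a candidate
marker for meniscal pathology (ramp lesions, posterior-horn instability).
Measuring it requires more than subtracting mask centroids: the whole knee
also moves between scans.  This package implements the full measurement
chain:

1. **Tibia-anchored rigid alignment** — 6-DOF transform minimising
   sum-of-squared-differences restricted to the tibia mask, so all
   subsequent motion is relative to the tibia:
   `phi* = argmin sum_{x in tibia} (T(x) - M(phi(x)))^2 dV`.
2. **Deformable registration of the menisci** — a dense displacement field
   `u` (mm, template grid) minimising
   `J[u] = SSD(T, M, u) + alpha * 1/2 sum_l ||Lap u_l||^2 + beta * 1/2
   sum_{x in T_mask} D_mov(x + u(x))^2`,
   i.e. mask-indicator SSD, curvature (squared-Laplacian) regularisation,
   and a distance-transform shape penalty that registers the meniscus
   faces even when the masks share no initial overlap.  Solved by a
   matrix-free multilevel Gauss-Newton method (preconditioned CG on the
   normal equations, Armijo line search; deterministic).
3. **Segment analysis** — PCA of the combined meniscus voxel cloud yields
   the anatomical medio-lateral (positive = lateral) and
   anterior-posterior (positive = posterior) axes; each meniscus is cut
   into anterior/intermediate/posterior horn at thirds of its arc length;
   per segment the mean displacement vector is reported as
   `(Avg, ML, AP)` in mm.
4. **Cohort statistics** — mean ± SD tables per condition, meniscus,
   segment and measure, plus paired two-sided Wilcoxon signed-rank tests
   (exact by rank-convolution up to n = 25 without ties, normal
   approximation with continuity and tie correction beyond), with no
   multiplicity adjustment.

Because real cohort images are rarely shareable, the package also ships a
**synthetic knee phantom generator** (`make_phantom()`, `apply_motion()`,
`simulate_cohort()`) producing template and moved volumes/masks with
analytically known ground-truth motion, so the entire pipeline can be
validated end-to-end on any machine.

## Worked example

Simulate a small phantom cohort (two knee positions per subject relative
to a reference scan, meniscal translations drawn around the
internal/external-rotation pattern), run the pipeline, and read the
cohort table:

```r
library(meniscusmotion)

sim <- simulate_cohort(cohort_spec(n_subjects = 4, seed = 42),
                       out_dir = "cohort")
cfg <- run_config("cohort", output_root = "cohort/out")
res <- run_cohort(cfg)
print(res)
```

```
<cohort_result> 4 subjects, 48 comparisons
 condition meniscus segment measure       mean        sd n
  external       LM   whole     avg  5.6740389 1.5823834 4
  external       LM   whole      ml -0.2895734 0.3631268 4
  external       LM   whole      ap -5.6056675 1.6419723 4
  external       MM   whole     avg  6.6698967 2.2849843 4
  external       MM   whole      ml  2.1590556 0.2904005 4
  external       MM   whole      ap  6.2468702 2.3625957 4
  internal       LM   whole     avg  4.3647120 0.6137136 4
  internal       LM   whole      ml -1.4329025 0.6124394 4
  internal       LM   whole      ap  4.0315180 0.6901975 4
  internal       MM   whole     avg  2.2779007 1.1380188 4
  internal       MM   whole      ml -0.3842838 0.3764870 4
  internal       MM   whole      ap -2.1093827 1.0818694 4
```

Reading the `whole`-meniscus rows: signs follow the anatomical convention
(positive ML = lateral, positive AP = posterior).  Under internal rotation
the LM of this simulated cohort moves ~4.0 mm posteriorly and slightly
medially while the MM moves ~2.1 mm anteriorly; under external rotation
the roles reverse (LM ~5.6 mm anterior, MM ~6.2 mm posterior) — the
opposite-direction pattern the generator encodes.  (Note the ML column is
reported in each knee's own left/right-corrected frame, and `Avg` is the
norm of the mean vector, so it need not equal `sqrt(ML^2 + AP^2)` across
the cohort.)  Per-subject motion CSVs, deformation fields (NIfTI),
segment-label images, objective traces, the summary/comparison tables and
a Markdown report with per-segment vector figures are written under
`cohort/out/`.

A command-line front end wrapping the same functions lives at
`inst/cli/meniscusmotion.R` (`simulate`, `run-subject`, `run-cohort`).

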