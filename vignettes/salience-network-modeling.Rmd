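---
title: "Methods: parcellation-based structural-functional network modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parcellation-based structural-functional network modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salnet)
```

# The modeling problem

`salnet` rebuilds, as a tested pipeline, a common workflow for deriving an
anatomically specific cortical network model from the published literature:

1. **Coordinate-based meta-analysis.** Published fMRI studies report
   activation peaks ("foci") as stereotaxic millimetre coordinates. An
   activation likelihood estimation (ALE) pools them: each focus becomes a
   3-D Gaussian probability kernel, each study's kernels combine by voxelwise
   maximum into a modeled-activation (MA) map, and the study maps combine by
   the complement-product union `ALE = 1 - prod(1 - MA_i)`. Cluster-level
   permutation inference separates convergent activation from noise.
2. **Parcel selection.** The significant ALE peaks are intersected with a
   volumetric cortical parcellation; a parcel joins the network model when
   more than 10% of its volume lies inside the ALE-derived mask.
3. **Structural connectivity.** Deterministic streamline tractography on
   per-subject fiber-orientation fields, with whole-brain random seeding and
   two-ROI endpoint filtering, counts tracts between every selected region
   pair per hemisphere.
4. **Edge statistics.** Per pair: the number of subjects showing the
   connection, the mean tract count over those subjects and over all N
   subjects, a laterality index `LI = (R - L)/(R + L)` of the all-subject
   means, an uncorrected two-sided Wilcoxon rank-sum p comparing hemispheres,
   a fiber-type taxonomy (frontal aslant tract between insular-opercular and
   middle-cingulate clusters, U-fibers within clusters, "Other" for pairs
   touching the dorsolateral prefrontal cluster), and a schematic filter
   dropping pairs averaging fewer than 10 tracts in both hemispheres.

The package ships verbatim transcriptions of the source tables it validates
against: a 35-study foci table and a 36-row connection-strength table
(`fixture_tables()`).

# Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `cluster_alpha` | 0.05 | cluster-level significance for ALE |
| `n_perm` | 1000 | relocation permutations |
| `voxel_p_threshold` | .001 | cluster-forming threshold |
| `kernel_fwhm` | per study | Gaussian FWHM; `NULL` derives it from the study's sample size via the empirical two-component uncertainty model (template 5.7 mm ED + subject 11.6 mm ED / sqrt(n)); tests fix it for deterministic oracles |
| `overlap_threshold` | 0.10 | parcel inclusion, strict (`fraction > threshold`) |
| `angular_threshold_deg` | 45 | tracker halt on direction change |
| `step_mm` | 1.5 | tracker step |
| `max_len_mm` / `min_len_mm` | 800 / 1 | streamline length window |
| `n_seeds` | 1e6 | whole-brain random seeds (full fidelity) |
| N (`n_subjects`) | 25 | cohort size |
| `min_edge_strength` | 10 | schematic edge filter (mean tracts) |

All tunables live in one `run_config()`; a root seed spawns per-stage seeds
so stages are individually reproducible, and stage outputs can be cached
content-addressed on disk (`cache_dir`).

# Numerical and design choices

**Monte-Carlo null instead of an analytic histogram null.** The original
meta-analysis software derives its null analytically by convolving kernel
histograms. We instead relocate every focus uniformly at random over mask
voxels and recompute the full ALE map per permutation. This is simpler,
directly testable by enumeration on tiny masks, and makes the observed map
exchangeable with the permutations.

**Pooled cluster-forming threshold.** Under the relocation null each
permutation covers the mask sparsely, so thresholding each voxel by its own
permutation rank marks every permutation's kernel cores suprathreshold and
destroys the contrast between convergent signal and noise (planted two-blob
signal came out cluster-nonsignificant when we tried it). The cluster-forming
cutoff is therefore the `1 - voxel_p` quantile of the *pooled* null histogram
of ALE values over all mask voxels and permutations (zeros included) - the
Monte-Carlo counterpart of the analytic histogram null. The cutoff is a
symmetric function of the permutations, so observed and permuted maps are
thresholded identically and the max-cluster-size test stays calibrated; the
acceptance suite verifies type-I error of 0.05 over 100 null runs. Per-voxel
uncorrected p-values (`voxel_null()`) still use the plus-one estimator
`p = (1 + #{perm >= obs}) / (n_perm + 1)` exactly.

**Kernel truncation.** Gaussian stamps are truncated where the omitted 1-D
tail mass falls below 1e-10 of total mass (about 6.6 sigma); the unit test
asserts the bound. Foci snap to the nearest voxel center before stamping.

**Talairach conversion.** Published Talairach peaks are mapped to MNI with
the inverse of the Lancaster `icbm_spm2tal` affine, stored as explicit
constants; the tests freeze independently computed values of the inverse.

**Tracker.** Direction lookup is nearest-voxel peak selection with sign
disambiguation (maximize |dot| with the incoming direction); trilinear
interpolation is deliberately omitted so a 0.01 mm fine-step integrator with
the same lookup is an exact oracle. Propagation is bidirectional from each
seed with a shared length budget; the 1 mm minimum length is kept verbatim
even though it is nearly vacuous at a 1.5 mm step. The anisotropy threshold
of the emulated tool (randomized there) is replaced by an explicit mask -
a randomized threshold is not reproducible.

**Rank-sum test.** Exact enumeration of rank splits for combined n <= 12,
otherwise the normal approximation with tie and continuity corrections;
uncorrected for multiplicity, per the source analysis.

**Rounding.** Report tables round half-up to 2 decimals, matching the
formatting of the source tables; undefined laterality (both hemispheres
zero) renders as "-".

# The synthetic world

The generators produce every input the pipeline consumes, with known ground
truth:

- `gen_foci()` emulates the structure of the published study table: a few
  activation loci shared across studies, per-focus Gaussian jitter (default
  4 mm, a typical between-study spatial scatter), optional uniform background
  foci, and sample sizes uniform over 14-255 (the printed table's range).
- `gen_parcellation()` voxelizes spherical parcels at named left-hemisphere
  centers and mirrors them across the midline. `salience_regions()` provides
  the 9-region table (insular-opercular AVI/MI/FOP4/FOP5, middle-cingulate
  a24pr/a32pr/p32pr/SCEF, dorsolateral prefrontal 46) with representative
  MNI centers.
- `gen_cohort()` plants straight, arc, or U-shaped (half-circle) fiber
  bundles between parcels as tubes of unit tangent vectors, present per
  subject and hemisphere with a configurable probability. Count asymmetry is
  tube *multiplicity*: `count_scale = c(L = 1, R = 3)` rasterizes three
  congruent parallel copies on the right. Because every copy shares radius
  and curvature (hence streamline retention) and uniform seeding makes
  expected counts proportional to swept volume, the expected count ratio
  equals the multiplicity ratio exactly. (Scaling the tube radius instead
  breaks this: retention varies with radius - we measured a 4:1 count ratio
  for a sqrt(3)-scaled radius targeting 3:1 - which is why multiplicity was
  chosen.)

What the synthetic world does **not** emulate: realistic diffusion signal or
reconstruction noise, crossing-fiber geometry beyond 3 peaks per voxel,
registration error, grey/white contrast, or the actual multimodal-atlas
parcel shapes. A green end-to-end test therefore establishes that the
pipeline's logic - seeding, propagation, endpoint filtering, counting,
statistics - is correct on fields whose ground truth is known; it does not
establish fidelity to any in-vivo dataset.

# Reduced test scales

The stochastic acceptance checks run at reduced scale so the suite stays
inside a CI budget: ALE nulls at 200 permutations (with the paper-default
.001 cluster-forming threshold, attainable because the pooled null has
`n_mask x n_perm` values), and the end-to-end cohort at 6 subjects with
4e4 seeds per subject instead of 25 subjects at 1e6. Tract counts scale
linearly with seed count, so ratios, laterality indices, and edge
classification are unaffected; only the Monte-Carlo noise floor changes.
Null-foci calibration runs use a deliberately small table (6 studies x 2
background foci) so each permutation's suprathreshold set concentrates in a
few kernel cores and the integer max-cluster-size statistic has a
quasi-continuous null; richer tables would spread the same suprathreshold
mass over many tiny cores and make the size distribution degenerate at small
integers.

# Known limitations

- The per-voxel Monte-Carlo p can exceed the nominal cluster-forming level
  at sparsely covered voxels; cluster membership is governed by the pooled
  cutoff (see above), and the two agree as coverage grows.
- Overlap scoring resamples the ALE mask nearest-neighbour onto the
  parcellation grid; sub-voxel partial overlap is not modeled.
- The 10% inclusion rule is applied per hemisphere (the source is silent on
  this); each hemisphere's parcel is scored and reported separately.
- Whether the schematic strength labels pool hemispheres is unstated in the
  source; reports carry both hemispheres.
- Tube multiplicity supports integer count ratios only; non-integer density
  ratios would need a different mechanism and would reintroduce the
  retention confound.
- Configs are JSON (no YAML parser in the supported dependency set);
  orientation fields and label volumes use a minimal built-in NIfTI-1
  reader/writer for the same reason.
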