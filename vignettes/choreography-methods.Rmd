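---
title: "Methods: windowed choreography statistics and the population simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed choreography statistics and the population simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choreoscope)
```

# Scope and model

`choreoscope` reconstructs the segregation choreography of chromosomal
loci from snapshot images of steadily growing bacteria.  The input is a
per-cell table: cell length and, per fluorescent channel, the axial
positions of detected foci.  The package takes over *after* image
segmentation and spot detection; it never touches images.

Two assumptions underpin everything:

1. **Length is a cell-cycle clock.**  In steady-state exponential
   growth, cell length increases monotonically through the cycle, so
   binning cells by length (0.1 µm intervals) and sliding a 0.3 µm
   window along the length axis orders cells by cycle progression.
2. **One axial dimension suffices.**  Focus positions are straight-line
   coordinates along the long axis, not curved-midline arclengths.  The
   choreography statistics are all ratios against the measured length,
   so the 1-D reduction is internally consistent; a curved-midline
   pipeline would feed the same tables with slightly different numbers.

# The windowed statistics

For window center $c$ (a multiple of the 0.1 µm interval width), cells
with binning length in $[c - 0.15, c + 0.15)$ are pooled.  Both bounds
are fixed conventions: intervals are half-open and labelled by their
lower edge, and the window is centred (a trailing window would shift
every curve by a constant without changing any ordering).  Windows with
fewer than `min_cells = 10` scoring cells are masked; 10 keeps the
window percentiles stable while retaining the sparse longest-cell
intervals at n = 800 cells per strain.

The duplication frequency is $f = n_2 / (n_1 + n_2)$; cells with zero
or more than two foci in a channel are retained in the dataset but do
not score in that channel (the analysis contrasts the one- and
two-focus states only).  The dominant cell type of a window is
two-focus when $f \ge 0.5$, mirroring the $\ge 50\%$ anchoring
convention.  Percentiles are interpolating type-7 quantiles — R's
default, fixed so that an independent implementation can reproduce the
numbers bit for bit.  Sisters are ordered within each cell before
rank-wise percentiles, so the lower-sister median can never exceed the
upper-sister median.

`bin_index()` computes `floor(length / width + 1e-9)`; the epsilon
absorbs decimal-representation error (4.2/0.1 is not exactly 42 in
floating point) and is far below any physical length difference.

# Axis orientation

Pole preference is classified on dividing cells, defined as cells at or
above the 90th percentile of binning length — the analysis-side proxy
for "the last length interval".  Per focus, the septum distance
$|x - L/2|$ and pole distance $\min(x, L - x)$ are compared; a cell
votes new-pole when its mean septum distance is strictly smaller, with
exact ties voting old-pole (a fixed, documented tie-break at the
quarter position).  Preferences with vote margin below 0.1 are
ambiguous and excluded from scoring.

Cells are then oriented by
$S = \sum_c w_c\, s_c\, (\bar{x}_c/L - 1/2)$ with channel weight
$w_c$ = preference margin and sign $s_c = \pm 1$.  $|S|$ below
`ambiguity_tolerance = 0.1` (relative units, after weight
normalisation) marks the cell ambiguous; $S = 0$ is never flipped.
The tolerance trades coverage against errors: fully segregated cells
have mirror-symmetric focus configurations (the affine sister mapping
is symmetric about midcell) and genuinely carry no orientation
information, so forcing a call on them would inject coin-flip errors
into the trajectories.

`refine_orientation()` rescues ambiguous cells against length-binned
profile templates built from the already-oriented cells, and iterates
to a fixed point.  Two guards matter:

* only *informative* templates are used — a dominant-one window whose
  median sits within `asym_min = 0.1` of midcell, or a dominant-two
  window whose sister pair is mirror-symmetric within the same bound,
  cannot distinguish the two orientations and would only transmit
  sampling noise;
* a cell is assigned only when the summed absolute deviation of its
  foci from the template medians differs between the two orientations
  by more than `margin = 0.15` relative units (about half a micron in
  a dividing cell).  Both defaults were calibrated on labelled
  simulations: with them the inferred orientation matches ground truth
  for 96–99% of non-ambiguous cells while leaving under 15% of cells
  ambiguous; with a permissive margin the rescue pass decides
  borderline cells at little better than chance.

Duplication frequencies, distances and polarity never consume the
orientation, so orientation ambiguity only thins the position
trajectories.

# Realignment

Two strains' length axes are aligned by a shared anchor: the first
interval where a common channel's duplication frequency reaches a
threshold (0.5, or 0.25 for the chromosome-II terminus), or the first
interval where a dominant single-focus channel's median enters the
midcell band $0.5 \pm 0.1$ and stays for two consecutive intervals.
The band width and persistence requirement make the "arrival at
midcell" anchor well defined on noisy medians.  Offsets are quantized
to the 0.1 µm interval width (whole-interval alignment), and apply only
to the binning axis: relative positions remain ratios against the
measured length, because the shift is a population-comparison device,
not a claim about any individual cell's geometry.  An anchor that is
never reached raises an error; the package deliberately refuses to
guess an offset in that case.

# The population simulator

The generator emulates the study conditions the analysis assumes:

* **Ages** from the steady-state density
  $f(a) = (2\ln 2/\tau)\,2^{-a/\tau}$, $\tau = 55$ min, by CDF
  inversion.
* **Growth** exponential from Gaussian birth lengths
  (mean 2.05 µm, sd 0.07 µm), so newborns sit near the 2 µm interval,
  dividing cells near 4.2 µm, and the bulk of the population spans
  1.9–4.3 µm.
* **Replication**: B/C/D = 11/32/12 min.  Fork speed is set so the
  longest chromosome-I replichore (1480.5 kb) completes in exactly the
  C period (≈ 46.3 kb/min); chromosome II fires late enough that both
  chromosomes terminate together, which reproduces the delayed
  chromosome-II origin firing with a single shared fork speed.  A
  locus's replication age is the earliest fork arrival over active
  origins along the circular map, so an ectopic origin advances its
  neighbourhood automatically.
* **Cohesion**: sister foci separate at replication age plus an
  exponential delay.  Origin-proximal and arm loci use a 5 min mean —
  short enough that duplication curves rise from 10% to above 80%
  within ≲ 0.6 µm of elongation.  Terminus-macrodomain loci are instead
  calibrated by the fraction of dividing cells that should show two
  foci (0.50 / 0.40 / 0.10 for the two macrodomain flanks and the
  chromosome-I terminus; 0.25 for the chromosome-II terminus), with the
  reference age at the middle of the D period, when septation is
  visible.
* **Positions**: pre-duplication homes interpolate linearly in genomic
  path-fraction from the *ori* home (0.8 chromosome I, 0.55
  chromosome II) to the *ter* home (0.1 / 0.28).  Terminus-region loci
  follow a midcell-early program: they ramp to midcell over 10 min
  (≈ 4 length intervals), completing late in the cycle (ages 41–47
  depending on the locus), before their own duplication.  After
  duplication, sisters glide from the split position to the affine
  homes $h_{old} = \frac12 + h/2$, $h_{new} = \frac12 - h/2$ over
  `seg_transition_um = 0.1` µm of elongation — the elongation scale of
  one length interval, consistent with segregation completing "within
  the next interval"; the value is configurable because snapshots bound
  it only from above.  Gaussian localisation noise (sd 0.05 relative
  units; 0.08 for *parS*-deletion scenarios, whose positioning is
  visibly looser) is added and positions are clamped to [0.02, 0.98] —
  detected spots never sit exactly on a pole.
* **Storage axis**: each cell's stored axis is flipped with probability
  exactly 0.5, and the flip is recorded only in the ground truth, so
  the pipeline must re-infer every orientation.

The affine sister mapping is the unique linear choice that makes the
pattern self-similar across divisions — mapping a sister home into the
corresponding daughter's frame returns the mother's pre-duplication
home exactly — so a snapshot mixture of generations is internally
consistent without extra parameters.

## Perturbation presets

* `parS_displaced(p_kb)`: the polar anchor moves to `p_kb`; homes of
  non-terminus chromosome-I loci are recomputed from their circular
  genomic distance to the displaced anchor through the wild-type
  distance→home relation.  The terminus program is pinned unchanged,
  matching its anchor-independent behaviour.
* `delta_parS`: chromosome-I homes shrink towards midcell by the factor
  that maps the ori home 0.8 to 0.7, and chromosome-I noise inflates to
  0.08.
* `delta_parS_ectopic_ori`: adds an origin at 651 kb; chromosome-I
  homes become a decreasing function of replication age (earliest
  replicated ≈ 0.65, latest 0.5), the ori region keeps a small
  (+0.03) residual polar bias, and its sisters use asymmetric homes
  (0.88, 0.28): one copy stays relatively polar while the other takes a
  more central position.  The paper-level observation behind this
  preset is qualitative, so the asymmetry pair is a modelling choice;
  the preset is used for ordinal comparisons (polarity erosion), not
  for quantitative recovery.

## What the generator does and does not emulate

It reproduces the statistical structure the analysis relies on:
steady-state age/length mixing, replication-ordered duplication with
variable cohesion, stereotyped homes with noise, unknown pole identity,
and between-strain length offsets.  It does **not** model 2-D/3-D cell
geometry, spot-detection failures (missed or spurious foci, merged
sister spots at small separations), multifork replication, lineage
correlations, or cell-to-cell growth-rate variability.  Passing tests
therefore demonstrate that the pipeline's inference is correct when its
assumptions hold, not that those assumptions hold for any particular
microscope or strain.

# Numerical choices

* Window centers are exact integer multiples of the interval width;
  membership tests use plain half-open comparisons, so an independent
  per-window recomputation matches bit for bit.
* Simulated lengths and positions are stored on a dyadic grid of
  $2^{-20}$ µm (≈ 1 nm, the scale of localisation precision).  On this
  grid $L - x$ is exact in floating point, so reversing a stored axis
  is exactly invertible and the orientation-free statistics are
  bit-identical under flips; distances are computed as micrometre
  differences before normalisation for the same reason.
* One master seed drives a single RNG stream with a fixed draw order
  (ages, birth lengths, flips, then per-locus delays and noise), making
  a dataset a pure function of (scenario, n, seed).  Per-cell
  substreams were considered and dropped: they complicate vectorised
  generation and add nothing once the draw order is fixed.
* Tie-breaks are all fixed and documented: quarter-position votes go
  old-pole, zero orientation scores are never flipped, midcell foci
  belong to the lower half-cell, polarity ties within $0.01\,L$ land in
  a separate tie bucket, and equal duplication crossings are broken by
  genomic distance from *ori* and flagged.

# Problem sizes

The test suite and the acceptance script use n = 800 cells per strain
for population-level checks (matching the per-locus cell counts the
windowed statistics are designed for), 500-cell datasets for
brute-force oracle comparisons, and $10^5$ ages for the steady-state
distribution test.  The scenario-ordering checks average three seeds at
n = 800.

# Known limitations

* Orientation of fully segregated cells is information-theoretically
  impossible in this framework; such cells are reported ambiguous
  (≈ 7–13% of a wild-type population) rather than guessed.
* The realignment anchor fails loudly when a channel never reaches its
  threshold; no fallback anchor is attempted.
* `parS_displaced` re-anchoring applies the wild-type distance→home
  relation unchanged; subtler effects of anchor displacement (e.g. on
  cohesion) are not modelled.
* Focus-count classes above two ("many") are excluded from statistics
  rather than deconvolved; under multifork growth conditions the
  analysis would need a different state model.
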