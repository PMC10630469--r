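---
title: "Variable-window DIA lipidomics with lipidia: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable-window DIA lipidomics with lipidia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidia)
```

# The workflow

`lipidia` implements a quadrupole-resolved data-independent-acquisition
(DIA) lipidomics workflow in five stages:

1. **Library building** — iterative data-dependent (DDA) injections of a
   pooled extract are merged into consensus MS/MS spectra, matched against
   reference libraries, and serialized as an in-house spectral library with
   measured retention times.
2. **Window design** — MS1 features detected on the DDA map drive a
   variable-width isolation-window scheme that equalizes precursor density
   across the mass range.
3. **Targeted extraction** — for every library entry, the MS1 precursor
   trace and one MS2 trace per library fragment are extracted from the
   correct isolation window, integrated at the library retention time, and
   missing cells optionally filled by forced integration.
4. **Quality control** — per-channel relative standard deviation (RSD)
   over pooled-QC injections, fragment-to-precursor Pearson correlation,
   and dilution-series linearity.
5. **Differential abundance** — rule-based channel filtering, a
   representative readout per lipid, Welch tests with Benjamini–Hochberg
   control, and median-centred log2 matrices for display.

A synthetic-run simulator generates every input the pipeline consumes, so
all stages are validated against known ground truth.

# Window design

DIA instruments fragment everything inside a scheduled isolation window,
so wide windows in precursor-dense regions produce chimeric spectra while
wide windows in sparse regions waste nothing. The calculator therefore
(i) computes, for each MS1 feature, a **density** — the number of features
within ±`density_radius` of its m/z — and (ii) partitions the acquisition
range into `n_windows` contiguous windows whose summed density is as equal
as possible, subject to instrument limits on window width.

Cut points are restricted to midpoints between consecutive feature m/z
values, so no precursor sits exactly on a boundary unless duplicated m/z
forces it; a feature exactly on a cut belongs to the lower window, a rule
used identically in density accounting and in channel assignment. Among
all feasible cut placements the implementation finds, by dynamic
programming, the one minimizing the variance of the window density sums
(with the total density and window count fixed, this equals minimizing the
sum of squared window sums). We chose the exact optimum over a greedy
sweep because it is just as fast at realistic sizes (a fraction of a
second for 1,000 features and 20 windows), it is reproducible by an
independent exhaustive search in the test suite, and it makes the
"approximately equal density" contract sharp. A greedy cumulative-density
sweep with feasibility clamping remains as the fallback when the midpoint
grid admits no feasible placement (very few or heavily clustered
features); an empty feature list falls back to uniform tiling.

After partitioning, every window is extended by `extension` (default
0.5 Th) on both edges, giving adjacent extended windows a 1 Th overlap so
precursors near a boundary are not lost to quadrupole edge effects. A
precursor in the overlap is *acquired* in two windows but *quantified*
from exactly one — the window whose core contains it — to avoid double
counting.

Tunable parameters, with defaults matching the plasma-study
configuration:

| parameter | default | unit | meaning |
|---|---|---|---|
| `mass_low`, `mass_high` | 300, 1000 | Th | precursor acquisition range |
| `n_windows` | 20 | — | number of isolation windows |
| `min_width`, `max_width` | 10, 100 | Th | instrument limits on core width |
| `extension` | 0.5 | Th | per-edge extension (1 Th overlap) |
| `density_radius` | 2.5 | Th | "nearby" radius for the density count |

`density_radius` has no canonical value; 2.5 Th spans an isotope envelope
plus near-isobars, and the partition is insensitive to it at the 10–100 Th
window scale. Density is computed over m/z only, ignoring retention time:
the quadrupole schedule is RT-independent, so every feature loads its
window somewhere in the gradient.

# Spectral library construction

Consensus spectra are built by grouping MS2 scans across iterative DDA
injections by precursor m/z (±`ms1to1`, default 0.005 Th) and retention
time (±0.2 min), merging peaks at `ms2to1` (0.01 Th) resolution with the
**median** intensity across injections — the median resists the
systematic underestimation that occurs when DDA triggers on a peak flank
rather than its apex.

Matching uses a greedy closest-first one-to-one peak pairing within a
fixed 0.01 Da tolerance, and scores the pairing with the **cosine
similarity of square-root intensities** over the union of paired and
unpaired peaks. The score threshold (0.5) and minimum matched-peak count
(1) are workflow settings; the functional form of the score is our choice
from the dot-product family that dominates spectral matching, and it is
isolated behind `match_score()` so it can be swapped.

Candidates are gated on precursor m/z and — when the reference carries a
retention time — on an RT shift window. The RT-shift unit is not
standardized across tools; `match_params()` defaults to seconds (10 for
DDA library building, 20 for DIA extraction) and exposes
`rt_shift_units = "min"` for the alternative reading.

Exact score ties resolve to the **last** entry in the reference list.
That rule reproduces the behaviour of the established annotation software
this workflow is modelled on (it is why a lipid can be reported by the
last-listed molecular constituent of its sum composition); passing
`tie = "first"` gives the conventional alternative. Because molecular
constituents are not distinguishable from window-multiplexed MS2 alone,
all readouts are reported at **sum composition** level (`"SM 32:1"`
rather than `"SM 30:1;2O/2:0"`), computed by a shorthand parser that
handles legacy sphingoid prefixes (`d`/`t`/`m` mapping to 2/3/1
hydroxyls), ether markers (`-P`/`-O`), hydroxyl counts (`;xO`) and
stable-isotope labels (`-d9`), and is idempotent on already-summed names.
Only `[M+H]+` / `[M+NH4]+` adducts are admitted in positive mode and
`[M−H]−` / `[M+HCOO]−` in negative mode; duplicate identifications of one
(sum composition, adduct, polarity) keep the highest-scoring entry, ties
resolved by earliest retention time.

# Targeted extraction

DIA severs the link between precursor and product spectra. The extractor
restores it through the library: the MS1 trace is extracted at the
precursor ±`ms1to1`; the precursor is assigned to its core window; each
library fragment is extracted in that window at ±`ms2to1`. The MS1 peak
nearest the library RT within ±`rt_shift` anchors the record, and
fragment peaks must **co-elute** with that anchor within ±`rt_shift`/2 —
picking fragment peaks independently would let a co-isolated isobar
masquerade as the target. When no MS1 peak qualifies, fragments fall back
to the library RT with the full gate.

Missing channels are *null*, not zero: absence of a detectable peak is
informative and is kept distinct from a measured low area. The fill step
re-integrates null channels by a forced trapezoid over ±`rt_shift` around
the anchor, flagging them; the two output tables (`quant_all.tsv` with
detected cells only, `quant_fill_all.tsv` with filled cells added) share
bit-identical detected cells. No saturation correction is applied at
extraction time; saturation is handled downstream by capping the
linearity fit (below).

Peak detection operates on a 5-point running mean of the trace (apexes
and boundaries), while heights and trapezoidal areas come from the raw,
baseline-unsubtracted trace. Boundary walks track their running minimum
and stop when the smoothed trace rises more than 10% (or 0.5% of the apex
height) above it — multiplicative detector noise otherwise fragments one
elution peak into many. `min_points = 3` is a detection floor, not a
quality filter; the classic ten-points-across-a-peak rule is an
acquisition design target and is recorded per channel (`n_points`) rather
than enforced.

MS1 feature detection for window design uses greedy mass traces (most
intense unclaimed peak seeds a trace, nearest peak within ±tol per scan
joins it) with no deisotoping — deliberately, since isotopes load the
quadrupole and should count toward window density. The upstream tool's
feature detector is unspecified, so this component is a documented
stand-in with the same interface.

# Statistics

* **RSD** uses the sample (n−1) standard deviation, computed on
  *detected* QC values only, so forced fill cannot flatter
  reproducibility; channels with fewer than two detected QC values are
  non-quantifiable. Two median-RSD conventions coexist deliberately: the
  median over channels passing the 30% gate (dilution-series reporting)
  and the overall median (two-group-study reporting); both are emitted,
  labelled.
* **Retention filter**: a lipid enters differential testing iff its MS1
  channel and at least one fragment have QC RSD strictly below 30% *and*
  such a fragment correlates with MS1 at Pearson R² > 0.8 over all study
  samples (filled values, since fill precedes this step in the workflow
  order). Loosening any threshold can only grow the retained set.
* **Representative readout**: among the passing channels of a lipid —
  both polarities merged on the sum-composition string — the lowest QC
  RSD wins.
* **Differential abundance**: fold change is the ratio of arithmetic
  group means of areas (matching the "fold change > 2" convention on raw
  abundances), the test a two-sided Welch t on log2 areas (robust to
  unequal variances at n = 5; Mann–Whitney would need larger groups to
  reach p < 0.05 at all), and multiplicity is controlled by
  Benjamini–Hochberg, reported as q-values. Significance requires both
  |log2 FC| > log2(2) and q < 0.05. A degenerate zero-variance group gets
  a 1e-12 variance floor and a flag.
* **Linearity** regresses mean area on injection volume only up to
  `linearity_max_volume` (4 µL), because detector saturation above that
  volume would otherwise bias the fit; the 8 µL point is reported but not
  fitted.
* **Median centring** subtracts each lipid's median log2 area, so row
  medians are exactly zero for any sample count (centring raw ratios on
  the area median leaves a nonzero row median when the sample count is
  even).

# The simulator

The simulator emulates a reversed-phase gradient on a Q-TOF:

* **Catalog**: species drawn from a class mixture (TG > PC > SM > LPC,
  plus Cer/PE/DG/PI) whose class-specific precursor regions make the m/z
  density non-uniform — the regime variable windows exist for. Retention
  times are uniform on the gradient, abundances log-normal (σ = 1 in log
  space), and each species carries 1–10 product ions in 50–1000 m/z with
  yields summing to at most 1. Species are redrawn until no two collapse
  to the same sum composition, because the catalog stands for distinct
  quantifiable lipids at readout level. Elution peaks are Gaussian with
  σ = 0.04 min (≈0.16 min base width).
* **DIA runs**: cycles of one MS1 scan plus one MS2 scan per window at
  20/40 spectra/s; species contribute to every window whose *extended*
  bounds contain their precursor, so overlap-region species genuinely
  appear in two channels. Noise is multiplicative mean-one log-normal per
  species and scan; saturation, when enabled, is a smooth `tanh` ceiling
  so linearity degrades gradually rather than clipping.
* **DDA runs**: auto-MS/MS pacing at 4 spectra/s; per cycle the top ≤ 5
  eligible precursors above 200 counts trigger; a precursor selected
  twice (initial + one repeat) within 0.08 min is actively excluded, and
  an iterative exclusion list (±20 ppm, ±0.2 min) carried across
  injections makes repeat injections dig deeper into the abundance range.
  The "0.01%" clause attached to the 200-count threshold in vendor
  acquisition software is ambiguous; only the absolute count threshold is
  modelled.
* **Designs**: dilution series (0.25–8 µL as intensity scales),
  two-group studies with per-species fold changes and pooled-QC
  injections at the mean of the group abundances.

For statistics-only studies, `simulate_quant_table()` generates the
quantification table directly at the area level: each sample draws one
realized ion load per species — shared between the MS1 channel and all
fragments, with CV `noise_cv` — and each channel adds small independent
detector noise (`ms1_cv`, `ms2_cv`). The shared-load term is what makes
fragment and precursor readouts of the same lipid correlate, as they do
in real data; per-channel CV overrides (`ms2_cv_override`) plant noisy
fragment channels for filter testing. This area-level route exists
because the statistics chain needs many replicate studies (e.g. 20-seed
power estimates) that would be wasteful to render scan by scan; the
scan-level and area-level routes are cross-checked against each other on
small designs in the test suite.

**What the simulator does not model**: isotope envelopes, in-source
fragmentation, ion suppression and matrix effects, retention-time drift
between runs, chimeric backgrounds beyond window co-isolation, and
profile-mode peak shapes. Passing tests therefore demonstrate the
correctness of the algorithms under clean, known-truth conditions — not
performance on real instrument data, where annotation error and matrix
structure dominate.

# Problem sizes

Validation uses desk-scale designs chosen to keep peak sampling realistic
(≥20 scans per peak) while runs stay small: gradients of 1–4 min with
catalogs of 5–100 species and 2–8 windows for scan-level checks; the full
default geometry (15.8 min, 20 windows, 20/40 spectra/s) is exercised by
the window-design path, which is scan-count independent. The two-group
power study runs 200 lipids (50 changed 2.5-fold) × 16 samples × 20
seeds at the area level. These sizes are the package's validation
choices; all rates, widths, thresholds and design counts are the
workflow's standard values.

# Known limitations

* Profile-mode data are rejected rather than centroided; vendor raw files
  must be converted to centroided mzML externally.
* No RT alignment across runs: the library RT plus the RT-shift gate
  substitutes for it, which assumes a stable gradient.
* The greedy mass-trace feature detector claims peaks first-come
  first-served; a tie where two traces want one peak is resolved by claim
  order, not by re-optimization.
* The exact statistical test behind the original workflow's FDR gate is
  not published; Welch + BH is this package's documented choice, and
  p-values from other choices will differ.
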