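---
title: "Methods: Fourier statistics and traveling-wave analysis for phase-encoded fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Fourier statistics and traveling-wave analysis for phase-encoded fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasewave)
library(tibble)
```

## The model

A phase-encoded scan presents one task cycle — e.g. stimulus (0–5 s),
speech output (5–10 s), rest (10–16 s) — repeated $K = 16$ times at
TR = 1 s, giving $N = 256$ samples per unit (voxel or vertex). A unit
engaged by some stage of the task fluctuates at the task frequency
$\omega_s = K$ cycles per scan, and its Fourier phase at that bin encodes
*when* within the cycle it activates, up to the hemodynamic lag that is
common to all units.

`dft_spectrum()` applies
$X(\omega) = \sum_{t=0}^{N-1} x(t)\, e^{-j 2\pi \omega t/N}$ and keeps the
one-sided bins $0 \ldots N/2$. Significance of periodic activation is the
signal-to-noise F-ratio

$$F = \frac{|X(\omega_s)|^2/df_s}{\sum_{\omega_n}|X(\omega_n)|^2/df_n},
\qquad df_s = 2,\; df_n = 2\,|\{\omega_n\}|,$$

which under Gaussian noise follows $F(df_s, df_n)$: each retained Fourier
bin contributes two degrees of freedom (its real and imaginary parts), and
the task bin contributes the two in the numerator.

**Noise-bin selection.** The set $\{\omega_n\}$ is every one-sided bin
except (i) DC and Nyquist, which carry no phase information and one degree
of freedom respectively; (ii) drift bins 1–3, where scanner and
physiological drift concentrate; (iii) the task bin and its two immediate
neighbors, to guard against leakage; and (iv) task harmonics
$2\omega_s, 3\omega_s, \ldots$ below Nyquist, because a periodic but
non-sinusoidal response puts genuine signal there. For $(N, \omega_s) =
(256, 16)$ this leaves 115 bins and $df_n = 230$:

```{r partition}
part <- build_frequency_partition(256, 16)
glance(part)
```

Every exclusion is configurable (`drift_bins`, `exclude_task_neighbors`,
`exclude_harmonics`, `extra_exclude`) and recorded with a reason tag in
`part$excluded`; this particular reconstruction is one consistent choice
among several that yield the same count, and the partition object, not a
hidden default, travels with every downstream result.

**p-values and thresholds.** With $df_s = 2$ the upper-tail probability has
the closed form $p = (1 + 2F/df_n)^{-df_n/2}$; `f_to_p()` uses the F
distribution directly and the closed form serves as an independent check in
the tests. The three conventional display thresholds are

```{r thresholds}
round(critical_f(c(0.01, 0.001, 0.0001), 2, 230), 1)
```

i.e. F > 4.7, 7.1, 9.6 for uncorrected p < .01, .001, .0001. No
multiple-comparison correction is applied anywhere: these are display
thresholds for maps, matching standard practice in phase-encoded mapping,
and `f_thresholds()` ships them as named constants.

**Complex F-values and the delay convention.** Each unit's result is also
stored as the vector $\sqrt{F}(\cos\theta, \sin\theta)$ with
$\theta = \arg X(\omega_s) \in [0, 2\pi)$. Because averaging happens on
these vectors, incoherent phases cancel while coherent activation
survives. Under the $e^{-j\omega t}$ kernel, delaying a response rotates
$\theta$ negatively, so

$$\text{delay} = \frac{(-\theta) \bmod 2\pi}{2\pi}\times \text{period}.$$

The sign convention is fixed by simulation: two planted units whose onsets
differ by 5 s recover a delay difference of exactly +5 s (a circular-shift
DFT identity for integer-TR shifts). Absolute delays include the
hemodynamic lag (≈5–6 s here), so analyses interpret *differences* in
delay, never absolute values, as activation timing.

**Degenerate inputs.** A noiseless synthetic unit can have exactly (or to
rounding) zero noise power. Rather than erroring, `f_statistic()` flags
such units with $F = \infty$, $p = 0$ and a warning; their phases remain
valid, which keeps exact test fixtures usable. The degeneracy test is
relative (`noise_power <= amplitude^2 * 1e-20`) so that double-precision
leakage from a pure planted cosine is treated the same as an exact zero.

## Averaging maps across scans and subjects

`average_scans()` and `average_group()` compute per-unit arithmetic means
of the complex values — the same arithmetic, differing only in the required
space (group averaging demands a single common mesh, identified by a
content hash so silent mesh mismatches fail loudly). Averaging is done on
*unthresholded* values; thresholds are applied afterwards for display and
ROI work, preserving the order average-then-select. A unit missing from
some inputs contributes complex zero and the per-unit count of contributing
maps is recorded in `valid_n`; `weight = "valid"` switches to dividing by
that count instead of the number of maps. Equal weighting is the default
because it keeps averaging linear and the triangle-inequality bound
$|\bar F| \le \max_k |f_k|$ exact; both conventions are exposed because
neither is canonical when coverage differs between subjects.

Transfer between meshes is deliberately minimal: `resample_nearest_sphere()`
assigns each target vertex the value of the great-circle-nearest source
vertex on the registered unit sphere (ties break to the lowest source
index, making the operation deterministic), and
`sample_volume_to_surface()` does nearest-voxel lookup under the volume
affine. Spherical registration itself — morphing a subject's surface to a
template sphere — is out of scope; the package consumes its output.

## Traveling-wave fields on flattened meshes

All phase comparisons use the minimal signed circular difference
(`circular_difference()`, range $[-\pi, \pi)$); there is **no global phase
unwrapping**, which would be path-dependent on annular activation
patterns.

`phase_gradient_field()` fits, at each significant vertex $v$, the 2D
vector $g$ (radians/mm in flattened coordinates) minimizing
$\sum_u \big(\Delta\theta_{uv} - g\cdot(x_u - x_v)\big)^2$ over the
significant ring-1 neighbors $u$. The ring-1 stencil is the smallest
neighborhood that determines a plane; vertices with fewer than two
non-collinear significant neighbors are marked invalid rather than
extrapolated. The fit is done on the *delay phase* $(-\theta) \bmod 2\pi$
by default, so arrows point toward later-activating cortex — along the
direction of wave travel, which is what propagation-path figures show; the
raw $\theta$-gradient (its negation) is available via
`orientation = "phase"`. For a wave of speed $s$ mm/s and period $T$, the
planted relationship $|g| = (2\pi/T)/s$ is recovered within 5 % on interior
vertices of a 50 × 50 grid, and the field is equivariant under rotations of
the flat coordinates and invariant under global phase shifts (both are
tested properties).

`movie_frames()` and `isophase_bands()` discretize the cycle: a 9° window
moved in 4.5° steps gives 80 frames per cycle — 0.2 s/frame for a 16-s
period — with each significant vertex appearing in exactly two half-open
windows. The frame *masks* are the tested contract; rendering
(`plot_phase_map()`, `autoplot()`) is a thin optional layer over them.
`dominant_path_direction()` summarizes an ROI's field by the
magnitude-weighted mean direction with resultant length
$|\sum g| / \sum |g| \in [0, 1]$ as a coherence score.

## Surge profiles

`surge_profile()` aggregates an ROI: for each of the 80 bins, the complex
F-values of the $V$ member vertices whose delay phase falls in the moving
window are averaged, and the magnitude of that average — which lives on the
$\sqrt F$ scale, since that is how complex F-values are built — is
*squared* before being referred to $F(df_s, df_n)$. This reading makes the
single-vertex case reproduce the vertex's own per-unit p-value exactly,
which is the only self-consistent calibration of the bin heights
$-\log_{10}(p)$. Empty bins get $p = 1$ (height 0) rather than missing
values so profiles stay plottable and metrics well-defined. Whether
vertices must pass the display threshold before gathering is not canonical;
the default applies the threshold (`f_threshold = 4.7`) and `NULL` disables
it.

`surge_metrics()` reports the longest *circular* run of bins at or above a
height threshold (wraparound across the cycle boundary is handled), with
arrival/ending as the run's first/last bin centers in delay seconds,
latency as the peak bin (ties break to the earlier delay), and duration as
run length × 0.2 s. A profile with no supra-threshold bin yields an all-`NA`
row, not an error.

## The synthetic generator

`simulate_unit_timeseries()` builds a boxcar over the chosen paradigm
segment (crossmodal: Phase 1 = 0–5 s, Phase 2 = 5–10 s, rest 10–16 s;
unimodal/multimodal: Phase 1 = 0–5 s, rest 5–16 s; 16 cycles, TR 1 s),
optionally shifted by an extra onset delay, and convolves it **circularly**
with a double-gamma hemodynamic kernel (`canonical_hrf()`, gamma shapes
6 and 16 at rate 1, undershoot ratio 1/6, unit peak at 5 s). Circular
convolution is the honest choice for a steady-state periodic design — there
is no "first cycle" transient in the analyzed regime — and it makes DFT
phases exact and testable. Fractional-TR onsets are handled by area
sampling of the boxcar within each TR, which keeps planted phases accurate
to the (tiny) aliasing of harmonics above Nyquist.

Defaults are response amplitude 5, white-noise SD 1 and baseline 100 a.u.
No empirical amplitude or SNR is available for this kind of data at the
per-voxel level, so these were chosen once for clear detection power
(typical recovered F ≈ 7000 ≫ 4.7, per-unit phase SD ≈ 0.008 rad): the
simulator's job is ground truth for the *operators*, not MR realism. What
it deliberately does not emulate: temporally autocorrelated (pink) noise
beyond an optional low-order polynomial drift, motion, spatial noise
correlations, or anatomical variability — so passing tests certify the
analysis chain, not robustness to every artifact of real scans. Drift, when
enabled, is a low-order polynomial whose energy concentrates in the
excluded bins 1–3 at these scan lengths (a tested property). All
randomness is seeded and local: the same seed gives bit-identical scans
without disturbing the caller's RNG stream.

`make_flat_grid_mesh()` provides regular triangulated grids (interior
degree 6, Euler characteristic 1) and `plant_wave_truth()` lays delays
along Euclidean flat distance from a seed (radial wave) or along a fixed
direction (planar wave front), wrapped into the cycle. Euclidean distance
is adequate on these flat synthetic patches; a geodesic option would matter
only on strongly curved meshes, which the generator does not produce.

## Numerical choices and test scales

* Phases are stored in radians $[0, 2\pi)$; degrees appear only in window
  configurations (9°/4.5°) and the CLI.
* Percent signal change uses the per-unit temporal mean as baseline; units
  with near-zero mean fall back to demeaned raw signal with a warning.
* Half-open windows ($[c - w/2,\, c + w/2)$) and half-open bands everywhere
  prevent double counting; with window = 2 × step each vertex lands in
  exactly two windows, so bin counts sum to twice the vertex count.
* Vertex and voxel indices are 0-based in all objects and artifact files,
  matching the convention of surface-analysis label files.
* Map files are TSV + JSON sidecar (space tag, provenance, partition);
  writers are byte-reproducible for a given input.

Test problem sizes were chosen so the whole suite runs in well under a
minute apart from the null-calibration check, which simulates $10^5$
white-noise units in chunks to verify the empirical false-positive rate at
F > 4.7 lies in [0.007, 0.013] (±3 Monte-Carlo SE of the nominal 0.01).
Planted-wave recovery uses a 50 × 50 grid (2 304 interior vertices); delay
recovery uses 500 paired replicates at SNR 5. The vignette states no
empirical number that the tests or `scripts/acceptance.R` do not themselves
compute.

## Known limitations

* The noise-bin exclusion set is a reconstruction constrained by the
  printed $df_n$; other sets of the same size are possible and selectable.
* The ring-1 gradient stencil is unsmoothed; on very noisy maps a larger
  ring (exposed as future config) or pre-smoothing would reduce variance at
  the cost of blurring wave fronts.
* Nearest-neighbor spherical resampling does not interpolate; at target
  resolutions much finer than the source, staircase artifacts appear.
* Surge metrics describe one profile; the package deliberately offers no
  inferential comparison *between* profiles.
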