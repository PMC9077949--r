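---
title: "Modeling beam delivery time and spot sequence for a pulsed synchrocyclotron PBS system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling beam delivery time and spot sequence for a pulsed synchrocyclotron PBS system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbstime)
```

## The delivery model

A compact superconducting synchrocyclotron delivers pencil-beam-scanning
protons as a pulsed beam: 1 kHz pulse trains (about 7 µs beam-on per pulse),
with each energy layer painted in several radiation *bursts*. Because the
charge extracted per pulse carries statistical uncertainty, the control
system delivers most of each spot's monitor units (MU) in a first burst,
corrects in a second, and trims the residual in a third — an iterative layer
delivery that behaves like adaptive layer repainting. The package models the
total beam delivery time as the sum of four components,

$$T_{\mathrm{BDT}} = T_{\mathrm{LSW}} + T_{\mathrm{BSW}} + T_{\mathrm{SSW}} + T_{\mathrm{SSP}},$$

the totals of layer switching, burst switching, spot switching and spot
spill. Each component is a sum of per-event terms produced by one of four
sub-models, every parameter of which lives in a `machine_model` object
(`proteus_one()` returns the fitted defaults).

### Energy layer switching (ELST)

Switching between layers is a step function of the energy interval
$\Delta E_i = E_{i+1} - E_i$:

* $0.7$ s for a shallow descending switch ($S(E_i) \le \Delta E_i < 0$),
* $3.75$ s for a deep descending switch ($\Delta E_i < S(E_i)$),
* $5.5$ s for any ascending switch ($\Delta E_i > 0$),

where the critical interval $S(E_i)$ is piecewise linear in the starting
energy ($0.2E-39.5$ below 110 MeV, $0.1E-28.5$ to 150 MeV, $0.05E-21$
above; always negative over the machine's 70–227 MeV range). A repeated
energy ($\Delta E = 0$) is mapped to the short descending time: the case is
undefined in the source data and does not occur clinically, but a total
function is easier to reason about.

### Spot switching

Within a scan line (the fast axis, x) the switching time is a modified
softplus of the travel distance $x$ in mm:

$$t_x = 0.26\,\ln(1 + e^{x - 30}) + e^{-\frac12\left(\frac{x-30}{10}\right)^2} + 6 \quad (\mathrm{ms}),$$

a smoothed ramp with asymptotic slope 0.26 ms/mm (numerically equal to
s/m) turning on at 30 mm, a Gaussian bump at the turning point, and a 6 ms
magnet-preparation baseline. The bare exponential in the fitted formula is
given its 1 ms amplitude explicitly as a parameter (`gauss_amp`). The
softplus is evaluated in overflow-safe form (`log1p(exp(z))` below
$z = 30$, $z$ itself above, error $< 10^{-13}$), so distances up to a meter
are safe.

The slow axis (y) uses a three-piece model: constant 10 ms below 15.35 mm,
a degree-7 polynomial with the fitted 16-digit coefficients between
15.35 and 100 mm, and $0.2399\,y + 34.809$ ms at or above 100 mm (the
boundary inclusive on the linear side, as fitted). The branches are
evaluated exactly as parameterized: the seams are mildly discontinuous
(8.51 ms vs 10 ms at 15.35 mm; 55.06 ms vs 58.80 ms approaching 100 mm)
and we deliberately do not smooth them — the branch values, not
continuity, are what the data constrained.

Line switching covers both axes at once; the slower axis governs:
$t_{\mathrm{RSW}} = \max(t_x(|\Delta x|),\, t_y(|\Delta y|))$.

### Scan ordering

The controller scans from the lower-left corner of the field, spot by spot
along x, line by line upward. Entering a new line, it chooses whichever
line end (left-most or right-most spot) is closer to the previous line's
exit spot. `order_spots()` reproduces this serpentine-with-shortest-entry
rule; exact ties go to the left end, consistent with the controller's
lower-left starting bias (the source data is silent on ties). Lines are
formed by clustering spot y-coordinates with a tolerance (`y_tol`, default
$10^{-3}$ mm): plans exported from a TPS share exact row coordinates, so
the tolerance only guards float noise.

### Spill time and the maximum-efficiency model

Each spot in each burst is delivered as an integer number of 1 ms pulses.
Assuming every pulse carries the maximum charge available at full Dee
voltage — the *maximum efficiency* $v_i$ in MU/pulse, a linear function of
energy below the 123 MeV degrader seam and a degree-5 polynomial above —
the pulse count for spot $k$ of burst $j$ in layer $i$ is

$$n^{i,j,k}_{\mathrm{pulse}} = \left\lceil \frac{MU^{i,k}\,S_j}{v_i} \right\rceil,$$

with burst MU fractions $S = (0.609, 0.330, 0.061)$, the averaged weights
observed across energies and gantry angles. The fractions are applied
deterministically: charge-per-pulse statistics are explicitly not modeled
(the averaged-fraction model is the point), so two deliveries of the same
plan are identical. The third burst's fraction is small enough that spots
are delivered there as a single pulse in practice; the ceiling formula is
followed verbatim, so extreme MU can exceed one pulse. The curve as
printed has a 0.0054 MU/pulse jump at the 123 MeV seam, which we keep.

### Burst switching (BST)

Between bursts the controller exchanges two files with the delivery
system: the irradiation record of the finished burst (one row per
millisecond — its spot-switching row count $N_{\mathrm{SSW}}$ plus its
pulse count) and the command file for the next burst (one row per pulse
and per spot). The gap is linear in the transmitted row count:

$$t_{\mathrm{bsw}}^{i,j} = \mu\,(N_{\mathrm{SSW}}^{i,j} + N_{\mathrm{pulse}}^{i,j}
 + N_{\mathrm{pulse}}^{i,j+1} + N_{\mathrm{spot}}^{i,j+1}) + 0.2228\ \mathrm{s},
 \qquad \mu = 5\times10^{-5}\ \mathrm{s}.$$

$N_{\mathrm{SSW}}$ is the burst's summed switching time rounded to whole
milliseconds (log rows are 1 ms quanta). Travel from a burst's last spot
back to the next burst's first spot is absorbed in this gap — no extra
spot-switching time is charged between bursts, and no burst switch is
charged across a layer boundary (the layer switch covers it).

### Timeline assembly and units

`build_timeline()` emits one event per pulse and one event per switching
gap, in delivery order; `breakdown()` sums durations by event kind, so the
four-component identity holds exactly by construction, and the total also
equals last-event end minus first-event start (the way recorded deliveries
are timed). Internally all switching/spill arithmetic is in milliseconds;
ELST and BST are specified in seconds and converted once at assembly
(0.7 s is exactly 700 ms in binary floating point, so the identity test at
$10^{-9}$ s is safe).

## The log dialect

`emit_log()` writes the package's own documented CSV dialect (vendor
binary formats are out of scope): one row per pulse carrying position and
delivered MU, and one marker row per millisecond of every switching
interval, so a burst occupies exactly $N_{\mathrm{SSW}} +
N_{\mathrm{pulse}}$ rows. `parse_log()` reconstructs the component totals
and per-burst counts from rows alone — spot counts are recovered as
maximal runs of consecutive pulse rows, which is unambiguous because any
two spots are separated by at least the 6 ms zero-distance switch.
Round-tripping a timeline through its log reproduces each component to
within the half-millisecond rounding of each switching interval.

## Calibration

Every fitted parameter can be re-derived from log-style observations,
mirroring how the model was built:

* `fit_bst()` — ordinary least squares of burst gaps on transmitted-count
  sums; slope and intercept are the transmission coefficient and dead
  time. $R^2$ is reported ($1 - SS_{res}/SS_{tot}$) but never asserted
  against any external value.
* `fit_xswitch()` — least squares of the fast-axis curve with the
  nonlinear shape constants (turn 30 mm, width 10 mm, Gaussian amplitude
  1 ms) held fixed, which makes the model linear in the two free
  parameters (baseline, slope). Requires distances on both sides of the
  turn.
* `fit_burst_fractions()` — per-layer MU sums by burst, normalized,
  averaged across layers, renormalized to sum to one.
* `estimate_elst()` — for single-spot-per-layer ladder fields the
  inter-layer gap between pulse blocks *is* the ELST.

Observations come either from `synth_observations()` (model truth plus
zero-mean Gaussian noise, seeded and reproducible — the recovery test
harness) or from `extract_observations()` (read off a log table, with
1 ms quantization). The synthetic noise model is a single Gaussian per
observation kind; real burst gaps mix network and controller-load
variation, so recovery tests validate the fitters, not the latency
distribution. Parameter-recovery checks use a 32-layer design whose
spot counts and MU span few-spot/low-MU to many-spot/high-MU layers,
giving transmitted-count sums from tens to thousands — the range over
which the linear BST fit is identifiable; noise magnitudes (0.01 s on
burst gaps, 0.5 ms on switch times, 2.6 percentage points per-layer on
burst fractions) match the spreads reported for the machine.

## The interplay simulator

`run_interplay()` quantifies the interplay between delivery timing and
periodic target motion on a deliberately simple rigid phantom: a 2D grid
(default 2 mm spacing), a circular 20 mm target, and a unit-mass Gaussian
kernel (default $\sigma = 4$ mm) per pulse. Motion is a 1D sinusoid
(amplitude 5 mm, period 4 s, ten phases — the waveform itself is a design
choice; only "periodic" is given) and each pulse deposits at its planned
position shifted by the displacement at its start time, for each of the
ten starting phases. Target coverage is summarized as D99, computed as
the 1st percentile of within-target voxel dose.

What this toy does *not* model: 4DCT anatomy, deformable registration, a
clinical dose engine, or absolute dose. Directional claims are the test
surface — the spread of D99 across starting phases is smaller for the
three-burst delivery than for a non-burst continuous-spill reference, and
volumetric repainting (`repaint_field()`, whole field repeated at $1/N$
MU) reduces the spread further — not cGy values.

The non-burst reference (`nonburst_machine()`) is a single pass per layer
with a continuous spill of duration $MU/\text{rate}$, discretized at the
1 kHz clock, sharing the scan-order and switching models. Its default
rate, 20 MU/s, was chosen once so that the two machines' total delivery
times agree within a few percent on the package's default scenario
(`interplay_scenario()`: two 9×9 square layers at 5 mm spacing, 0.5
MU/spot, 160 and 155 MeV), keeping the comparison about delivery
*structure* rather than duration.

One caveat observed on the default scenario: beyond three paintings the
D99 spread reaches the averaging floor set by how the (repainted)
delivery duration covers fractional breathing periods, where the spread
is no longer strictly decreasing from one repainting number to the next
(it remains far below the unrepainted spread). This is a real property of
phase averaging with a finite, non-commensurate delivery duration, not a
numerical artifact — it persists when the dose grid is refined.

## Numerical choices and degenerate inputs

* Validation (`validate_field()`) reports physics violations (MU below
  0.01, energy outside 70–227 MeV, non-finite coordinates) as data, and
  only `build_timeline()` refuses an invalid field; readers never enforce
  physics.
* `group_lines()` clusters sorted y-gaps greater than `y_tol`; a single
  spot is a single line; equal entry distances break left.
* Pulse counts are always at least 1 (`ceil` of a positive quantity, and
  a guard for the non-burst discretization).
* Dose conservation in the interplay engine relies on kernels staying
  inside the grid; `run_interplay()` rejects fields whose spots, motion
  amplitude and kernel reach ($3\sigma$) together leave the grid.

## Problem sizes in the test suite

The suite exercises the timeline oracle on 200 randomly generated small
fields (at most 3 layers and 5 spots per layer — small enough that the
closed-form component sums are an independent hand-checkable oracle),
parameter recovery on the 32-layer calibration design and a 250-layer
fraction ladder, and the interplay comparison on the default two-layer
scenario with all four repainting numbers. These sizes keep the full
suite under a minute on a single core while leaving every statistical
check at 3σ or better power.

## Limitations

* Gantry-angle and day-to-day machine variation are not modeled (both
  were found negligible for the modeled system).
* Charge-per-pulse statistics, Dee-voltage feedback and the ion-number
  per MU curve are out of scope; the maximum-efficiency model is the
  deliberate simplification.
* The ELST critical-interval thresholds are configuration, not fitted by
  the calibration module (the underlying experiment's raw data is not
  reproducible from printed values).
* Vendor log and command file dialects are not parsed; the package's CSV
  dialect carries the same information content.
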