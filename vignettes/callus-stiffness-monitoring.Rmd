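---
title: "Monitoring bone callus stiffness with an instrumented external fixator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring bone callus stiffness with an instrumented external fixator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixmon)
```

## The measurement problem

In distraction osteogenesis a long bone is cut and the fragments are pulled
apart at a controlled rate (here 1 mm/day for 15 days after a 7-day latency),
so that new bone — the distraction callus — forms in the widening gap and then
mineralizes during the consolidation phase. The clinically interesting
quantity is the axial stiffness of that callus, `Kc` (N/mm): it tracks
mineralization without X-rays or sacrifice.

An external fixator instrumented with four load cells (one per bar, each
0–1 kN) reads the force share that bypasses the callus. fixmon implements
the complete computational chain from the device's framed byte stream to a
phase-tagged stiffness estimate with an uncertainty statement, plus a
synthetic bench that generates every input with planted ground truth.

## The mechanical model

During a stance the internal skeletal force `Fa` splits between two parallel
load paths, the fixator (`Ff`, the four-cell sum) and the callus (`Fc`):

* **Force partitioning.** `Fc = Fa − Ff`, exactly (`partition_force()`).
* **Skeletal force from gait.** `Fa` is not directly measurable; a floor
  platform reads the ground reaction force (GRF) and `Fa = 3.22 × GRF`, a
  ratio taken as constant across the consolidation phase
  (`skeletal_force_from_grf()`).
* **Consolidation stiffness.** Parallel springs deform equally, so
  `Kc = Kf · Fc / Ff = Kf · (Fa − Ff) / Ff` at the stance-peak instant,
  with `Kf = 593 ± 21 N/mm` the fixator stiffness measured over re-assembled
  frames (`consolidation_stiffness()`).
* **Distraction stiffness.** During a distraction the limb rests (`Fa = 0`,
  `Ff = Fc`), and `Kc = Ff / Δd` with `Δd` the applied displacement. Because
  the young callus is viscoelastic the force peaks immediately and then
  relaxes; the reported value is the instantaneous peak callus stiffness,
  `PCS = max Ff / Δd` (`distraction_stiffness()`).
* **Young's modulus.** Treating the callus as a homogeneous column,
  `E = Kc · L / A` in MPa, with `L` the cumulative distraction gap (mm) and
  `A` the bone cross-section (default 147.8 mm², a CT-segmented sheep
  metatarsus) (`young_modulus()`).

A worked bound motivates the sensor range: peak internal metatarsal forces
in walking sheep reach about 1.26 body weights, i.e.
`1.26 × 53.5 kg × 9.81 m/s² ≈ 661 N` shared by four 1 kN cells
(`gait_load_bound()`).

### Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `Kf` | 593 | N/mm | fixator stiffness; scales every consolidation estimate |
| `Kf_sd` | 21 | N/mm | between-assembly spread of `Kf`; drives replication uncertainty |
| `fa_grf_ratio` | 3.22 | – | GRF-to-skeletal-force scaling |
| `min_ff_N` | 1 | N | division guard in the Eq. inversion; below it a step is flagged degenerate |
| `peak_window_s` | 60 | s | PCS search window after distraction onset |
| `threshold_fraction` | 0.05 | – | stance detection threshold on GRF |

The model is most sensitive where `Ff` is small (stiff callus): the estimate
`Kf (Fa − Ff)/Ff` amplifies force noise by `Kf · Fa / Ff²`. The degenerate-step
guard makes that regime explicit instead of returning wild numbers: a flagged
step means the callus has consolidated beyond the measurable range.

## Telemetry format and baseline normalization

The firmware transmits 10 samples per 150-byte buffer. fixmon fixes a
byte-exact convention for the 15-byte frame — a 3-byte sync mark
`0xAA 0x55 0xA5`, four little-endian `int16` counts, and a little-endian
`uint32` millisecond timestamp — because the device documentation publishes
only the mark width and buffer size; the layout is therefore a stand-in
convention, documented in `encode_block()` and kept byte-exact by the codec
tests.

The decoder (`decode_stream()`) never fails on corrupted input. It scans for
sync marks and accepts a candidate frame only if (a) no other sync mark lies
inside its 15-byte window (an interior mark means the frame was truncated)
and (b) its timestamp fits a strictly increasing sequence — implemented as a
longest-increasing-subsequence filter so that a single corrupted frame
carrying an arbitrary timestamp cannot shadow the frames after it. Any
single contiguous corruption costs at most the two frames it touches;
everything later is recovered bit-exactly, and every resynchronization is
reported with its byte offset (no silent data loss:
`frames_in = frames_decoded + frames_lost`, both logged by the pipeline).

Load cells drift with temperature and resting posture, so sessions open with
a static rest window (default 10 s); the per-cell arithmetic mean of that
window is subtracted from all subsequent samples (`compute_baseline()`,
`apply_baseline()`). Normalization is a pure shift: it changes no variance
and no step height, and the stiffness estimators consume only normalized
traces.

## Calibration and the uncertainty budget

The estimators are validated in vitro on elastic springs of known stiffness
`Ksr` standing in for the callus (16.75–208.83 N/mm for the distraction
procedure; 103.01–7448.78 N/mm for consolidation). Each spring is measured
over 4 independent fixator re-assemblies × 5 repeats, and `Ksr` itself from
5 direct tests. `summarize_bench()` reports the relative error
`e = 100·|Ks − Ksr|/Ksr` and an expanded relative uncertainty built
GUM-style from the three named sources, combined in quadrature with coverage
factor `k = 2`:

* `u_ref = SD/(√5 · Ksr)` — reference-spring characterization,
* `u_repl = SD(assembly means)/(√4 · Ks)` — replication (re-assembly),
* `u_rept = pooled within-assembly SD/(√5 · Ks)` — repetition.

The published bench campaign this reconstruction is checked against is
shipped as `bench_reference_table()`; its per-row errors and the footer
averages (6.73 % / 7.50 % distraction, 4.90 % / 14.04 % consolidation)
reproduce exactly under the 2-decimal per-row rounding convention. Three
published rows differ by 0.01–0.02 points from `100·|Ks − Ksr|/Ksr`,
consistent with a mean-of-per-estimate-errors estimator; both conventions
are available and neither is asserted for those rows. The coverage factor
behind the published per-row `U` values is not stated, so `k = 2` is a
documented assumption and individual `U` values are order checks only —
their column average is exact. The phase-average uncertainties are also what
`distraction_stiffness()` and `consolidation_stiffness()` attach to in vivo
estimates by default, mirroring how the bench uncertainty is propagated to
the animal measurements.

`force_acquisition_error()` scores a measured force trace against a
testing-machine reference (pointwise relative error with a 5 %-of-full-scale
reference floor); on a synthetic compression ramp to −661 N with a planted
3.5 % gain error it recovers that mean error, the structural analogue of the
physical calibration statistic.

## What the synthetic bench emulates — and what it does not

`synthetic_scenario()` fixes the study conditions; every generator draws all
randomness from its `seed` (identical scenario + seed ⇒ identical bytes):

* **Sensor noise.** Independent zero-mean Gaussian noise per cell, SD
  0.18 N in vitro, so the four-cell sum has SD `2 × 0.18 = 0.36 N` by
  quadrature. In vivo the aggregate noise is 3.01 N on the summed channel,
  split equally across cells in quadrature. Slow drift is a linear ramp,
  off by default (the noise-budget rest windows are drift-free) and
  exercised explicitly in tests.
* **Viscoelastic relaxation.** The response to a 1 mm distraction is a
  single-exponential decay from the instantaneous peak to a residual
  plateau, residual ratio 0.6 and τ = 300 s — a standard-linear-solid-like
  shape chosen because only the peak-then-relaxation structure is known, not
  a functional form. The planted stiffness schedule rises linearly to
  `k_end = 250 N/mm` on day 15, matching the observed end-of-phase magnitude
  and monotone trend.
* **Gait.** A 0.6 s stance as two raised-cosine humps (braking and push-off,
  first/second height ratio 1.1, peak GRF 200 N); no published GRF waveform
  exists for this setup, so the profile is generic quadruped walking. The
  fixator share follows the parallel-spring split
  `Ff = Fa · Kf/(Kf + Kc)` exactly, giving the inversion oracle.
* **Bench grids.** Replication is modelled purely as assembly-to-assembly
  fixator variability (relative SD `21/593 ≈ 3.5 %`): in consolidation the
  physics uses the perturbed `Kf_a` while the estimator applies the nominal
  `Kf`; in distraction the same variability acts as a per-assembly
  transmission gain. Repetition noise is the 0.36 N summed sensor noise.
  Gaussian shapes are assumed throughout; nothing beyond mean ± SD is
  published.

Passing tests therefore demonstrate correct *inversion of the model the
generator shares with the estimator* under the stated noise — they do not
validate the 3.22 ratio, the constancy of `Kf` in vivo, tissue heterogeneity,
soft-tissue load sharing, or gait variability in a live animal. The absolute
in vivo stiffness trajectories (0.53→1.85 kN/mm over consolidation) and the
physical calibration error (3.66 %) depend on unpublished hardware inputs and
are deliberately covered by structural surrogates only: monotone generator
trends, modulus linearity, and planted-gain-error recovery.

## Numerical choices and degenerate inputs

* PCS peak search over the first 60 s; the 20-min relaxation tail is kept on
  the event for inspection but never enters the PCS.
* Division guards: `|Ff| ≥ 1 N` at the stance peak; relative-error traces
  mask samples with reference below 5 % of full scale.
* Signs: traces are stored signed (compression negative); stiffness formulas
  consume magnitudes at the evaluated instant.
* Rounding: bench reports round per-row `e` and `U` to 2 decimals before
  averaging (this convention is what reproduces the published footers).
* Degenerate cases raise classed conditions (`fixmon_*_error`) rather than
  returning sentinels: empty baseline windows, incomplete bench grids,
  all-zero GRF, out-of-protocol distraction days, wrong block sizes.
* Problem sizes: property tests run tens of short streams and 1000 bench
  grids; the noise-quadrature check uses 1.2 × 10⁵ samples, comfortably
  enough for a ±0.01 N assertion on a 0.36 N SD.

## Known limitations

Single axial callus only (no bone-transport two-callus discrimination, no
bending or torsion); `Fa/GRF` fixed at 3.22 rather than measured per animal;
the wire format is a stand-in convention pending the real byte layout; the
uncertainty budget is a GUM-style reconstruction of a procedure whose exact
formulas are unpublished.
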