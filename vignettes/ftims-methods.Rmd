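---
title: "Stepped-frequency FTIMS: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepped-frequency FTIMS: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftims)
```

## The measurement this package models

In a dual-gate drift-tube ion mobility spectrometer both Bradbury–Nielsen
gates are driven by the *same* square wave. An ion swarm with drift time
$t_d$ reaches the second gate delayed by $t_d$, so the time-averaged
transmission at gate frequency $f$ is the circular overlap of two
duty-$d$ square waves offset by the phase $\varphi = \mathrm{frac}(f\,t_d)$.
For the FT experiment's defining 50% duty this is the triangle

$$g(f, t_d) = \tfrac12\left(1 - 2\min(\varphi,\, 1-\varphi)\right),$$

maximal ($g = 0.5$) when the gate period matches the drift time and zero in
anti-phase. Sweeping or stepping $f$ while recording the averaged detector
current therefore encodes each species as a periodicity $1/t_d$ in the
*frequency* axis; a magnitude FFT of that record (the interferogram) maps
the mixture back onto a drift-time axis. `gate_correlation()` implements
the exact overlap; `simulate_interferogram()` sums
$\sum_i a_i\,\mathbb{E}\,g(f, t_i)$ over the mixture, the expectation taken
over each species' Gaussian arrival distribution (mean $t_d$, sd $\sigma$,
evaluated by 241-node quadrature across $\pm 6\sigma$ of the exact
piecewise overlap).

Because the interferogram value at each step is a *steady DC level*, the
experiment tolerates asynchronous, software-timed data windows — provided
the current amplifier is slow enough to erase the per-period gate ripple.
We model the amplifier as a single-pole RC low-pass with time constant
$\tau = t_r/2.2$ (the 10–90% rise-time convention for a first-order
system); with the FT-mode default $t_r = 100$ ms the ripple at any gate
frequency of interest is attenuated by orders of magnitude, and the
windowed mean of `simulate_time_domain()` output becomes insensitive to
where the window starts. The test suite quantifies this: with a rise time
of 30 gate periods, windowed means across 20 trigger offsets spanning a
full period vary by well under 1%. That is the package's operational
definition of "asynchronous triggering is valid".

## Acquisition plans

`plan_stepped(f_min, f_step, f_max, n_avg)` builds the stepped protocol:

* the frequency grid runs $f_{\min}, f_{\min}+\Delta f, \dots$ up to the
  largest grid point $\le f_{\max}$ (never rounded up, so the FFT sees a
  uniform grid);
* every step dwells for $n_{\mathrm{avg}}/f_{\min}$ seconds — the
  *constant-time* averaging rule, anchored to the slowest frequency, so 4
  averages at a 4 Hz minimum give exactly 1 s of signal per step;
* the data window opens `trigger_offset` (default 0.5 ms) after the
  frequency changes. The offset shifts only the data window, never the
  gate phase — that is the asynchrony.

`plan_swept()` describes the linear-chirp alternative (instantaneous
frequency $f_{\min} + (f_{\max}-f_{\min})\,t/T$), and
`plan_single_gate()` the conventional pulsed mode (50 ms scan, 0.2 ms
pulse, 275 averages by default — a 0.4% duty cycle, inside the 0.1–0.5%
range typical of pulsed drift tubes, against 50% in FT mode).

`plan_duration()` reports pure-dwell time plus an optional per-step
`switch_overhead`. Published wall-clock times for stepped acquisitions
imply per-step bookkeeping of a couple hundred milliseconds that the dwell
rule alone cannot produce and that depends entirely on the controller, so
the default overhead is 0 and the knob is exposed rather than guessed.

## Drift cell and mobility calibration

Geometry mode uses the standard drift-tube relation
$t_d = L/(KE)$ with $K = K_0\,(T/273.15)(760/P)$, the reduced mobility
referenced to the universal 273.15 K / 760 Torr standard state.
Calibration mode summarises the cell by the constant $C = t_d K_0$, which
is what a practitioner actually has when the cell length is not published:
the default `drift_cell()` takes $C$ as the mean of $t_d K_0$ over the
four bundled tetraalkylammonium standards (43.137 ms·cm²·V⁻¹·s⁻¹);
across all nine benchmark compounds the products agree to under 2%
relative spread, which is the internal-consistency check the suite runs.
The two relations are exact inverses and tested to $10^{-9}$ relative.

## Reconstruction

`reconstruct_spectrum()` mean-subtracts (the correlation signal carries a
DC pedestal of $\approx d^2$ per unit abundance that would otherwise leak
across low drift times), apodises, zero-pads, and reports the magnitude
FFT. Choices the underlying protocol leaves open, fixed here as package
defaults:

* **Window**: rectangular by default (the rawest presentation of the
  transform); Hann by flag. The transform-limited full width at half
  maximum is $c_w/(f_{\max}-f_{\min})$ with $c_w = 1.2067$ (rectangular
  sinc main lobe) and $c_w = 2$ exactly (Hann); `ft_limited_fwhm()`
  returns this closed form and the tests verify it against brute-force
  transforms of the windows and against reconstructed pure cosines.
* **Zero padding**: factor 8 (rounded up to an FFT-friendly length), so
  width estimates are interpolated rather than bin-limited.
* **Magnitude, not real part**: under asynchronous triggering the phase of
  each component is arbitrary, so only the magnitude is meaningful.
* **Axis**: bin width $1/(N_{\mathrm{fft}}\,\Delta f)$, maximum
  representable drift time $1/(2\Delta f)$. Frequencies below $f_{\min}$
  are treated as absent — no extrapolation towards 0 Hz; for a magnitude
  spectrum the missing band start only shifts phase.

Two artifacts are inherent to the 50%-duty triangle correlation and are
surfaced rather than hidden. First, every species also contributes odd
harmonics at $3t_d, 5t_d, \dots$ with $1/k^2$ amplitudes; `flag_harmonics()`
marks fitted peaks at odd multiples of a stronger peak (within one
resolution bin, below 20% of its height) as possible artifacts. Second,
harmonics beyond the conjugate-domain Nyquist $1/(2\Delta f)$ fold back
into the axis; at a 2 Hz step this adds roughly 1.5% to the third
harmonic's amplitude over its continuum value of $1/9$ — the tests carry
the folded-series oracle for exactly this reason.

## Peak metrics

`fit_peaks()` detects local maxima above a height threshold (fraction of
the global maximum, default 0.1), suppresses candidates that sit inside a
taller peak's window-transform footprint (a rectangular window carries 22%
sidelobes which are line shape, not species), and fits a Gaussian over
$\pm 2$ preliminary half-widths, with bounded parameters and a moment
fallback when the fit rejects. FWHM is $2.3548\,\hat\sigma$; ties in
height resolve to the shortest drift time. The Gaussian line model is a
deliberate simplification: drift-tube peaks are near-symmetric, and no
line-shape information beyond FWHM enters any reported metric.

Resolving power is $R_p = t_d / w_{1/2}$. RMS noise is the population
root-mean-square deviation $\sqrt{\sum_i (H_i - \bar H)^2 / n}$ (an
$n-1$ variant is available via `ddof`); S/N is maximum fitted peak height
over the RMS noise of a peak-free region — by default the final 20% of
the drift axis, slid earlier in 10% steps if a peak (within $\pm 3$
half-widths) intrudes, and refusing a user-supplied region that overlaps
a peak. A noiseless region reports `Inf` rather than a number.

## Comparison statistics

`build_report()` summarises paired single-gate vs FT measurements. The
headline percent improvements are computed as *ratio of column means*,
not the mean of per-row ratios — on the bundled nine-compound benchmark
the two readings differ materially (21% vs ≈29% for resolving power), and
only the ratio-of-means convention reproduces the published summary.
`paired_delta_summary()` returns the per-compound differences with their
paired $t$ statistic; the p-value is descriptive output, not a gate.
`run_frequency_study()` re-runs the full pipeline over a grid of one plan
parameter with per-replicate seeds derived as `seed + 1000*i + r`
(triplicate by default, matching bench practice), reporting mean and sd
of the target peak's resolving power and the predicted acquisition time.

## What the generator does and does not emulate

The simulator reproduces the *signal structure* of the experiment: the
triangular dual-gate correlation with its DC pedestal and odd harmonics,
Gaussian arrival-time broadening, amplifier low-pass smoothing, dwell-time
noise averaging ($\sigma/\sqrt{\mathrm{dwell}\cdot f}$ per interferogram
point, white Gaussian, per-step substreams of one seed), and the
single-gate pulse-width convolution with $1/\sqrt{n_{\mathrm{scans}}}$
averaging. It deliberately omits gate-depletion and field-penetration
dynamics (the empirical high-frequency signal droop of real hardware),
space charge, ion–molecule chemistry and transient bridging species, and
every DAQ/driver layer. Consequently passing tests demonstrate the
protocol arithmetic, the reconstruction mathematics and the asynchrony
argument — not the absolute resolving powers or S/N of any physical
instrument, which depend on the unmodeled hardware.

Within a dwell, samples are combined by the arithmetic mean (the choice
matters only as a constant scale). Simulated signals are kept in
normalised transmission units; the amplifier gain is carried as metadata
for conversion to volts.

## Problem sizes and numerics

The shipped tests run stepped plans of 500–4000 steps, time-domain records
of $\le 8\times10^4$ samples, and 100-trial recovery batches at spectral
S/N near 10 — sizes chosen so the whole suite completes in well under a
minute while leaving every effect it probes (sub-percent oracle agreement,
one-bin centre recovery, fourfold bandwidth-resolution scaling) far above
its numerical noise floor. Time-domain oracle comparisons sample at
400–2000 points per gate period because the square-edge discretisation
error ($\sim$ one sample per edge) must sit below the 1–2% tolerances
being asserted. The recursive low-pass filter is initialised at the
record's DC level, representing continuation from the already-established
steady state of the running experiment rather than a cold start.

## Known limitations

* Peaks closer than the transform-limited width merge; no deconvolution
  beyond the FFT is attempted.
* The harmonic flagger is heuristic (odd multiple, one bin, <20% height);
  a genuine species sitting exactly at $3t_d$ of a strong peak with a
  weak signal would be mis-flagged.
* Calibration mode assumes $t_d K_0$ truly constant across species, i.e.
  a common standard state and field; geometry mode exists for anything
  more demanding.
* The swept simulator assigns each sample the steady-state correlation at
  the instantaneous chirp frequency; chirp-rate transients (finite
  settling within a sweep) are not modeled.
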