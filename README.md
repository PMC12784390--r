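# ftims

Simulation and analysis of **asynchronous stepped-frequency
Fourier-transform ion mobility spectrometry** (FTIMS) on dual-gate
drift tubes, for instrument builders and method developers who want to
explore gate-modulation protocols, reconstruction settings and figures of
merit without hardware in the loop.

## The method

In a dual-gate drift tube both ion gates are driven by one square wave of
frequency *f* and 50% duty. A species with drift time *t_d* arrives at the
second gate delayed by *t_d*, so its time-averaged transmission is the
triangular correlation of the two gate waveforms,

    g(f, t_d) = ½ (1 − 2·min(φ, 1−φ)),   φ = frac(f · t_d),

maximal when the gate period matches the drift time (a 20 ms drift time is
matched by 50 Hz). Stepping *f* over a uniform grid while recording the
averaged detector current yields an interferogram in which each species is
a periodicity 1/*t_d*; a magnitude FFT maps it back to a drift-time
mobility spectrum. Because a slow current amplifier (100 ms rise time,
modeled as a single-pole low-pass with τ = rise_time/2.2) turns each step
into a steady DC level, the data windows can be software-timed
*asynchronously* to the gate waveform — the timing claim this package
makes quantitative.

On top of the simulator the package provides: acquisition planning with
the constant-time dwell rule (`n_avg / f_min` seconds at every step),
swept-chirp and pulsed single-gate modes for comparison, FFT
reconstruction with windowing/zero-padding and odd-harmonic flagging,
Gaussian peak fitting, resolving power `Rp = t_d / w½`, population RMS
noise `√(Σ(Hᵢ−H̄)²/n)` and S/N = peak height / RMS noise, reduced-mobility
calibration `t_d·K0 = C`, frequency-parameter optimisation studies, and
single-gate vs FT comparison reports.

## Worked example

```r
library(ftims)

mix  <- fixture_mixture("txa4")          # four tetraalkylammonium standards
plan <- plan_stepped(10, 5, 4000, n_avg = 4)
ig   <- simulate_interferogram(plan, mix$ions, mix$cell,
                               noise_model(white_rms = 0.05, seed = 1))
sp    <- reconstruct_spectrum(ig)        # rectangular window, 8x zero pad
peaks <- analyze_spectrum(sp, mix$cell)
peaks
#>      td w_half  height    rp     K0   snr possible_harmonic
#> 1 30.07 0.8624 0.05564 34.86 1.4346 150.6             FALSE
#> 2 35.04 0.9881 0.04801 35.47 1.2310 130.0             FALSE
#> 3 40.33 1.1248 0.04150 35.86 1.0695 112.3             FALSE
#> 4 45.56 1.2943 0.03718 35.20 0.9469 100.6             FALSE
plan_duration(plan)
#> [1] 319.6
```

The four standards come back at their reference drift times (30.11,
35.06, 40.33, 45.49 ms) to within a fraction of a transform bin, with
reduced mobilities from the calibration constant, resolving powers set
jointly by the 4 kHz band's transform limit and the ions' intrinsic
widths, and S/N from the injected white noise. The plan itself dwells
0.4 s at each of 799 steps (320 s of pure dwell).

Comparison arithmetic on the bundled nine-compound benchmark table:

```r
rep <- build_report(reference_compounds())
glance(rep)
#>   n mean_rp_sg mean_rp_ft pct_rp_increase mean_snr_sg mean_snr_ft pct_snr_increase
#> 1 9       64.0       77.7            21.3        5.40        10.9             103.
paired_delta_summary(rep)$t
#> [1] 2.693928
```

FT mode improves the mean resolving power by 21% (ratio of column means)
over single-gate operation on the same cell, a gain that is significant in
a paired t test.

Plotting: `autoplot(ig)`, `autoplot(sp, peaks)`,
`autoplot(run_frequency_study(...))`, `plot_comparison(rep)`.
A command-line wrapper with `plan` / `simulate` / `reconstruct` /
`analyze` / `compare` / `study` subcommands ships in
`inst/scripts/ftims.R`.

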