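# sdoftf

Motion-artifact removal from arterial pulse signals measured at rest,
built on a single-degree-of-freedom (SDOF) model of the
tissue–contact-sensor stack and a time–frequency decomposition of the
pulse harmonics.

## Who this is for

Researchers working with arterial pulse waveforms (APW) from tactile or
PPG sensors who need, from a single resting record: the waveform cleaned
of motion artifacts, harmonic amplitude/phase indices, heart rate,
respiration rate and modulation depth, and a partition of heart-rate
variability (HRV) into a respiratory share and a remainder attributable
to other physiological factors.

## The model in brief

The transmission path from artery to transducer is one base-excited
oscillator,

```
m0 x'' + (c0 + cs) x' + (k0 + ks) x = k0 y + c0 y',
```

driven by the arterial wall displacement `y(t)`.  Motion adds a
baseline drift `x_b(t)` (< 0.7 Hz) and modulates the oscillator
parameters — `m(t), c(t), k(t) ∝ x_b(t)` — turning the artifact into a
multiplicative distortion `x_tvsp(t)` riding on every pulse harmonic.
The pulse itself is a harmonic sum with respiratory phase modulation
(respiratory sinus arrhythmia):

```
y(t) = Σ A_i cos(2π i f_C t + φ_0i + ψ(t)),   ψ(t) = R sin(2π f_r t + α0).
```

The analysis separates the harmonics by zero-phase band-passes at
`i·f_C ± (f_C − 0.2)/2`, extracts each harmonic's instant amplitude
`A_i(t)`, instant frequency `f_i(t)` and instant initial phase
`φ_0i(t)` by Hilbert vibration decomposition, and removes the artifact
by replacing `A_i(t)` with its regression line and `φ_0i(t)` with its
mean.  Two reconstructions come out: `x_tf` (time-varying frequency,
HRV preserved) and `x_cf` (constant frequency — the extracted APW).
Respiration is read from both `f_i(t)` and `φ_0i(t)`; the phase route
is nearly immune to motion artifacts, and

```
RMSE(HR_PF) = RMSE(HR) − RMSE(HR_φ)
```

splits total HRV into respiratory and other-physiological-factor parts.

## Worked example

Simulate a tactile measurement of a three-harmonic pulse with
respiratory modulation and a seeded resting artifact, then analyse the
measured channel:

```r
library(sdoftf)

spec <- pulse_spec(f_c = 1.2, amplitudes = c(1, 0.457, 0.407),
                   phases = c(0, 5.781, 5.420),
                   resp_amplitude = 0.1, resp_rate = 0.25)
y  <- synth_pulse(spec)
ma <- gen_ma_rest(fs = 100, duration = 80, rms_amplitude = 0.3, seed = 42)
bundle <- simulate_measurement("tactile", sdof_params(), tvsp_coupling(),
                               y, ma)

fit <- run_analysis(dplyr::select(bundle, time, value = measured),
                    analysis_config(n_harmonics = 3))
fit
#> <pulse_analysis>
#>   record:   8000 samples @ 100 Hz (80 s)
#>   f_c:      1.2 Hz (72 bpm)
#>   harmonics: 3
#>   mean HR:  72 bpm;  total HRV 1.05 bpm;  respiratory HRV 4.22 bpm (harmonic 1)
#>   RR (phase source, harmonic 1): 14.97 breaths/min
```

The fundamental is recovered at 1.2 Hz (72 bpm) and the respiration
rate at 14.97 breaths/min against a ground truth of 15.  The waveform
summary gives the harmonic indices of the *measured* signal:

```r
tidy(fit, "apw")
#>   harmonic a_bar_ratio a_x0_ratio a_tf_ratio a_cf_ratio phase_diff
#> 1        1       1.000      1.000      1.000      1.000       0.00
#> 2        2       0.474      0.474      0.474      0.474       5.77
#> 3        3       0.448      0.448      0.448      0.448       5.39
```

The amplitude ratios differ from the generator's (0.457, 0.407) because
the sensor stack transmits the higher harmonics with slightly higher
gain as they approach its 10 Hz resonance — the analysis reports what
the sensor measured, which is the quantity available in practice.  The
phase differences recover the generated 5.781 and 5.420 rad to within
0.03 rad.  `glance(fit)` condenses the record to one row
(`mean_b_phi = 0.099` against a generated modulation depth of 0.1);
`tidy(fit, "hrv")` returns the full per-harmonic heart-rate and
respiration report, and `autoplot(fit, type = "recon")` (or `"tracks"`,
`"hr"`, `"resp"`) draws the result.  Note the negative `rmse_hr_pf`:
with purely respiratory HRV, the literal radians-as-hertz convention of
the phase-derived heart rate makes the respiratory share exceed the
total — the vignette discusses this convention and the `pm_to_fm`
alternative.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/sdof-tf.R simulate --config sim.yaml --out bundle
Rscript inst/cli/sdof-tf.R analyze record.csv --n-harmonics 3 --out results/
Rscript inst/cli/sdof-tf.R config        # print all defaults
```

`analyze` accepts two-column CSV or WFDB records (formats 16/212/80,
`--channel PLETH`, `--segment "70,150"`).

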