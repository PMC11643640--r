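# kndysim

Conductance-based modelling of arcuate kisspeptin (Kiss1^ARH^ / KNDy)
neurons — the hypothalamic cells whose estradiol-dependent switch between
NKB-driven sustained firing and spontaneous phasic bursting underlies the
GnRH pulse generator.

`kndysim` is for computational neuroendocrinologists and
electrophysiologists who want to simulate these cells, reproduce the
published voltage-clamp calibrations, and analyse real or simulated traces
with the field's standard measurements.

## The model

A Hodgkin–Huxley-style single compartment with twelve ionic currents,

C_m dV_m/dt = −(I_NaT + I_NaP + I_A + I_BK + I_h + I_SK + I_M + I_T + I_Ca +
I_TRPC5 + I_GIRK + I_leak),

plus single-pool calcium dynamics
dCa/dt = −α_Ca (I_T + I_Ca + f·I_TRPC5) − (Ca − Ca_rest)/τ_Ca and
first-order NKB/dynorphin receptor drives. SK opens as a Hill function of
calcium (half-activation 0.3 µM), BK's midpoint shifts with calcium, and
TRPC5 — the plateau-potential current — opens as (receptor drive) ×
(calcium facilitation), which makes the NKB-evoked slow EPSP regenerative.
Two calibrated presets are shipped: `OVX` (ovariectomized) and `OVX_E2`
(estradiol-replaced), pinning the published conductances (g_SK = 28.1 nS,
g_BK = 20 nS, g_Ca = 2.1/2.8 nS, g_T = 0.66/5 nS) and Boltzmann midpoints
(−32.3 / −48.9 mV).

The package provides declarative voltage/current-clamp protocols,
pharmacology, spike/burst/firing-mode analysis, Boltzmann and calibration
fitting, 2-D conductance-space regime scans with boundary extraction, qPCR
ΔΔCT utilities, and seeded synthetic-data generators. Simulation is
deSolve over a compiled-C right-hand side; analysis functions take and
return tibbles and every fitted object supports `tidy()`/`glance()` and
`autoplot()`.

## Worked example

Reproduce the apamin-subtraction experiment (SK current density at +40 mV)
and the two firing phenotypes:

```r
library(kndysim)

ovx <- kndy_params("OVX")

# apamin-sensitive SK density: control minus full SK block, end of the
# 500 ms step to +40 mV, divided by C_m
density_ksens(ovx, "SK")
#> [1] 60.5        # pA/pF; the measured value is 60.2 +/- 3.3

# saturating NKB drive (10 s) on the OVX state
tr <- simulate_neuron(ovx, nkb_synch_protocol(), dt_out = 0.25)
drv <- dplyr::filter(tr, epoch == "drive")
classify_firing(detect_spikes(drv), drv)[, c("label", "rate_Hz")]
#>   label   rate_Hz
#>   tonic   20.1     # sustained repetitive firing through the drive

# spontaneous activity of the estradiol-treated state
e2 <- kndy_params("OVX_E2")
tre <- simulate_neuron(e2, drive_protocol(nkb_target = 0, duration = 20000),
                       dt_out = 0.25)
classify_firing(detect_spikes(tre), tre)
#>   label         n_bursts  burst_period_cv  intra_burst_rate_Hz  updown_range_mV
#>   phasic_burst  45        0.24             121                  15.0
```

The phasic-burst classification means the E2 state fires regular spike
bursts (>100 Hz within bursts, period CV < 0.5) on top of alternating
depolarized/hyperpolarized membrane states — the estradiol phenotype.

Analysis utilities work on any trace-like tibble:

```r
fit_boltzmann(gen_activation_dataset(-32.3, 5, seq(-80, 0, 5),
                                     noise_sd = 0.02, seed = 2))
#> <kndy_boltzmann> activation fit: V1/2 = -32.58 mV, k = 5.16 mV, r2 = 0.9978

qpcr_efficiency(c(-3.352, -3.478))
#>   slope  efficiency  percent
#>  -3.35       0.988       99
#>  -3.48       0.939       94
```

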