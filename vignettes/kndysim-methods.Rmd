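---
title: "Modelling arcuate kisspeptin (KNDy) neurons with kndysim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling arcuate kisspeptin (KNDy) neurons with kndysim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Arcuate kisspeptin (Kiss1^ARH^, "KNDy") neurons co-release kisspeptin,
neurokinin B (NKB) and dynorphin and form the hypothalamic GnRH pulse
generator. Estradiol switches their firing mode: ovariectomized (OVX,
low-estradiol) cells are mostly silent or tonically active and respond to
NKB with sustained firing, whereas estradiol-replaced (OVX+E2) cells fire
spontaneous phasic bursts riding on alternating depolarized/hyperpolarized
membrane states.

`kndysim` implements a Hodgkin–Huxley-style single-compartment model of this
cell. The membrane equation is

$$C_m \frac{dV_m}{dt} = -I, \qquad
I = I_{NaT}+I_{NaP}+I_A+I_{BK}+I_h+I_{SK}+I_M+I_T+I_{Ca}+I_{TRPC5}+I_{GIRK}+I_{leak},$$

with outward current positive and units fixed throughout as mV, ms, nS, pA,
pF and µM (so 1 nS·mV = 1 pA and 1 pA/pF = 1 mV/ms). Every gated current is
ohmic, $I = g\,x^{p}y\,(V-E)$, with Boltzmann steady states
$x_\infty(V) = \mathrm{floor} + (1-\mathrm{floor})/(1+e^{(V_{1/2}-V)/k})$
and first-order kinetics whose time constants are constant or bell-shaped in
voltage. Three currents have non-voltage gates:

* **SK** opens as a Hill function of cytosolic calcium,
  $\mathrm{Ca}^{n}/(\mathrm{Ca}^{n}+K_{SK}^{n})$, with the literature
  half-activation $K_{SK} = 0.3$ µM; it is voltage independent.
* **BK** uses a single voltage gate whose midpoint shifts by
  `bk_ca_shift` (−20 mV) per decade of calcium above rest, a one-parameter
  stand-in for joint Ca/voltage gating.
* **TRPC5** (the model's calcium-activated non-selective cation current,
  reversal 0 mV) opens as
  $(c_{base} + (1-c_{base})\,a_{NKB})\cdot
  \mathrm{Hill}(\mathrm{Ca}; K, n)$: the NKB receptor drive multiplies a
  calcium facilitation, and the basal openness $c_{base}$ couples TRPC5
  conductance to resting excitability, which is what reproduces the
  direction of the CRISPR knock-down effects on resting potential and
  rheobase.

GIRK is gated by the dynorphin drive times a fixed inward-rectification
sigmoid. Receptor drives $a_{NKB}$ and $a_{Dyn}$ relax with first-order
kinetics (rise 200 ms, decay 1 s) toward protocol targets; "saturating"
stimulation is a target of 1. Calcium follows a single-compartment balance

$$\frac{d\mathrm{Ca}}{dt} = -\alpha_{Ca}\,(I_T + I_{Ca} + f_{TRPC5} I_{TRPC5})
 - \frac{\mathrm{Ca}-\mathrm{Ca}_{rest}}{\tau_{Ca}},$$

with inward current negative, so influx raises calcium. Which currents feed
the pool is not observable from the published measurements, so the TRPC5
fraction `f_TRPC5` is an explicit parameter.

## Parameterization: pinned values and calibration products

The published record pins a handful of parameters, which the presets carry
verbatim: $g_{SK} = 28.1$ nS (both states), $g_{BK} = 20$ nS (OVX+E2) with
the OVX value scaled by the measured density ratio $32.8/90$,
$g_{Ca} = 2.1/2.8$ nS and $g_T = 0.66/5$ nS (OVX / OVX+E2), the whole-cell
calcium Boltzmann midpoints (−32.3 mV activation, −48.9 mV inactivation),
$K_{SK} = 0.3$ µM, the M-conductance ratio
$g_M(\mathrm{E2}) = 4\,g_M(\mathrm{OVX})$, and the qualitative directions of
the E2 effect on TRPC5, GIRK and h conductances. Everything else — the full
gating table, $C_m$, the calcium-handling constants and the unprinted
conductances — is a calibration product of this package, obtained by
requiring the presets to reproduce, simultaneously:

1. the six printed current-density anchors (apamin-sensitive 60.2 pA/pF and
   total outward 125.5 pA/pF at +40 mV in OVX; iberiotoxin-sensitive
   90.0 pA/pF and total 195.4 pA/pF in OVX+E2; peak calcium density
   7.2 / 13.4 pA/pF at −10 mV), each measured by simulating the actual
   voltage-clamp protocols; and
2. the firing phenotypes: OVX silent at rest (−66 mV), driven to sustained
   ~20 Hz firing by saturating NKB; OVX+E2 firing spontaneous, metronomic
   phasic bursts (~2.3 Hz burst rate, triplets at >100 Hz intra-burst,
   ~15 mV up/down alternation); abolition of the NKB plateau under calcium
   clamp; and monotone TRPC5/GIRK effects.

Notable calibration choices, made once and kept:

* **$C_m = 19$ pF**, a typical value for these small neurons; densities are
  always reported as $I/C_m$.
* **$n_{SK} = 4$.** A steep SK calcium dependence keeps SK silent at resting
  calcium (~0.1 µM) yet strongly activated at the ~0.25 µM reached at the
  end of a 500 ms step to +40 mV. Shallower Hill exponents make SK a
  resting-conductance brake that suppresses every firing phenotype.
* **Per-state values for several unprinted parameters** ($g_{NaT}$,
  $g_{NaP}$, $g_{leak}/E_{leak}$, $c_{base}$, $f_{TRPC5}$,
  $\alpha_{Ca}/\tau_{Ca}$). A single shared calcium pool serves SK, BK and
  TRPC5; with fully shared unprinted parameters the density anchors and the
  two firing phenotypes cannot be met jointly. The two presets are therefore
  calibrated per state, exactly as the printed conductances are.
* **Linear driving force with $E_{Ca} = +60$ mV** for both calcium currents
  rather than a flux equation, matching how the whole-cell data were
  fitted.
* **HVA activation slope $k = 7$ mV.** With the pinned −32.3 mV midpoint and
  linear driving force, slopes shallow enough to put the continuous I–V peak
  exactly at −10 mV pass a large calcium window current near rest, which
  floods the pool and destroys the firing modes. With $k = 7$ the simulated
  densities at −10 mV match the printed values, at the cost of the discrete
  I–V minimum sitting one 10-mV grid step lower (−20 mV). We consider this
  the better trade-off and document it as a known limitation.

## The burst mechanism

In the OVX+E2 preset the spontaneous oscillation is a relaxation cycle in
the calcium–SK–TRPC5 subsystem: calcium decays between bursts until the
steep SK conductance disengages, the basal TRPC5 and persistent-sodium bias
then depolarize the cell through the T-type window into a spike triplet,
whose calcium influx (T, HVA and the TRPC5 fraction) re-engages SK and
terminates the burst with a deep AHP; h-current and M-current kinetics shape
the refilling trajectory. The limit cycle is deliberately reported with its
diagnostics (burst count, period CV, intra-burst rate, up/down range) rather
than as a single label, because conductance-based bursters of this type are
sensitive to parameter changes of a few percent — which is also the
scientific point of the conductance-space scans.

## Protocols and measurement operators

All recording programs are declarative constructors: the calcium I–V family
(150 ms steps from −80 mV), the potassium step family (500 ms steps from
−70 mV at 0.2 Hz), the M-current deactivation protocol (300 ms prepulse to
−20 mV, 500 ms steps −75…−30 mV), 50 pA/s current ramps, and receptor-drive
epochs standing in for 10 s of 20 Hz optogenetic stimulation. Sweeps restart
from the holding steady state, matching the slow inter-sweep recovery of the
recordings. Pharmacology is multiplicative conductance scaling
(`apply_block()`), with complete block assumed for apamin and iberiotoxin as
in the source calibration; the TTX/CNQX/AP5/picrotoxin cocktail maps to
zeroed sodium conductances (no synaptic currents are modelled), and calcium
isolation additionally zeroes the potassium conductances (Cs⁺/TEA internal).
Whole-cell calcium is measured as the cadmium-sensitive component: the
per-sweep difference between the isolation family and the same family with
the calcium channels blocked. Model "drug subtraction" does not freeze
calcium dynamics; because the calcium trajectory is shared between control
and blocked runs of SK/BK blocks, the subtraction is exact up to the small
TRPC5 coupling.

Chelator (BAPTA) emulation clamps cytosolic calcium at the nominal resting
concentration from the start of the recording — the chelator is dialysed
before stimulation — which prevents the calcium build-up that sustains the
NKB-evoked plateau.

Trace analysis includes spike detection (0 mV upward crossings, 2 ms
refractory merge), the five-way firing-mode taxonomy (silent < 0.1 Hz;
bursts of ≥ 3 spikes with ISIs < 80 ms terminated by gaps > 300 ms;
phasic versus irregular bursting split by burst-period CV < 0.5 plus
≥ 8 mV of subthreshold up/down alternation; tonic at ISI CV < 0.5), rheobase
from ramp latency, F–I curves, peak and end-of-step I–V extraction,
drug-subtraction, Boltzmann fits (Levenberg–Marquardt on the shared sigmoid
form; the printed activation and inactivation equations are the same curve
up to the sign of $k$), M-current relaxation amplitude (initial < 10 ms
minus sustained > 475 ms), low-pass slow-EPSP amplitude (2 Hz zero-phase
Butterworth), and the percent decomposition of the outward current over the
repolarizing potassium set. The up/down-state detector uses a ~51 ms running
median of the membrane potential: unlike a 2 Hz low-pass it does not
attenuate burst rhythms near or above 2 Hz, while still rejecting spikes.
The qPCR module implements $E = 10^{-1/m}-1$ (rounded half-up to integer
percent) and the comparative $2^{-\Delta\Delta C_T}$ quantification with the
control-group mean ΔCT as calibrator.

## Synthetic data

The generators emulate the statistical structure of the source datasets so
every analysis operator has a testable round trip: per-cell I–V families
with lognormal cell-to-cell scale (and lognormal capacitance around 20 pF),
additive per-voltage Gaussian noise, paired control/drug families built from
the measured channel-subtype fractions (L 26.1%, N 25.1%, P/Q 3.9%, R 31.1%,
T 6.7% in OVX; 24.9/24.6/11.0/27.0/11.1% in OVX+E2), Boltzmann activation
points, and 10-cell-pool qPCR CT datasets with animal-level (σ = 0.3 CT) and
pool-level (σ = 0.2 CT) variance components. All generators are pure
functions of their arguments and a seed; no global RNG state leaks. What
these fixtures do **not** emulate — electrode artifacts, series resistance,
liquid-junction offsets, space clamp, PCR chemistry — means that green
round-trip tests certify the analysis code, not robustness to raw
experimental data.

## Numerics

The state vector (membrane potential, 12 gates, calcium, two receptor
drives) is integrated by deSolve through a compiled-C right-hand side. The
default solver is an adaptive Runge–Kutta (Dormand–Prince, `ode45`) with
relative tolerance 1e-6, absolute 1e-8 and a 1 ms maximum step; `lsoda` and
a brute-force fixed-step RK4 oracle (default 0.01 ms) are selectable, and
the adaptive and fixed-step solutions agree to well under 0.5 mV over
multi-second windows of bursting. Initial conditions come from a ≥ 5 s
relaxation at the protocol's holding condition with gates started at
$x_\infty(V_{hold})$. Voltage-clamp pins the potential exactly (the clamp
equation, not a large-conductance approximation). The optional
Ornstein–Uhlenbeck background current (off by default) is pre-sampled with
its exact discretization under a mandatory seed and fed to the solver as a
forcing, so stochastic runs are reproducible. A pure-R reference
implementation of the right-hand side is cross-checked against the compiled
code in the test suite at 1e-9 relative tolerance.

Calibration is bounded Levenberg–Marquardt least squares on relative
residuals with seeded multi-start (conductances bounded to [0, 100] nS,
$C_m$ to [5, 60] pF, midpoints to ±40 mV of their defaults); printed
conductances are never free. Regime scans derive one deterministic seed per
grid cell from the global seed and the cell index, so cells are independent
and order-invariant; diverging cells are flagged and the scan continues.
Boundaries between labelled regions are marching-edge midpoints (geometric
means on the log-spaced axes), flagged as non-simple when a grid column
crosses more than once.

## Problem sizes

The shipped tests and the anchor-reproduction script run every protocol at
the sizes a desk check needs: full 11/12-sweep voltage-clamp families with
3 s holding relaxations, 10–20 s current-clamp simulations for the firing
phenotypes, 5-point-per-axis regime scans, 200-replicate estimator checks
and 10⁴-cell generator checks. Larger grids (the default 21×21 scan axes)
and longer recordings use exactly the same code paths.

## Known limitations

* The discrete calcium I–V minimum sits at −20 mV (see above).
* The burst limit cycle is parameter-sensitive; small perturbations can
  yield doublets (classified irregular) instead of triplet phasic bursts.
* Lumped currents (one HVA calcium current, one A-type/delayed outward
  current) absorb the subtype structure the transcript data resolve.
* Drug subtraction leaves calcium dynamics running; subtracting a
  calcium-carrying current therefore carries a small coupling error in the
  calcium-activated currents.
* No synaptic currents, network coupling, temperature dependence, GHK flux
  or Markov channel models.
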