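---
title: "Circuit models and readout methods for metallized-bead resistive-pulse assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circuit models and readout methods for metallized-bead resistive-pulse assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadpulse)
```

## Scope

`beadpulse` models a single-aperture impedance flow cytometer used as the
readout of a bead-based electronic immunoassay. Analyte binding is
transduced into enzymatic silver deposition on 8.2 µm beads; beads transit
a 30 µm × 30 µm aperture while magnitude and phase of the impedance are
recorded at six carriers (45 kHz, 150 kHz, 380 kHz, 2 MHz, 11 MHz, 35 MHz)
at 57,000 samples/s. This vignette documents the models, the calibration of
every tunable parameter, the numerical choices, and what the synthetic data
do and do not establish about real instrument data.

## The lumped-element model

**Empty cell.** The sensing zone is the fluid resistance $R_f$ in parallel
with a parasitic capacitance $C_p$, behind a series lead inductance $L_s$:

$$Z_\mathrm{base}(\omega) = j\omega L_s + \frac{R_f}{1 + j\omega R_f C_p}.$$

The magnitude is flat at $R_f$ below the corner $1/(2\pi R_f C_p)$ and
falls above it; the phase returns towards positive values only far above
the band of interest, where $\omega L_s$ dominates.

**Resistive pulse.** A nonconducting sphere of diameter $d$ displaces
conductive fluid and transiently raises the aperture resistance by the
DeBlois–Bean amplitude

$$\Delta R = \frac{4\rho d^3}{\pi D_\mathrm{eff}^4}
  \left[1 - 0.8\left(\frac{d}{D_\mathrm{eff}}\right)^3\right]^{-1},$$

with $\rho$ the fluid resistivity and $D_\mathrm{eff} = 2s/\sqrt{\pi}$ the
equal-area circular diameter of the square aperture of side $s$. In the
small-bead limit the amplitude scales with displaced volume ($d^3$); the
bracket is the standard finite-size correction.

**Bead element.** The bead occupies a slab of the sensing zone carrying
$R_\mathrm{slab} = \eta R_f$. With the bead present the slab becomes the
parallel combination of the displaced-fluid branch
$R_\mathrm{slab} + \Delta R$ and, for a metallized bead, a shell branch
$Z_\mathrm{sh} = R_\mathrm{sh} + 1/(j\omega C_\mathrm{sh})$:

$$\Delta B(\omega) = \left(R_\mathrm{slab} + \Delta R\right) \parallel
  Z_\mathrm{sh}(\omega) - R_\mathrm{slab}.$$

The series resistor–capacitor shell reflects the nanostructured morphology
of the enzymatic silver film: an intricate mesh of metal spheroids and
electrolyte whose metal–electrolyte interfaces contribute an equivalent
capacitance. It reproduces the defining signature of metallized beads: the
interface capacitance blocks conduction at low frequency
($\mathrm{Re}\,\Delta B > 0$ at 45 kHz), while in a mid-frequency band the
shell shunts the displaced slab and the pulse flips sign
($\mathrm{Re}\,\Delta B < 0$ at 150 kHz–2 MHz). Removing the capacitance
($C_\mathrm{sh} \to \infty$, a conformal conductive layer) makes the pulse
negative at *every* carrier — the behaviour a field simulation of a plain
conductive coating predicts, and exactly what distinguishes that model from
the measured spectra. Both behaviours are asserted in the test suite.

**Bead capacitance.** A dielectric bead also adds a small capacitance. It
is placed in parallel with the baseline capacitance (the measured phase
effect is a deepening of the capacitive phase near the corner), so the full
cell with a bead at pulse-shape scalar $s \in [0,1]$ is

$$Z(\omega, s) = j\omega L_s + \left(R_f + s\,\Delta B(\omega)\right)
  \parallel \frac{1}{j\omega\left(C_p + s\,C_b\right)}.$$

An alternative reading places $C_b$ across the slab branch itself. We
rejected it: with any $C_b$ large enough to matter it drives the
nonmetallized bead element negative at high frequency, i.e. it predicts
negative pulses for plain dielectric beads, which are not observed; the
outer-node placement keeps $\Delta B = \Delta R > 0$ exactly at all
frequencies for nonmetallized beads.

## Parameter calibration

No element values for the cell are published, so defaults are calibrated
once against the qualitative landmarks the measurements fix, and kept:

| Parameter | Default | Rationale |
|---|---|---|
| side length $s$ | 30 µm | aperture geometry |
| sensing length | 30 µm | axial extent comparable to the constriction |
| fluid conductivity | 1.6 S/m ($\rho$ = 0.625 Ω·m) | ~1× PBS |
| $R_f$ | 20.8 kΩ | slab geometry: $\rho L / s^2$ |
| $\eta$ (slab fraction) | 0.3 | makes negative pulses possible when the shell conducts |
| $C_p$ | 3.82 pF | places the cell's RC corner at 2 MHz, the observed band of maximal phase deviation |
| $L_s$ | 1 µH | lead-scale inductance; restores positive phase far above band |
| $C_b$ | 0.1 fF | sub-femtofarad scale of an 8 µm dielectric sphere (~$\varepsilon_0 \varepsilon_r d / 2$) |
| $R_\mathrm{sh}$ at full metallization $R_0$ | $0.1\,\eta R_f$ = 625 Ω | a dense film conducts ~10× better than the slab it spans |
| $C_\mathrm{sh}$ at full metallization $C_0$ | 60 pF | electric double layer (~20–30 µF/cm²) over the bead surface |

The shell link is monotone in the metallization density $m \in [0,1]$:
$R_\mathrm{sh} = R_0/m$, $C_\mathrm{sh} = C_0 m$, degenerating to an absent
branch at $m = 0$. With these defaults the working bead's resistive pulse is
$\Delta R$ = `r round(coulter_delta_r(8.2e-6, aperture_model()), 1)` Ω —
comfortably above the 110 Ω detection threshold — and the noise-free phase
deviation of a nonmetallized transit is maximal at the 2 MHz carrier, the
printed spectral landmark the acceptance script recomputes.

## The synthetic-data generator

`synthesize_trial()` emulates one 60-bead trial:

* per-bead metallization densities are lognormal around the binding-curve
  mean (log-scale sd 0.6, mean-preserving, clipped to $[0,1]$), producing
  the continuum that the M_hi/M_med/M_lo gates discretize without
  hard-coding subpopulations;
* the concentration → mean-density link is a saturable (4PL-shaped) binding
  curve with floor 0.01 (background metallization), ceiling 0.85, midpoint
  30 nM and Hill slope 1.2 — an invented stand-in, since the true binding
  calibration is not published; absolute synthetic LODs therefore have no
  quantitative meaning, only the recovery machinery does;
* transits are symmetric Gaussian bells with FWHM $\tau$ = 0.2 ms, the
  transit time of the sensing region at 10 µL/min through the aperture
  cross-section; apex times are drawn uniformly conditional on a 10 τ
  minimum spacing (exact conditional draw, no rejection loop); an
  off-centre factor (sd 0.05, clipped to (0, 1.2]) multiplies each pulse;
* noise is i.i.d. Gaussian per channel (10 Ω magnitude, 0.5° phase) plus a
  1 Hz, 100 Ω sinusoidal baseline drift on the magnitude channels, which is
  what justifies the high-pass stage;
* everything derives from the trial and acquisition seeds; the caller's RNG
  state is untouched.

What the generator does **not** emulate: coincident transits (overlapping
pulses are counted as one record — a documented detector limitation),
aperture clogging, electrode fouling or 1/f noise, bead-velocity spread
beyond the amplitude factor, and any chemistry upstream of the
metallization density. Passing tests therefore establish the correctness of
the readout chain under these idealized conditions, not instrument-level
performance.

## Pulse recovery

The six magnitude and six phase channels are median-subtracted and filtered
with a second-order Butterworth high-pass (default 5 Hz) applied
forward–backward for zero phase distortion. A first-order section would
leave ~4% of a 1 Hz drift in the passband; the second-order filter keeps
apex recovery under drift within 2%, at negligible pulse attenuation
($\tau \ll 1/f_c$). Peaks are found on the filtered 45 kHz magnitude as
strict local maxima above 110 Ω, pruned greedily by descending amplitude
(ties to the earlier index) under a minimum separation of 34 samples
(~3 τ); the suite proves this identical to brute-force enumeration on
random traces. "Directly indexing" the other channels is implemented
literally — same sample index — with an optional ±window extremum search
(off by default). Because apexes fall between samples, recovered amplitudes
carry a bounded sampling loss of up to ~0.6% at the default rate; tests use
1–2% tolerances accordingly.

## Gating, metric, dose–response

**Gates.** M_hi = negative ΔZp at any of {150 kHz, 380 kHz, 2 MHz} *and* a
45→150 kHz drop ≥ half the working bead's ΔR (~169 Ω); M_med = negativity
only; M_lo = the rest. The drop threshold quantifies the unquantified
"large decrease" criterion; an absolute threshold tied to the working
bead's pulse scale separates the sharp-drop subset without training data.
Negativity is strict (< 0) on the filtered, baseline-referenced values.

**Metric.** Features are ΔZp and Δφp at 11 MHz, z-scored with pooled
training statistics (the scaler is frozen at training and reused on test
trials, which is what makes the metric transferable to clinical trials).
The discriminant is the two-class Fisher direction
$w \propto S_w^{-1}(\mu_\mathrm{high} - \mu_\mathrm{low})$, unit-normalized,
with an orientation sign fixing *higher = more metallized* (the raw sign
convention of the training data is absorbed here). The per-bead score is the
1-D projection; the trial metric is its mean over the ~60 beads; the
decision threshold for positive/negative calls is the midpoint of the
projected training means. Singular within-class scatter errors out with a
regularization hint rather than silently shrinking.

**Dose–response.** $y = d + (a-d)/(1+(x/c)^b)$ is fitted by
Levenberg–Marquardt least squares on the residual function with a numeric
Jacobian — the symbolic gradient of $(x/c)^b$ is undefined at $x = 0$, and
zero concentrations are legitimate data points on the linear axis.
Initialisation is from the data (floor/ceiling from the extreme dose means,
$c$ from the mid-response level, $b = 1$), with $c$ bounded positive.
Degenerate or non-convergent fits are flagged, never silent. The LOD is the
closed-form 4PL inverse at blank mean + 3 sd — the conventional criterion,
since none is published; it is monotone in the blank sd and flagged when the
cutoff exceeds the fitted ceiling. The LOD recovery study uses a
12-replicate blank panel: with fewer blanks the chi-square noise of the sd
estimate, not the curve fit, dominates the error.

## Problem sizes in the test suite

Detector–oracle equivalence runs 1,000 random traces; completeness runs 100
seeded 60-bead trials at default noise (2 s, 57 kHz, 12 channels each);
metric separation trains on two full-pipeline trials and evaluates 100
held-out high/low pairs (0.8 s trials) plus a pooled per-bead AUROC on 20
pairs; dose-response recovery uses 200 noisy series for $c$ and 100 for the
LOD. These sizes give stable pass/fail behaviour at the stated tolerances
while keeping the default suite in the minutes range.

## Known limitations

* The element values are calibrated to qualitative landmarks only; no
  claim is made that they match any particular instrument.
* The per-frequency *sign* of the metallized bead's phase change depends on
  unpublished element values; the model pins the magnitude signatures and
  the nonmetallized phase peak, and the metric is trained on whatever
  contrast the model produces at 11 MHz rather than on assumed signs.
* Overlapping transits are not deconvolved; records never exceed detected
  apexes.
* The 110 Ω threshold is applied after filtering (the alternative —
  pre-filter thresholding — is not distinguishable from the published
  description); with the default calibration every bead kind pulses well
  above threshold at 45 kHz, so the choice is immaterial here.
* Whether the drop criterion for M_hi should be absolute or relative to the
  45 kHz pulse is unknown; the absolute variant is implemented and
  overrideable via `gate_config()`.
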