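---
title: "Inferring sparse binding-mode populations from spin-label PREs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sparse binding-mode populations from spin-label PREs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premodes)
```

## The measurement and the model

A nitroxide spin label (MTSL) attached through a disulfide bond to an
engineered cysteine carries an unpaired electron whose dipolar coupling to
nearby protons adds a paramagnetic contribution Γ₂ to their transverse
relaxation. The experiment measures, for every assigned cross-peak, the
ratio of intensities in the oxidized (paramagnetic) and reduced
(diamagnetic) samples. `premodes` models this ratio in two stages.

**Rate from distance.** For a complex tumbling with correlation time τ_c,

$$\Gamma_2(r) = \frac{K}{r^6}\left(4\tau_c +
  \frac{3\tau_c}{1+\omega_H^2\tau_c^2}\right)$$

with $K$ the electron–proton interaction constant (default
$1.23\times10^{16}\,\mathrm{\AA^6 s^{-2}}$, the standard nitroxide S = 1/2
value; configurable for other electron spins). At the default τ_c = 40 ns
and 800 MHz, $(\omega_H\tau_c)^2 \approx 4\times10^4$, so the spectral
density is dominated by the $4\tau_c$ term; dropping the dispersive term
changes Γ₂ by under 0.01% (this is asserted as a test).

**Ratio from rate.** Paramagnetic broadening lowers the peak height through
the linewidth and attenuates magnetization during the ¹H
transverse-evolution periods of the pulse sequence:

$$\frac{I_{ox}}{I_{red}} = \frac{R_2}{R_2+\Gamma_2}\,
  e^{-\Gamma_2 t_{evol}}, \qquad R_2 = \pi\,\Delta\nu_{1/2}$$

The Lorentzian half-height convention $R_2 = \pi\Delta\nu_{1/2}$ is used
throughout.

**Fast exchange.** For a complex populated at fraction $p$ exchanging fast
on the relaxation timescale, the observed rate is $p\,\Gamma_2^{bound}(r)$.
This is the validity condition of every inversion in the package; it holds
comfortably for the weak (millimolar-K_D) complexes the method targets,
where free and bound states interconvert on sub-millisecond timescales.
Intermediate or slow exchange, cross-correlated relaxation, and solvent
PREs are out of scope.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `tau_c` | 4.0e-8 | s | correlation time of the bound complex |
| `proton_frequency` | 8.0e8 | Hz | spectrometer field |
| `linewidth_dia` | 25 | Hz | diamagnetic linewidth → $R_2 = \pi\Delta\nu$ |
| `t_evol` | 9.0e-3 | s | total ¹H transverse-evolution time |
| `k_const` | 1.23e16 | Å⁶s⁻² | electron–¹H interaction constant |

The transverse-evolution time deserves comment: the observable depends on
it exponentially, yet it is rarely reported with published ratio analyses,
and the exact ratio expression in the underlying equation family (whether
and with which $t$ an exponential factor enters) is a genuine ambiguity.
The package resolves it by construction: `t_evol = 9` ms — a typical total
INEPT/evolution period of a TROSY-HSQC — was chosen once such that the
model's full-occupancy predictions at 11.0 and 10.6 Å reproduce the
one-significant-digit literature values (3×10⁻⁶ and 2×10⁻⁷) for this
experimental configuration, and it is exposed as an ordinary parameter so
other pulse sequences can be described. This calibration is documented
uncertainty, not a fitted quantity.

Numerical inversions (`gamma2_from_ratio`, `distance_at_ratio`) use
bracketed root-finding on the strictly monotone forward model with
automatic bracket expansion; round-trips are accurate to 1e-9 relative.
The 1:1 binding quadratic is solved in the cancellation-free form
$B = 2LP/(s+\sqrt{s^2-4LP})$, $s = L+P+K_D$, so that populations round-trip
with dissociation constants even in the weak-binding limit where
$K_D \gg L, P$.

## Degenerate inputs and tie-breaks

* Observed ratios ≥ 1 arise routinely from intensity noise. They are
  clipped to population 0 and flagged (`no-binding-information`) rather
  than rejected: a ratio of 1.1 is evidence of nothing, not an error.
* Observed ratios ≤ 0 (peak broadened beyond detection) cannot be
  inverted; they carry only a lower bound on Γ₂ and are reported as such.
* `kd_from_population(0)` returns `Inf` with a message: no detected
  binding places no upper limit on K_D.
* Glycine probe sites have no Cβ; the `cbeta` rule falls back to Cα with a
  warning.

## Probe placement on label-free structures

Crystal structures of candidate complexes contain the cysteine mutation's
wild-type residue, not the label. Two pseudo-atom rules are provided:
`cbeta` (the Cβ position — a conservative lower bound on distances) and the
default `cbeta_extended`, Cβ displaced 7 Å along the Cα→Cβ direction to
approximate the nitroxide midpoint of the extended MTSL side chain. No
rotamer-ensemble averaging or ⟨r⁻⁶⟩ weighting is attempted; where published
per-residue distances exist they should be supplied directly as the
distance table, decoupling inference from the placement model. Amide
hydrogens are usually absent from X-ray structures; distances default to
the backbone N with roughly 1 Å systematic uncertainty, flagged on the
table.

## Classification and replicate statistics

Intensity-ratio classes use half-open bins, exhaustive over [0, ∞):
strong < 0.4, intermediate [0.4, 0.6), moderate [0.6, 0.8), baseline
[0.8, 1.2), elevated ≥ 1.2. (The baseline band is where most ratios of a
non-binding experiment fall; its upper edge at 1.2 is assigned to
"elevated" by the half-open convention — the breaks are configurable if the
closed-interval reading is preferred.) Replicate SDs use the sample (n−1)
formula, appropriate for duplicate spectra. The alternative
summed-replicate profile (Σ I_ox / Σ I_red) serves low-sensitivity samples;
it equals the mean-of-ratios exactly when replicate denominators are equal.

Region annotations (e.g. primary interface, polybasic region, tripartite
interface) ship as user-supplied residue sets, not hard-coded lists: the
literature gives exemplar residues rather than exhaustive definitions.

The normalized intensity-ratio perturbation analysis divides
complex-sample by free-sample intensities at the free-protein peak
positions and normalizes by the mean ratio, making it invariant to the
overall concentration difference between the two samples; residues below
the 0.75 default threshold are reported as perturbed.

## The mode verdict

`assess_mode` mirrors the argument structure of a footprint test: a
binding mode that is substantially populated must produce strong PREs
(< 0.4 by default) at the residues its geometry places near the probe. The
expected footprint is computed at full occupancy; if no footprint residue
shows an observed strong PRE, the mode is flagged unsupported. Residues
with sub-unity ratios still yield per-residue population and K_D point
estimates; the largest of these is reported as the K_D lower bound
(most-constraining-residue aggregation), with its residue id. Surface-
exposed side chains can contact the probe in sporadic encounters, so
side-chain peaks participate only when present in both inputs. Point
estimates carry no error bars: the dominant uncertainties (placement
model, t_evol, fast-exchange assumption) are systematic, and pretending a
posterior would misstate them.

## What the synthetic generator emulates — and what it does not

`simulate_peak_tables` emulates a weak-binding titration end point:
20 µM observed protein, 110 µM spin-labeled partner, duplicate spectra,
and multiplicative log-normal noise on every intensity. Log-normal (rather
than additive Gaussian) noise keeps intensities positive and matches how
peak-height variability scales; the mean-one parameterization makes the
expected ratio at each residue exactly the forward-model prediction. The
default CV of 3% was set once to reproduce the 0.8–1.2 scatter band that
null residues occupy in practice; the true experimental noise magnitude is
not a reproduced quantity. A titration ladder (20/50/80/110 µM partner)
can be simulated by varying `binding_context`.

Not emulated: chemical-shift changes, peak overlap, H/D-exchange intensity
loss, assignment errors, and distance-distribution averaging from label
flexibility. Passing recovery tests therefore demonstrates the
*inversion machinery* is unbiased under the stated noise model — not that
real spectra are free of these systematic effects.

Problem sizes used by the shipped studies: parameter-recovery runs use 200
trials of duplicate spectra at a single informative residue (10.6 Å, 2%
CV), which resolves a 1% population to well within ±30% at the median;
property grids span r ∈ [4, 40] Å and p ∈ [1e-5, 1].

## Known limitations

* Populations and K_Ds inherit the fast-exchange and single-conformer
  distance assumptions; for K_D near or below the total concentrations the
  fast-exchange reading of the ratio progressively fails.
* The analysis treats each residue independently; no mixture deconvolution
  across simultaneously populated modes is attempted.
* τ_c is an input, never fitted; an error in τ_c rescales Γ₂ linearly and
  populations inversely.
* Structure-derived distance tables are only as good as the probe
  placement convention; the two rules provided bracket plausible label
  positions but do not model its conformational ensemble.
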