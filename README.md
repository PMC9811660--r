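# premodes

Spin-label PRE analysis of sparsely populated protein–protein complexes.

NMR paramagnetic relaxation enhancement (PRE) experiments can detect
protein complexes populated at well under 1% — far below what chemical-shift
titrations or ITC resolve. A nitroxide spin label (MTSL) attached to an
engineered cysteine on one binding partner broadens the resonances of any
nucleus that comes close to it; the observable is, per residue, the ratio of
cross-peak intensities measured with the label paramagnetic (oxidized) and
after its reduction (diamagnetic). Because the paramagnetic rate scales as
r⁻⁶ in the electron–nucleus distance, even a tiny bound population of a
complex that brings a nucleus near the label leaves a measurable dent in
this ratio.

`premodes` implements the quantitative chain from structure to observable
and back, for questions of the form *"is this candidate binding mode
populated in solution, and if so, at what population and dissociation
constant?"* — typified by probing whether the synaptotagmin-1 C₂B domain
binds the SNARE–complexin-1 complex through a proposed "tripartite"
interface.

## The model

For a complex with rotational correlation time τ_c observed at proton
frequency ω_H, a nucleus at distance r (Å) from the nitroxide has a
paramagnetic transverse rate

    Γ₂(r) = (K / r⁶) · (4τ_c + 3τ_c / (1 + ω_H²τ_c²))      [s⁻¹]

with K = 1.23×10¹⁶ Å⁶s⁻² the electron–¹H dipolar interaction constant.
The oxidized/reduced intensity ratio follows from line broadening plus
attenuation during the transverse-evolution periods of the pulse sequence:

    I_ox/I_red = R₂ / (R₂ + Γ₂) · exp(−Γ₂ t_evol),   R₂ = π·Δν½

Under fast exchange a complex populated at fraction p contributes
Γ₂_obs = p·Γ₂(r), so an observed ratio and a bound-state distance invert to
a population, and 1:1 mass action at the known sample composition converts
that population to a K_D. Defaults are τ_c = 40 ns, 800 MHz, 25 Hz
diamagnetic linewidth, t_evol = 9 ms, and 20 µM labeled protein with 110 µM
spin-labeled partner.

## Worked example

Two amides sit closest to the spin-label site in the tripartite candidate
structure: residue 350 at 11.6 Å and residue 354 at 10.6 Å. If binding
through that interface were fully occupied, their predicted intensity
ratios would be ~6×10⁻⁵ and ~2×10⁻⁷ — the peaks would vanish. The observed
ratios are 0.89 and 0.77:

```r
library(premodes)

prof <- compute_pre_profile(peak_records(
  residue       = c(350L, 351L, 353L, 354L),
  intensity_ox  = c(89, 110, 107, 77),
  intensity_red = c(100, 100, 100, 100)))

dists <- data.frame(residue = c(350L, 351L, 353L, 354L),
                    atom_role = "amide_N",
                    distance_A = c(11.6, 11.5, 11.9, 10.6),
                    mode = "tripartite", placement_rule = "cbeta_extended")

assess_mode(prof, dists)
#> Binding-mode assessment: tripartite
#>   residues joined        : 4
#>   expected strong (<0.4): 350, 351, 353, 354
#>   observed strong        : none
#>   mode supported         : FALSE
#>   K_D lower bound        : 0.0161 M (residue 350)
```

All four residues fall inside the full-occupancy strong-PRE footprint, yet
none shows a strong PRE: the mode is unsupported as a substantially
populated state. Taking the two sub-unity ratios at face value bounds how
much complex could still be present:

```r
assess_mode(prof, dists)$rows[
  , c("residue", "observed_pre", "population_estimate", "kd_estimate")]
#>   residue observed_pre population_estimate kd_estimate
#> 1     350         0.89         0.006770340  0.01611747
#> 2     351         1.10         0.000000000          NA
#> 3     354         0.77         0.009052069  0.01202210
```

Populations of 0.7% and 0.9%, i.e. K_D ≈ 16 and 12 mM — at most a very
weak, transient complex. Ratios above 1 (residues 351, 353) are intensity
noise and carry no binding information; they are clipped to p = 0 and
flagged.

The synthetic generator closes the loop for validation:

```r
cfg <- synthetic_experiment(c(`354` = 10.6), true_population = 0.009,
                            noise_cv = 0, seed = 1)
rec <- simulate_peak_tables(cfg)
population_from_ratio(rec$intensity_ox[1] / rec$intensity_red[1], 10.6)
#> [1] 0.009
```

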