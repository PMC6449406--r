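# pxbinding

Classification of human phox-homology (PX) domains by their
phosphoinositide-binding specificities.

PX domains are ~110–120 residue membrane-interacting modules found in 49
human proteins (most of them sorting nexins). Many bind the canonical
endosomal lipid PtdIns3*P*; others prefer di- and tri-phosphorylated
phosphoinositides, and some bind no lipid at all. `pxbinding` implements,
as a tested and reusable pipeline, the analyses that resolve these
preferences into four binding groups and tie them to two sequence
determinants:

* **Liposome-pelleting profiles.** Band intensities from the pellet (P)
  and supernatant (S) fractions become P/S ratios, banded as none
  (0–0.1), weak (0.1–1), strong (1–2) or very strong (>2). A profile is
  classified by two booleans — binding to PtdIns3*P* (A) and binding to
  any other specific lipid (B): Group I = neither, II = PtdIns3*P* only,
  III = other lipids only, IV = both. The Folch broad-binding indicator
  is diagnostic only.
* **Sequence determinants.** On a structure-guided alignment, the
  canonical PtdIns3*P* site is the four strictly required residues
  (sequential Arg/Tyr at the β3→α1 junction, the Lys of the ΨPxxPxK
  PPK-loop motif, and an α2 Arg); the secondary site is a His/Tyr at the
  first α1 position plus a stretch of basic Lys/Arg leading into the PPK
  loop. The 2×2 rule over (canonical complete, secondary present)
  predicts the group from sequence alone.
* **Titration thermodynamics and kinetics.** Single-site (Wiseman) ITC
  isotherms under the published injection scheme (0.5 mM headgroup into
  20 µM protein, 13 × 3.22 µl at 25 °C), least-squares fitting of
  (K_d, ΔH) with N fixed at 1, ΔG = RT·ln(K_d) and ΔG = ΔH − TΔS, the
  two-independent-site competition experiment, and 1:1 BLI kinetic fits
  (k_on, k_off, K_d = k_off/k_on).
* **NMR chemical-shift perturbation.** Combined amide shift changes
  Δδ = [(0.17·ΔNH)² + (ΔHN)²]^½ across HSQC titrations, with residues
  flagged at Δδ > 0.1 ppm.
* **Curated fixtures and a synthetic generator.** The packaged roster of
  all 49 human PX-domain proteins (with per-channel binding calls and
  provenance notes), SNX25 NMR statistics, and generators for gel,
  alignment, ITC and HSQC data with recorded ground truth so every stage
  is testable offline.

## Worked example

```r
library(pxbinding)

# classify the purified screen
profiles <- fixture_group_profiles()
group_census(profiles)
#>   I  II III  IV
#>  10  12   9   8

# fit a simulated canonical-site titration
fit <- fit_isotherm(simulate_isotherm(binding_params(Kd = 1e-5, dH = -10)))
fit
#> ITC fit: Kd = 10 uM, dH = -10.000 kcal/mol, N = 1.000
#>          dG = -6.821 kcal/mol, -TdS = 3.179 kcal/mol

# predict groups from a planted-site alignment
g <- generate_alignment_with_planted_sites(synthetic_config(seed = 101))
pred <- predict_proteome(g$alignment, g$annotation)
mean(pred$predicted_group == g$truth$group)
#> [1] 1
```

The census says 12 of the 39 purified PX domains are
PtdIns3*P*-exclusive (Group II), 10 bind nothing (Group I), 9 bind other
phosphoinositides but not PtdIns3*P* (Group III) and 8 bind both
(Group IV). The ITC fit recovers the simulated 10 µM dissociation
constant and −10 kcal/mol enthalpy exactly in the noiseless limit, and
the sequence rule recovers every planted group when no mutation noise is
applied.

The numbered scripts under `analysis/` run the full workflow and write
tables to `results/`: `01_binding_profiles.R` (profiles, groups, census,
NMR bookkeeping), `02_sequence_determinants.R` (planted-site benchmark
and mutation sweep), `03_titrations.R` (isotherm fits, competition
design, BLI kinetics), `04_csp_mapping.R` (CSP mapping).

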