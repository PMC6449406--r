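---
title: "Classifying PX-domain phosphoinositide specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying PX-domain phosphoinositide specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pxbinding)
```

## The problem

Phox-homology (PX) domains recruit their host proteins to membranes by
recognising phosphoinositide headgroups. The human genome encodes 49
PX-domain proteins, and their lipid preferences fall into four classes:
no binding (Group I), PtdIns3*P*-specific (II), di-/tri-phosphorylated
phosphoinositides but not PtdIns3*P* (III), and both (IV). `pxbinding`
implements the quantitative steps that produce this classification from
liposome-pelleting data, link it to two sequence determinants, and
support it with titration calorimetry, biolayer interferometry and NMR
chemical-shift mapping. This vignette explains the models, the tunable
parameters, and the design choices behind each stage.

## Binding profiles from pelleting data

Each protein × liposome lane contributes a pellet and a supernatant band
intensity; their ratio P/S is the binding statistic. The band rule is
none for P/S in [0, 0.1), weak for [0.1, 1), strong for [1, 2], very
strong above 2. The published band edges overlap ("0–0.1", "0.1–1",
"1–2", ">2"); we resolve them as half-open intervals with 2 assigned to
*strong*, because "greater than twofold" is explicitly exclusive.
Classification is monotone in the ratio and invariant to rescaling both
intensities, so densitometry units never matter. A lane with an empty
supernatant but protein in the pellet is a *saturated* ratio, treated as
greater than any threshold rather than an error; a lane with both bands
empty is invalid.

Group assignment uses two booleans — binding in the PtdIns3*P* channel
and binding in any other specific channel — with *binding* meaning a
band at or above a configurable threshold (default weak, i.e.
P/S ≥ 0.1). Two deliberate choices:

* **Folch is diagnostic, not decisive.** The Folch fraction is a brain
  lipid extract used as a broad-binding indicator; it contains PS and
  PtdIns(4,5)*P*₂ but no PtdIns3*P*. It is excluded from the rule, and a
  warning is raised if Folch binds while no specific channel does —
  empirically broad binders always light up specific channels too.
* **All non-PtdIns3*P* doped species count as "other specific".** A
  hypothetical PtdIns4*P*-only or PS-only binder would be Group III;
  the experimental screen contains no such case, so this is a rule
  completion, not an observed behaviour.

A profile whose PC/PE control lane shows binding is flagged and refused
group assignment.

The packaged roster encodes all 49 human PX-domain proteins with cloned
and purified flags and, for the 39 purified domains, per-channel boolean
binding calls curated from the screen's figures. Where the source text
is ambiguous (the "slight preference" PtdIns3*P* binders, and the group
memberships the text does not name protein-by-protein) the calls are
curator judgement, flagged per record in `encoding_note`. The test suite
re-derives every experimental group from the curated calls through
`assign_group()`, so the fixture cannot drift from the rule.

## Sequence determinants and group prediction

Detection is anchor-based on a structure-guided alignment rather than on
absolute sequence positions: a packaged 110-column scaffold annotation
maps alignment columns to the PX fold elements (β1–β3, α1–α3, PPK loop)
and names five anchor columns. It is user-replaceable via
`read_annotation_tsv()` for other alignments.

The canonical PtdIns3*P* site is complete when the junction Arg, the
junction Tyr (a strictly sequential pair at the last two β3 columns),
the PPK-loop Lys, and the α2 Arg are all present; a gap at an anchor
counts as absent. The Lys is credited from its anchor column only — a
ΨPxxPxK motif detected elsewhere (`detect_ppk_motif()`, Ψ ∈ {V, I, L,
M}) is supporting evidence, never a substitute, since a displaced motif
does not place the lysine in the binding pocket.

The secondary site is a His or Tyr at the first α1 column plus "a
stretch" of basic residues running toward the PPK loop. The basics are
not positionally conserved, so they are counted over a window — by
default the last 4 α1 columns plus the first 6 PPK-loop columns, with a
minimum count of 2. Neither the window nor the minimum is stated
numerically in the source; both are this package's defaults, chosen so
that one incidental lysine does not constitute a "stretch", and both are
configurable. Whether His and Tyr are fully interchangeable at the α1
position is unresolved experimentally; the rule treats them identically.

The group prediction is the 2×2 rule table over (canonical complete,
secondary present) → (IV, II, III, I). Known exceptions (SNX11's basic
surface without His/Tyr, SNX17/SNX27's unused secondary site, SNX15's
domain-swapped dimer) are carried as annotation notes on the prediction
and never override the rule output, so predictions stay falsifiable.

## Titration calorimetry

`simulate_isotherm()` implements the single-site (Wiseman) isotherm:
after injection *i* the cumulative concentrations follow the
perfusion-displacement bookkeeping `Mt_i = M0 (1 − v/V0)^i`,
`Lt_i = Ls (1 − (1 − v/V0)^i)`, the bound complex comes from the 1:1
closed form

```
[ML] = ((N·Mt + Lt + Kd) − sqrt((N·Mt + Lt + Kd)² − 4·N·Mt·Lt)) / 2
```

and the normalized heat of injection *i* is `ΔH · V0 · δ[ML]_i / (moles
injected)`, where in displacement mode `δ[ML]_i` includes the standard
perfusion correction `ML_i − ML_{i−1} + (v/V0)(ML_i + ML_{i−1})/2`:
complex carried out of the cell in the displaced volume leaves intact
and releases no heat. Without this correction a saturated cell would
show a spurious ~0.4 kcal/mol dissociation signal, contradicting the
observed flat trace when the same ligand is pre-incubated at saturating
excess. The simpler no-displacement mode retains the plain Δ[ML] form;
there, total heat equals ΔH × final bound moles exactly, which the tests
use as a conservation oracle.

Defaults mirror the published protocol: 13 × 3.22 µl injections of
0.5 mM ligand into 20 µM protein at 298.15 K. The cell volume is not
stated in the source; 200 µl is typical for the instrument class and is
configurable. Units are kcal throughout with R = 1.987×10⁻³
kcal/(mol K); exothermic heats are negative; K_d is molar inside the
formulas and reported in µM.

`fit_isotherm()` estimates (K_d, ΔH) — and N when `fix_N = FALSE` — by
Levenberg–Marquardt least squares with K_d on the log scale and three
starts log-spaced over 0.1–1000 µM, keeping the best sum of squares. N
is fixed at 1 by default, the usual practice once an initial refinement
shows N ≈ 1. A flat isotherm returns a "no detectable binding" outcome
rather than an error. ΔG = RT·ln(K_d) and ΔS = (ΔH − ΔG)/T are stored so
both identities hold exactly.

The competition experiment is modelled with two independent sites:
pre-incubating the ligand of the *other* site leaves the titration
bit-for-bit unchanged (independence is exact, not approximate), while
pre-incubating the *same* ligand enters the pre-equilibrium through the
initial cell ligand concentration and suppresses the heats — at
saturating excess they vanish to the perfusion-correction floor.

BLI traces follow 1:1 Langmuir kinetics, `R(t) = Req(1 − e^{−(k_on C +
k_off)t})` with `Req = Rmax·C/(C + K_d)`, then exponential dissociation.
Fitting proceeds dissociation-first (k_off), then association (k_obs,
Req). A flat dissociation phase reports k_off = 0 with a below-tolerance
flag instead of failing. The analyte concentration defaults to 20 µM —
the source states both 20 and 25 µM in different places; we follow the
results section and leave it configurable.

## Chemical-shift perturbation

The combined amide perturbation is Δδ = [(0.17·ΔNH)² + (ΔHN)²]^½, and a
residue is significant when Δδ strictly exceeds 0.1 ppm — a residue at
exactly 0.1 ppm is not flagged. Peaks are matched by residue assignment,
never by nearest-neighbour tracking in ppm space; a residue that
disappears on titration is reported as missing (exchange-broadened), not
as a zero. Whether per-ligand summaries should use the final titration
point or the per-residue maximum over points is not specified in the
source; `series_max_csp()` defaults to the maximum (a residue in
intermediate exchange can attenuate at high ligand) and offers the
final-point mode.

## The synthetic generators

The generators produce data with the statistical structure the analysis
assumes, plus recorded ground truth, so every stage is testable without
external data:

* **Gel lanes.** Band pairs are drawn so the noiseless P/S ratio sits
  mid-band for the archetype (none 0.02, weak 0.5, strong 1.5, very
  strong 3.0 — maximally separated from the band edges), then both
  intensities are multiplied by lognormal noise of configurable CV
  (intensities are positive and errors multiplicative). Default CV 0.2
  represents realistic densitometry variation; at that level group
  recovery over 200 proteins stays above 95% because misclassification
  requires a ~5.7σ lognormal excursion.
* **Alignments.** Random scaffold residues with determinants planted per
  the true group; alphabets at determinant-sensitive positions are
  reduced so a Group I/III protein cannot acquire a canonical site by
  chance, and corruption applies per planted site with probability
  `mutation_rate`.
* **ITC.** `simulate_isotherm()` plus additive Gaussian heat noise.
* **HSQC.** Uniform apo peaks, planted residues moving along a fixed
  random direction scaled by a hyperbolic saturation curve to a
  configurable maximal Δδ, everything jittering at 0.01 ppm by default
  (a typical HSQC noise floor, far below the 0.1 ppm cutoff).

All generators derive fixed substream seeds from the root seed, so each
is a pure function of its configuration and components can be
regenerated independently. The default group mix (10, 12, 9, 8)/39
matches the curated screen.

What the generators do *not* emulate: gel backgrounds and lane bleed,
heat-of-dilution baselines and first-injection artefacts, peak overlap
and assignment errors, or realistic phylogenetic correlation between
sequences. Passing the synthetic benchmarks therefore demonstrates the
correctness of the inference machinery under the stated noise models,
not performance on raw experimental files.

## Problem sizes and numerical choices

The shipped analyses and tests use the study's own scales: 39–200
synthetic proteins for classification benchmarks, 13-injection
isotherms with 50 Monte-Carlo replicates at 2% heat noise, 110-residue
HSQC spectra. The isotherm fitter's convergence tolerances (1e-14 on
both ftol/ptol) make noiseless round trips exact to ~1e-15 relative
error; ties at band edges are resolved by the half-open interval rule;
degenerate inputs (flat isotherms, flat dissociation phases, all-gap
sequences, empty rosters) return typed outcomes instead of errors.

## Limitations

The curated roster's group memberships beyond the proteins named in the
source text are curator reconstructions flagged per record; the census
totals, not individual rows, are the validated quantities. The
competition model assumes strictly independent sites (no allosteric
coupling), the ITC model fits normalized heats (baseline integration is
out of scope), and the sequence rules operate on a user-supplied
alignment — computing the alignment itself, electrostatic surface
analysis, and membrane-insertion modelling are out of scope.
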