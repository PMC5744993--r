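---
title: "A resistance-network model of passive monolayer permeability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A resistance-network model of passive monolayer permeability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pappnet)
```

## The model

Apparent permeability, $P_\mathrm{app}$ (cm/s), of a solute across a
Caco-2 or MDCK monolayer grown on a porous filter is measured from the
steady-state flux between a stirred donor and acceptor compartment.
`pappnet` describes the *passive* part of that flux as an electrical
analogue: three parallel permeation pathways, each a series of
resistances $R_x$ (s/cm), with permeabilities adding across pathways
and resistances adding along each pathway:

$$P_\mathrm{app} = \frac{1}{R^{tot}_{para}} + \frac{1}{R^{tot}_{lat}}
 + \frac{1}{R^{tot}_{cyt}}$$

* **paracellular**: $R_{UWL} + R_{para} + R_{filter}$ — diffusion
  through water-filled tight-junction pores between the cells;
* **cytosolic (transcellular)**: $R_{UWL} + R_{m,ap} + R_{cytosol} +
  R_{m,bas} + R_{filter}$ — across the apical membrane, through the
  cytosol, across the basolateral membrane;
* **lateral**: $R_{UWL} + R_{lateral} + R_{filter}$ — sorption into the
  apical membrane and diffusion along the membrane plane around the
  cell.

$R_{UWL}$ lumps the apical and basal unstirred water layers, and each
pathway carries its own copy of the shared UWL and filter terms. This
literal series/parallel composition double-counts the shared aqueous
layers relative to a full 2-D network, but it is the stated model and
the error is small compared with the experimental scatter of merged
Caco-2/MDCK data (within-source replicates already differ by a median
of ~0.3 log units).

Every barrier follows the solubility-diffusion picture
$R = h/(\varepsilon\,D\,K)$: a thickness $h$, a diffusion coefficient
$D$ inside the barrier, a barrier-water partition coefficient $K$, and
a porosity $\varepsilon$ when only part of the area conducts.

### Speciation and the pH-partition hypothesis

All aqueous resistances (UWL, cytosol, filter, paracellular space) are
speciation-independent: ions and neutral species diffuse through water
at the same rate. The two membrane-crossing terms ($R_m$, $R_{lateral}$)
admit only the *non-zwitterionic neutral* fraction $f_n$ at pH 7.4,
assuming instantaneous acid-base re-equilibration at the membrane
surface. Three consequences:

* a chemical with $f_n = 0$ is confined to the paracellular route
  (its cytosolic and lateral totals are `Inf`);
* a chemical whose neutral-charge mass is dominated by the zwitterion
  ($f_{zwit} > f_n$) is treated as membrane-impermeant outright —
  zwitterionic amino acids cross vesicle bilayers at ion-like rates
  ($10^{-12}$–$10^{-14}$ cm/s), so their $P_m$ is negligible;
* neutral fractions below the `ionized_cutoff` of $10^{-4}$ (0.01%,
  the resolution of typical speciation software output) are clamped to
  zero by `clamp_speciation()`, with the removed mass redistributed
  proportionally over the remaining species. At this cutoff the
  redistribution is numerically negligible; it exists so the simplex
  stays closed.

### The individual resistances

**UWL.** $R_{UWL} = 1/(\chi_{UWL}\,\nu^{\alpha})$ with stirring speed
$\nu$ in rpm, $\chi_{UWL} = 2\times10^{-6}$ cm/s and $\alpha = 0.6$.
Unreported or sub-150-rpm stirring is modeled at 150 rpm, below which
UWL permeabilities are experimentally indistinguishable. The UWL does
not depend on the solute in this model; solute-size dependence of the
UWL thickness is a known refinement left out.

**Paracellular.** Two pore populations act in parallel:
$P_{para} = (\varepsilon/\delta)\,D_{aq}\,F(\rho)\,E(\Delta\varphi) +
(\varepsilon/\delta)_2\,D_{aq}$ with $\varepsilon/\delta = 0.78$,
$(\varepsilon/\delta)_2 = 0.05$ (both carrying units of 1/cm so the
expression yields cm/s). $F$ is the Renkin hindrance polynomial in
$\rho = r_{hydr}/r_{pore}$ with $r_{pore} = 12.9$ Å, clamped to 0 for
$\rho \ge 1$ where the polynomial is non-physical. The hydrodynamic
radius combines the Sutherland small-solute correction with
Stokes-Einstein, $r_{hydr} = (0.92 + 21.8/MW)\,k_BT/(6\pi\eta D_{aq})$,
using the *dynamic* viscosity $\eta = 0.6913\times10^{-3}$ N·s/m² at
310 K. The field factor $E$ weights each ionic species by
$x/(1-e^{-x})$ (cations), $x/(e^{x}-1)$ (anions), with
$x = \kappa|\Delta\varphi|$, $\Delta\varphi = 30$ mV,
$\kappa = e/k_BT \approx 0.0374$ /mV; divalent species take $2x$;
zwitterions count as neutral. Implementation note: the weights are
evaluated with `expm1` so the $E \to 1$ limit at small $\Delta\varphi$
holds to machine precision. The secondary pore population is, as
specified, neither size- nor charge-restricted; whether it should
saturate for very large solutes is left exactly as the printed model
has it.

**Cytosol.** A crowded aqueous layer, $R = h_{cyt}/(0.25\,D_{aq})$,
with $h_{cyt} = 15\ \mu m$ from averaged spherical-cell volumes and the
factor 0.25 from measured cytosolic diffusivity retardation.

**Filter.** $R = h_{filter}/(\varepsilon_{filter} D_{aq})$ with 10 μm
pore length and porosity 0.13 ("translucent"; set
`eps_filter = 0.05` for "clear" filters).

**Membrane.** The rate-limiting slab is the alkane-like interior,
approximated as 15 Å of hexadecane:
$P_m = K_{hexw} D_{hex} / h_{hex}$. Partitioning into the *whole*
membrane (headgroup-dominated for polar solutes) deliberately does not
enter here — the resistive region is the part of the membrane the
solute likes least. The basolateral resistance is $1/(f_n P_m)$; the
apical one is 24-fold smaller because microvilli amplify the apical
area. The factor is applied to every chemical: for lipophilic solutes
the resulting $P_m$ overestimate is harmless since their transport is
ABL-limited anyway.

**Lateral.** $R_{lateral} = h_{lat}\,\phi / (f_n K_{lipw} D_{lat})$.
Here the liposome-water coefficient $K_{lipw}$ *is* appropriate — a
solute diffusing laterally travels in whichever membrane region it
prefers. $h_{lat} = \tfrac{\pi}{2} h_{cyt} \approx 24\ \mu m$ (half the
circumference of a spherical cell) and the space-restriction factor
$\phi = r^2/((r + h_m)^2 - r^2) \approx 682$ (with $r = h_{cyt}/2$,
$h_m = 55$ Å) is the top-view area ratio of cytosol disc to membrane
annulus; it multiplies the resistance as the inverse of a porosity,
which is the orientation consistent with reported pathway-total
magnitudes.

## Parameters worth knowing about

| parameter | default | units | role |
|---|---|---|---|
| `chi_uwl`, `alpha` | 2e-6, 0.6 | cm/s, — | UWL hydrodynamics |
| `default_rpm` | 150 | rpm | stirring floor/default |
| `eps_over_delta`, `eps_over_delta2` | 0.78, 0.05 | 1/cm | pore populations |
| `r_pore` | 12.9 | Å | primary pore radius |
| `delta_phi`, `kappa` | 30, 0.037414 | mV, 1/mV | pore field |
| `h_cytosol`, `cytosol_d_factor` | 15 μm, 0.25 | | cytosol |
| `h_filter`, `eps_filter` | 10 μm, 0.13 | | filter |
| `h_hexlike`, `h_membrane` | 15, 55 | Å | membrane slab / full height |
| `microvilli_factor` | 24 | — | apical amplification |
| `ionized_cutoff` | 1e-4 | — | fully-ionized rule |
| `d_lateral_default`, `lateral_enabled` | 1e-8 cm²/s, TRUE | | lateral route |

`kappa` is stored at its printed reference value 0.037414 /mV;
`derive_kappa(310)` recomputes it from $F/(N_A k_B T)$ and agrees to
three significant figures (0.0374). The difference is far below any
observable effect.

**D_lateral** has no per-chemical model here: it is accepted as an
input column, with a configurable constant default of $10^{-8}$ cm²/s —
the order of magnitude of lipid lateral diffusion in fluid bilayers
(~1 μm²/s). Because this input is the least constrained part of the
model (and the lateral route rarely dominates — in the reference
analysis it mattered for only a handful of chemicals, with the
cytosolic route equally relevant within model uncertainty),
`lateral_enabled = FALSE` removes the route entirely.

## Route classification

`classify_routes()` labels each chemical by the pathway with the
smallest total resistance; ties (measure-zero, but tests need
determinism) break in the order cytosolic, paracellular, lateral. For
cytosolic-dominant chemicals the main barrier is the largest of UWL,
the two membranes summed, cytosol and filter. The broad pattern the
model produces: permanently ionized chemicals go paracellular;
lipophilic neutrals are cytosolic and UWL-limited (which pins
$P_\mathrm{app}$ near $3/R_{UWL} \approx 10^{-4}$ cm/s); very polar or
highly ionized — but not fully ionized — chemicals are cytosolic and
membrane-limited.

## Dataset curation and evaluation

`curate_records()` reproduces the passive-data curation rules: records
with efflux ratio ≥ 2 are removed (active transport); remaining
replicates — including opposite transport directions — are averaged as
arithmetic means of *linear-scale* $P_\mathrm{app}$, first within a
source, then across sources and cell lines; records stirred at ≥ 150
rpm keep their reported speed and are modeled separately per distinct
speed, so one chemical can legitimately appear twice. Metrics are RMSE
in log10 units and $R^2$ as squared Pearson correlation; since that
definition is a convention choice, `fit_metrics(..., method = "cod")`
offers the coefficient-of-determination variant, which also penalizes
systematic offsets. `evaluate_dataset()` accepts an exclusion list for
chemicals whose speciation input is known to be unreliable.

`blm_evaluate()` validates the membrane submodel in isolation against
black-lipid-membrane measurements of intrinsic $P_m$ (UWL-corrected,
artifact-free single bilayers), after excluding molecules below 50
g/mol: such small solutes permeate faster than the homogeneous
solubility-diffusion model predicts (polymer-like rather than
liquid-hydrocarbon membrane response), a documented deviation handled
by exclusion rather than by modifying the slab model.

## What the synthetic generator does and does not emulate

`generate_chemicals()` samples descriptors uniformly over the ranges
the model is meant to cover (MW 50–800, log $K_{hexw}$ −8 to 4, log
$K_{lipw}$ −1 to 6), aqueous diffusivities from a log-linear MW
scaling with mild scatter, $D_{hex}$ within a factor ~4 of $D_{aq}$,
and speciation from archetypal chemical classes (neutral, acid, base,
zwitterionic, permanent ion, diprotic), always injecting the corner
cases — neutral lipophile, neutral hydrophile, permanent cation/anion,
pure zwitterion, dication — so every classification branch is
exercised. `generate_pseudo_experiment()` pushes a table through the
forward model and adds Gaussian log10-noise (default 0.3, the scale of
within-source replicate scatter in real data).

What this shows, and what it does not: zero-noise closure (RMSE 0,
$R^2$ 1) and noise tracking demonstrate that curation, prediction and
scoring are mutually consistent — they say nothing about accuracy on
real chemicals, because the pseudo-experiments are generated by the
model itself. Synthetic descriptors are also sampled independently,
whereas real descriptors are strongly correlated (lipophilic chemicals
tend to be larger and slower-diffusing), and no active transport,
metabolism or lysosomal trapping is simulated. Testing against real
data requires transcribed experimental descriptor tables via
`read_descriptors()`/`read_experiments()`.

Test and example problem sizes (a few hundred synthetic chemicals, 500
for the closure checks) were chosen so the whole suite runs in seconds
while keeping Monte-Carlo noise on the recovered RMSE below a few
percent.

## Numerical choices and degenerate inputs

* Excluded pathways are represented by exact `Inf` resistances, never
  large sentinels; `total_papp()` treats $1/\infty = 0$ and errors only
  if all three pathways are closed.
* The Renkin polynomial is clamped to 0 at $\rho \ge 1$.
* Field-factor weights use `expm1` for small-argument accuracy.
* All-zero speciation rows, non-positive descriptors, and diffusion
  coefficients above $10^{-3}$ cm²/s (impossible for molecular solutes
  in condensed phases) are rejected with the field named.
* Pathway sums and the parallel combination are plain floating-point
  additions; agreement with an independent Kirchhoff node-equation
  solve is part of the test suite at $10^{-10}$ relative tolerance.

## A worked example

```{r example}
tbl <- generate_chemicals(8, seed = 1)
pred <- predict_papp(tbl)
pred[, c("name", "log_papp", "dominant_route", "cytosolic_main_barrier")]
```

```{r example2}
rec <- generate_pseudo_experiment(tbl, noise_sd = 0.3, seed = 2)
evaluate_dataset(tbl, rec)
```

## Known limitations

* Merging Caco-2 and MDCK into one parameterization imports up to an
  order of magnitude of inter-assay spread; predictions inherit that
  uncertainty floor.
* The UWL term depends only on stirring speed; assays with unusual
  geometries or unreported agitation are all mapped to one nominal
  hydrodynamic state.
* Within a dominant-route class, much of the experimental variance is
  not explained; the model's value lies chiefly in classifying the
  controlling barrier and pinning the right order of magnitude.
* No active transport, efflux correction, metabolism, or pKa /
  speciation prediction: species fractions are inputs.
* The lateral route rests on the least certain inputs ($D_{lat}$,
  $\phi$); it is retained for completeness but can be disabled, and
  conclusions should not hinge on it.
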