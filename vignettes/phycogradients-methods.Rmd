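---
title: "Modelling nutrient gradients around algal cells and across porous co-culture microplates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nutrient gradients around algal cells and across porous co-culture microplates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycogradients)
```

## The problem

A phytoplankton cell photosynthesises, exudes dissolved organic carbon
(DOC) and takes up inorganic nutrients such as nitrate. Diffusion then
imposes two opposing spatial gradients around the cell: DOC is enriched
towards the cell (the *phycosphere*) and nitrate is enriched away from it.
Porous-walled co-culture microplates reproduce the same pair of gradients at
millimetre scale: an algal culture in a central well consumes nitrate
diffusing in from an external medium reservoir and exports DOC outward
through nanoporous hydrogel walls, so bacteria incubated at different
distances experience different mixtures of organic and inorganic nutrients.

`phycogradients` implements both scales of this picture, a synthetic
algal–bacterial co-culture generator layered on top of them, and the
statistics used to quantify spatial responses. Everything is computable from
the shipped parameter presets; no experimental data are required.

## Phycosphere model

For a cell of radius $R$ releasing DOC at a constant per-cell rate $Q$
(fmol C cell$^{-1}$ d$^{-1}$) into a medium with diffusivity $D$ and
background concentration $C_\infty$, the steady spherically symmetric
diffusion equation gives

$$C(r) = C_\infty + \frac{Q}{4\pi D r}, \qquad r \ge R.$$

Nitrate is the sink mirror image with an effective uptake rate saturating at
the bulk concentration (Michaelis–Menten with half-saturation $K_m$):

$$C(r) = \max\!\left(0,\; C_\infty - \frac{U_{\mathrm{eff}}}{4\pi D r}\right),
\qquad U_{\mathrm{eff}} = U\,\frac{C_\infty}{C_\infty + K_m}.$$

A full Robin boundary condition would couple the surface concentration back
into the uptake rate; the explicit $U_{\mathrm{eff}}$ form was chosen
because it is closed-form, differs only quantitatively near a strongly
depleting cell, and keeps the source/sink symmetry exact (the test suite
verifies both solutions against an independent finite-volume discretisation
of the same boundary-value problem to a relative error below $10^{-3}$).

Profiles are computed on a log-spaced grid starting exactly at the cell
radius and extending to 100 radii (`defaultRGrid`), and can be normalised by
their maxima (`normalizeProfile`) for cross-scale comparison. The
surface-to-far-field ratio is the *fold decrease* (`foldDecrease`).

### Species presets

The shipped table (`speciesPresets()`) contains four taxonomically diverse
laboratory species (a cyanobacterium, a prasinophyte and two diatoms) with
per-phase exudation rates, uptake kinetics and bulk concentrations. All rows
are flagged `literature default (calibrated)`: per-cell exudation is at the
scale reported for cells of that size (tens of fmol C cell$^{-1}$ d$^{-1}$
for micron-sized cells, hundreds for a large diatom), and the relevant
background is the *labile* exudate-class DOC pool, which in seawater is
nanomolar — not the ~70 µM total-DOC pool, most of which is refractory. With
those two scales the excess-to-background ratio, and hence the fold
decrease over the default grid, lands in the 3–7 range characteristic of
phycosphere gradients for all four species in both growth phases. Growth
phase toggles the bulk values: nominal f/2 nitrate (882 µM) in exponential
phase versus a depleted (zero) nitrate background with proportionally
elevated exudation and labile background in stationary phase, so the
nitrate profile collapses to zero while the DOC fold is phase-invariant.

The stirring number $lv/D$ (`stirringNumber`) and the Péclet number $vL/D$
(`pecletCheck`) are provided as transport diagnostics; both are small in the
regimes modelled here, which is what justifies a diffusion-only treatment.

## Microplate model

Wells are well-mixed compartments (the experimental protocol mixes by
pipette before sampling) connected by porous walls and, for outer wells, by
a wall to the external reservoir. Each wall carries a Fickian flux

$$J = D_{\mathrm{eff}}\,A\,\frac{C_i - C_j}{L}$$

with wall thickness $L = 0.9$ mm, an effective shared cross-section
$A = 10$ mm$^2$, and $D_{\mathrm{eff}} = 0.5\,D$ (see below). Per well the
model integrates

* DOC: wall fluxes $+\,Q_a N$ (algal exudation) $-$ bacterial consumption,
* nitrate: wall fluxes $-\,U_a \frac{C_N}{C_N + K_u} N$ (algal uptake) $-$
  bacterial consumption,
* alga: $\dot N = \mu_{\max} \frac{C_N}{C_N + K_m} N$ (Monod on nitrate, no
  hard carrying capacity — limitation is purely nutrient-supply driven),

as a stiff ODE system (`deSolve::lsoda`, relative tolerance $10^{-8}$,
absolute $10^{-10}$ µM — tight enough that sealed-plate mass conservation
holds to $10^{-8}$ relative over 20 days, which a looser pair does not
guarantee). Negative states abort the run rather than being clipped. The
reservoir is an infinite bath by default (its ~25 ml dwarfs 100 µl wells); a
finite-volume reservoir is available for spent-medium scenarios.

### Layout presets

* `hex7` — one centre + six outer wells (75 µl) at 8 mm; all wells carry the
  alga; only outer wells face the reservoir. Used for the growth experiment.
* `isolate_rings` — central algal well plus six radial arms with bacterial
  wells at 7, 14 and 21 mm.
* `community_layers` — centre well (alga or medium control), bacterial layer
  1 at 8 mm and layer 2 at 16 mm, blank wells at 24 mm facing the reservoir.
* `single_well`, `custom` — testing and free-form graphs.

Shared-wall areas and reservoir-facing areas are stored explicitly on every
edge so the geometry assumptions are inspectable in the layout object.

### Calibration constants

Three constants are calibration, fixed once and used everywhere:

* **Porosity/tortuosity factor 0.5.** HEMA-based hydrogels are
  high-water-content nanoporous materials; literature reduction factors for
  small solutes span roughly 0.2–0.7. 0.5 reproduces the reference model
  outputs (below) and is the package default (`wallParams`).
* **Reservoir-facing wall area $0.8 A$.** Only part of an outer well's arc
  faces open medium below the liquid line.
* **Algal parameters** (`algalPopulation`): $\mu_{\max} = 1.0$ d$^{-1}$
  (standard laboratory-scale diatom maximum), per-cell nitrate uptake
  $U_a = 60$ fmol N cell$^{-1}$ d$^{-1}$ — giving a nitrogen quota
  $U_a/\mu_{\max} = 60$ fmol N cell$^{-1}$, which makes a sealed 882 µM
  batch top out near $1.5\times10^7$ cells ml$^{-1}$, the observed batch
  scale — and exudation $Q_a = 60$ fmol C cell$^{-1}$ d$^{-1}$.

Under these conditions the 7-day community-layout run gives a
centre-to-outermost DOC fold of ≈ 5.2 and centre-well nitrate depletion
(below 1 % of initial) at day ≈ 5.7; both are recomputed by
`scripts/acceptance.R` and asserted in the test suite.

## Synthetic co-culture generator

The study organisms motivate two growth strategies (`TaxonParams`):

* **Exudate specialist** (*Algoriphagus*-like): efficient Monod growth on
  algal DOC only ($\mu_{\max} = 2.5$ d$^{-1}$, $K_m = 50$ µM C), no use of
  inorganic N.
* **Generalist** (*Marinobacter*-like): weak DOC growth
  ($\mu_{\max} = 0.6$ d$^{-1}$) plus growth on nitrate
  ($\mu_{\max} = 0.25$ d$^{-1}$), modelled as *additive substitutable*
  resources — the simplest form supporting the two-niche picture.

Both have first-order mortality (0.1 d$^{-1}$) and fixed yields
(cells per µmol of substrate); resource drawdown is growth/yield, verified
against an exact accounting identity in the tests. Inocula follow the
experimental protocol: $4\times10^6$ (generalist) and $4\times10^5$
(specialist) cells ml$^{-1}$, with the alga pre-grown to $10^7$ cells
ml$^{-1}$ in the isolate design. In the isolate layout each strain occupies
its own radial arms (`placement = "arms"`), matching monoculture wells; the
community preset inoculates all eight taxa into every bacterial well.

One modelling choice deserves emphasis: the f/2 reservoir carries a small
labile-DOC background (10 µM C, representing vitamins, EDTA-organics and
carry-over metabolites). This is what lets a generalist grow modestly in
control plates (as observed) and what creates the early-phase outward
resupply gradient in control plates — at realistic bacterial N quotas,
bacterial nitrate drawdown is orders of magnitude too small to carve an
N gradient against reservoir resupply within six days, so the early
control-plate spatial pattern is carried by the labile-carbon gradient
instead. The observable consequence (generalist abundance non-decreasing
with distance at day ~6 in controls) is the same.

With the default calibration, the 20-day co-culture reproduces the
qualitative spatial fingerprint of the study system: late-phase decrease of
both strains with distance from the alga; a specialist distance fold that
exceeds the generalist's by far more than 10×; generalist dominance in the
outermost well (≈ 100×); and the early control-plate pattern above. Fold
*magnitudes* are calibration-dependent and are reported, not fitted.

Observation layers turn trajectories into data:

* `sampleCytometry` — bead-calibrated Poisson event counts; the
  back-calculation `cells/beads × bead density × dilution` is unbiased to
  < 2 % at ≥ 10⁴ expected events (ratio-estimator bias ~ 1/E[beads]).
* replicate noise — multiplicative lognormal with configurable geometric SD
  (default 1.3), matching the geometric-SD error model used for abundance
  replicates.
* `toRelativeAbundance` — multinomial read sampling at a given depth with
  optional mean-one lognormal overdispersion per taxon; with overdispersion
  0 and infinite depth the proportions equal the density ratios exactly.

Every stochastic operation requires an explicit integer seed; unseeded
calls are an error in library mode.

### What the generator does and does not emulate

It emulates: two-scale diffusion physics, Monod growth and resource
competition, flow-cytometry-like counting, compositional 16S-like tables
with replicate and sequencing noise. It does not emulate: attachment of
bacteria to algal cells (excluded by the experimental design itself),
chemotaxis and motility, DOC chemical heterogeneity (a single labile pool
stands in for a spectrum of compounds with different diffusivities),
pH/acclimation transients at the start of incubations, evaporation
(volumes constant; ~95 % retention was observed over two weeks), or
sequencing-pipeline artefacts (chimeras, primer bias, taxonomy error).
Passing tests therefore demonstrate internal consistency of the model and
pipelines under these idealisations, not fidelity to any particular
experimental replicate.

## Statistics layer

* `specificGrowthRate` — $\mu = (\ln N_2 - \ln N_1)/(t_2 - t_1)$ per
  replicate, then mean ± sd.
* `geometricStats` — $\exp(\mathrm{mean}(\log v))$,
  $\exp(\mathrm{sd}(\log v))$.
* `foldChangeByDistance` — ratio of innermost to outermost geometric-mean
  density with a detection floor (default $10^3$ cells ml$^{-1}$) clamped
  *before* the geometric means, so negligible outer growth yields a large
  finite fold rather than infinity; the trend statistic is the Spearman
  correlation of log density with distance.
* `welchTTest` — implemented from the Welch statistic and the
  Welch–Satterthwaite degrees of freedom (two-tailed); cross-checked against
  the reference implementation to $10^{-10}$ and calibrated to a 4–6 %
  type-I error at $\alpha = 0.05$ in the suite.
* `twoWayAnovaInteraction` — balanced factorial sums of squares from cell
  means; the decomposition $SS_{tot} = SS_A + SS_B + SS_{AB} + SS_E$ is
  asserted exactly, F and p from the F distribution. Unbalanced or empty
  cells are an error pointing at the permutation alternative. Applied to
  log densities by default (consistent with the multiplicative error
  model; whether the original tests used raw or log densities is not
  documented, so the package states its choice).
* `permutationTrendTest` — Spearman statistic, label permutation, p-value
  with the +1 correction; distribution-free alternative for small
  unbalanced spatial designs.
* `adjustFDR` — Benjamini–Hochberg across genera, reported alongside raw
  p-values since no multiple-testing convention is documented for the
  original per-genus comparisons.

## Pipelines and configuration

`runExperiment()` chains the modules into four named pipelines
(`fig3_growth`, `fig4_model`, `fig5_isolates`, `fig6_community`), writing
tidy CSVs plus a JSON manifest (config snapshot, seed, package version,
output checksums) sufficient to re-run deterministic stages bit-identically.
Configuration is nested YAML (`loadConfig`/`saveConfig`) validated against
the documented defaults: unknown keys are rejected by name, and the wall
porosity factor is bounded by 1 (effective diffusivity cannot exceed free
solution).

## Numerical choices and degenerate inputs

* Stiff integration (lsoda), rtol $10^{-8}$ / atol $10^{-10}$ µM; no state
  clipping — negatives beyond tolerance abort.
* Depletion times are linearly interpolated between output points; exact
  grid-point crossings are returned as-is; never-depleted wells give +Inf.
* All-zero profiles normalise to all-zero with a warning (no 0/0).
* Zero-variance Welch inputs: equal means give p = 1, separated means p = 0.
* Zero total density in a relative-abundance sample yields a flagged
  all-zero row.
* Well distances are rounded to $10^{-6}$ mm when layouts are built so that
  symmetric rings group exactly.

## Problem sizes

The test suite and acceptance script use the study-scale problems
throughout: 19–25-well plates over 7–20 simulated days, $10^4$ null
replicates for test calibration, 999-permutation trend tests, and
$10^3$–$10^5$ Monte-Carlo draws for the estimator checks. The full suite
runs in about a minute on one core.

## Known limitations

* The compartment approximation ignores in-well gradients and meniscus
  effects; it is consistent with pipette mixing but cannot resolve
  sub-well structure.
* Growth-phase coupling is one-way: bacteria do not feed back on algal
  growth (micronutrient cross-feeding off by default).
* The additive-substitutable resource model lets a generalist grow on
  nitrate using an implicit carbon source; the labile-DOC background makes
  this quantitative, but a stoichiometric C×N co-limitation model would be
  the natural refinement.
* Fold magnitudes from the co-culture generator are calibration artefacts;
  only their ordering and signs are biologically meaningful claims.

## Session

```{r}
sessionInfo()
```
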