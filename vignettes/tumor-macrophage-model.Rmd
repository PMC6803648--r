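---
title: "A hybrid continuum-discrete model of liver tumor growth with macrophage polarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid continuum-discrete model of liver tumor growth with macrophage polarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tamsim)
```

## The model

`tamsim` simulates the growth of a vascularized tumor lesion seeded in liver
tissue over about two weeks, on a single 2 mm x 2 mm tissue panel discretized
as a regular node-centered lattice. It couples three layers:

1. **Continuum fields.** Oxygen, four diffusible cytokines (TNF-alpha,
   TGF-beta1, tumor angiogenic factor TAF, and the M2 growth factor F),
   matrix-degrading enzymes (MDE), ECM density, and the Darcy
   pressure/velocity of the tissue.
2. **A vessel network.** An evenly spaced capillary grid (denser for the
   metastatic case, mimicking the highly vascularized liver) plus angiogenic
   sprouts launched where TAF is high, advancing up the TAF gradient on the
   lattice and anastomosing when they meet another vessel.
3. **Discrete macrophage agents.** Naive monocytes extravasate from
   peritumoral vessels in proportion to the local TAF gradient, migrate by
   biased random walk, and polarize terminally to M1 (driven by TNF-alpha)
   or M2 (driven by TGF-beta1) inside the tumor microenvironment.

### Tissue regions and growth

Each node is normal tissue, proliferating tumor, hypoxic (quiescent) tumor,
or necrotic debris. Classification is by oxygen: necrotic below the necrotic
threshold (irreversibly), hypoxic below the local quiescence level
`Q_OL`, proliferating above it. The net proliferation rate is

* normal tissue: 0,
* proliferating: `(lambda_M + lambda_M2) * sigma - (lambda_A + lambda_M1)`,
* hypoxic: `lambda_M2 * sigma - (lambda_A + lambda_M1)`,
* necrotic: `-G_N`,

so M1 macrophages kill (through the short-ranged NO field `lambda_M1`,
cell-cycle independent, hence acting on both cycling and quiescent tissue)
and the M2 growth factor F boosts proliferation (`lambda_M2`, a logistic
ODE with ceiling `lambda_M + lambda_M2 <= 1`) and transiently lowers the
quiescence threshold toward `Q_OL_min`. Note the ceiling: with
`lambda_M = 1` the M2 term would be identically zero, which is why the
default mitosis rate is 0.8/day.

Tissue moves with the Darcy/haptotaxis velocity
`v_c = -mu grad P + chi_E grad E`, where pressure solves
`-div(mu grad P) = lambda_p - div(chi_E grad E)` with zero-Neumann
boundaries, a zero-mean gauge, and the domain mean of `lambda_p` removed
for discrete compatibility. Velocities live on cell faces so that the
discrete divergence identity `div v_c = lambda_p - mean(lambda_p)` holds to
machine precision. One consequence worth stating: when `lambda_p == 0` the
discrete solution satisfies `mu P = chi_E E + const` exactly, so haptotaxis
is exactly screened by the induced pressure and `v_c == 0`; haptotaxis
shapes the flow only in combination with growth sources.

The tumor interface advances stochastically: a normal node adjacent to the
tumor converts with probability `v_n dt / h` given the outward face
velocity `v_n`; boundary tumor nodes accumulate a shrinkage debt from
negative `lambda_p` and revert to normal when a full cell equivalent has
been lost. The debt heals toward zero at 0.5/day, so only sustained local
mass loss erodes the boundary — this damps a collapse instability in which
a few transient M1 visits could otherwise erase a small lesion. Necrotic
nodes are permanent: the debris field degrades (`G_N`) as a pressure sink,
but necrotic area never decreases.

### Transport solvers

All diffusible species are solved in quasi-steady state with a sparse
5-point Laplacian (mirrored ghost nodes give zero-Neumann boundaries) and a
direct sparse factorization; at the default 61 x 61 this is exact to solver
tolerance (the test suite compares against a dense direct solve at 1e-8
relative). Oxygen is supplied at vessel nodes at a rate proportional to
hematocrit, the oxygen deficit `(1 - sigma)`, and
`max(0, 1 - P / P_eff)` — high interstitial pressure shuts extravasation
down. Because production saturates as concentrations approach 1 and the
circulation washout is applied proportionally to the concentration, every
solved field obeys a discrete maximum principle and lies in `[0, 1]`
without clipping; a bound violation raises an error rather than being
silently clamped. Only the MDE field is stepped explicitly in time
(its CFL bound `dt <= h^2 / (4 D_M)` is validated in the configuration);
ECM has no transport and is a pointwise ODE.

### Cytokine geometry and polarization

The polarization rule is threshold-based and terminal: a naive agent inside
the tumor microenvironment (tumor mask plus an 8-node margin) commits with
probability `polarization_prob * dt` to the species whose threshold it
exceeds; if both TNF-alpha and TGF-beta1 exceed their thresholds, the larger
normalized excess `(c - theta) / theta` wins, with ties to M1.

The spatial structure that makes primary tumors M2-balanced and metastatic
tumors M1-dominated is carried by the two cytokine profiles:

* TNF-alpha is short-ranged (`D = 0.02` mm^2/day, decay 2/day) and secreted
  in the inflamed hypoxic core, so its high-excess region is the lesion
  interior. The metastatic case produces it at 10x the primary rate — the
  fold measured in the indirect co-culture ELISA — which pushes the
  TNF-dominant region out across the whole microenvironment.
* TGF-beta1 is long-ranged and flat (`D = 0.15` mm^2/day, decay 0.8/day),
  secreted by all viable tumor tissue, and reaches well into the peritumoral
  margin, where TNF-alpha has already decayed. That annulus is where M2
  commitment happens.

Naive agents extravasate at peritumoral vessel nodes only (intratumoral
capillaries are treated as co-opted and non-recruiting); without this
restriction the TAF-gradient weighting drops most monocytes straight into
the TNF-high core and the primary M1:M2 balance collapses to all-M1.
Polarized M1 agents acquire an additional inward bias along a concentric
field (1 at the lesion centroid, falling linearly to 0 at the boundary),
reproducing their deeper infiltration; their NO kill rate acts within a
3-node Chebyshev vicinity at `lambda_NO = 0.006`/day per covered node.
The vicinity is wider and the rate smaller than a strictly nearest-node
reading of the short NO range, because the growth restriction of the
metastatic lesion is carried by margin-dwelling M1 whose NO must reach the
rim; the product of rate and coverage is what the endpoint calibration
constrains.

### Synthetic assays and calibration

The wet-lab inputs are replaced by a synthetic-assay module:

* `generate_elisa()` draws replicate TNF-alpha/TGF-beta1 panels for
  (naive, M1, M2) x (no tumor, primary, metastatic) with the measured fold
  structure — TNF 5x higher with M1 than M2 in every condition, 10x higher
  for metastatic-with-M1 than primary-with-M1, TGF flat except a <= 1.3x
  elevation for primary-with-M1 — under lognormal noise of a configurable
  CV. Absolute units are arbitrary; only ratios enter the model.
* `calibrate_cytokines()` maps panel means back to production rates
  (metastatic TNF = primary baseline x measured fold; TGF shared across
  tumor types). With CV 0.2 and 6 replicates the recovered fold lies in
  [8, 12] for ~92% of random draws; this is a property of the prescribed
  ratio-of-means estimator, not of the implementation.
* `calibrate_ecm()` root-solves the degradation rate so the scalar steady
  state of the ECM balance (with MDE at its uncoupled 0-D fixed point
  `lambda_prod / (lambda_prod + lambda_decay)`) gives the requested
  transitional:control density ratio. The default target 1.5 is a
  calibration choice, not a measured value; the shipped per-construct rates
  (1.5/day control, 1.0/day transitional at production 0.3/day) sit exactly
  on these steady states, so the far field is stationary.
* `normalize_migration()` divides transwell counts by their control-group
  mean, the normalization used for the migration readouts.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `lambda_M`, `lambda_A` | 0.8, 0.05 | 1/day | native mitosis/apoptosis |
| `necrotic_threshold` | 0.22 primary / 0.13 metastatic | — | lower metastatic value yields hypoxic, not necrotic, cores |
| `lambda_tumor` (oxygen uptake) | 10 | 1/day | sets the viable rim width |
| `line spacing` | 0.50 primary / 0.43 metastatic | mm | denser metastatic capillary grid |
| `TNF lambda_production` | 2.5 primary / 25 metastatic | 1/day | the ELISA 10x fold |
| `tnf_threshold`, `tgf_threshold` | 0.13, 0.12 | — | polarization thresholds |
| `polarization_prob` | 1.1 | 1/day | commitment rate in the microenvironment |
| `lambda_NO` | 0.006 | 1/day | M1 kill per covered node (3-node vicinity) |
| `lambda_F` | 1.5 | 1/day | M2 trophic effect rate |
| `extravasation_rate` | 1 | per vessel node/day per unit TAF gradient (1/mm) | recruitment strength |

The shipped problem size is a 61 x 61 lattice (h = 0.033 mm) over 13
simulated days at `dt = 0.1` day: one run takes roughly 10 seconds on a
single CPU and the full eight-case, three-replicate design about six
minutes. Parameters are stored in physical-ish units (mm, days,
concentrations normalized to vascular/saturation levels) so they transfer
across lattice resolutions; the vessel line spacings are rounded to nodes,
and the capillary lines are placed symmetrically about the center so the
central line always crosses the seed.

## What the synthetic data do and do not show

The generator encodes exactly the fold structure and noise model described
above: it emulates *ratios* between conditions, not absolute cytokine
biology, plate effects, or co-culture kinetics. Passing the
parameter-recovery tests therefore shows that the calibration pipeline is
consistent (generate -> calibrate recovers what was configured), not that
the model would recover folds from real ELISA data. Likewise the simulated
endpoints are reproduced under the shipped parameter set, many entries of
which are calibration choices rather than measured quantities; they
demonstrate internal consistency of
the mechanism (M1 cytotoxicity restricting metastatic growth; cytokine
geometry setting the polarization balance), not a validated prediction for
liver tissue.

## Numerical and design choices

* **Operator splitting order** within a step: oxygen solve, region
  classification, cytokine solves, sprouting, agent steps, effector ODEs,
  MDE/ECM steps, proliferation field, pressure/velocity, interface advance.
  Quasi-steady fields must precede classification and agent decisions; the
  rest of the order is a fixed convention.
* **Washout term**: applied as `-lambda_circ * 1_vessel * C` (proportional
  to the concentration) rather than as a constant sink, which would drive
  concentrations negative.
* **Hypoxic oxygen uptake** is linear, `q_sigma * sigma`.
* **Degenerate inputs**: an empty tumor mask yields a no-op step apart from
  the field solves; an empty agent list yields zero fractions flagged
  `empty`; a singular pressure system cannot surface because the gauge is
  fixed internally.
* **Determinism**: all stochastic elements (sprouting, extravasation,
  migration, polarization, interface conversion) draw from the single R RNG
  stream seeded by `rng_seed`; identical configurations produce
  byte-identical results. Polarized and naive runs of the same seed diverge
  stochastically (polarization consumes draws), so comparisons between arms
  are statistical, never pathwise.
* **Stochastic endpoints**: with a few hundred agents per run, day-13
  population fractions carry a per-run SD of several percentage points and
  the primary-vs-metastatic radius difference roughly 7-10 points at
  n = 3; the defaults were chosen so the expectations sit on the reported
  endpoints, and replicate means should be read with those errors in mind.
  The dominant variance sources are angiogenic sprouting and macrophage
  movement and polarization.

## Known limitations

2D lattice only; sprout tips move on the 4-neighborhood rather than
off-lattice; intravascular flow is reduced to a constant hematocrit and a
pressure-modulated extravasation factor; vessels are never occluded or
regressed; agents neither die nor emigrate, so population fractions are
cumulative; the M2 phenotype is a single state rather than a spectrum; and
mechanics beyond Darcy pressure (residual stress, viscoelasticity) are out
of scope.

## A short run

```{r, eval = FALSE}
cfg <- default_config(tumor_type = "metastatic", ecm_type = "cECM",
                      polarization_enabled = TRUE, rng_seed = 7)
run <- run_simulation(cfg)
print(run)
tail(run$series)
plot_state_panels(run$final)
```
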