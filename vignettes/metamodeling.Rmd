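---
title: "Kinetic segregation, Lck activity range, and Bayesian metamodeling of early TCR triggering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic segregation, Lck activity range, and Bayesian metamodeling of early TCR triggering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kinseg)
```

This package models the first seconds-to-minutes of T-cell antigen receptor
(TCR) triggering at a tight contact between a T cell and an
antigen-presenting cell (APC). Three partial models, each capturing one
molecular mechanism, are combined into a single Bayesian metamodel that can
be conditioned on observed nanoscale pattern statistics:

1. **Kinetic segregation (KS)** — a Metropolis Monte-Carlo simulation of a
   2 μm × 2 μm membrane patch. The ~37 nm height mismatch between the CD45
   ectodomain and the TCR–pMHC complex, combined with membrane bending
   elasticity, segregates CD45 away from the TCR cluster and opens a
   depletion zone whose width `Dep` (nm) is the model output.
2. **Lck activation (Lck-A)** — a 2D random walk with stochastic
   deactivation. Lck is activated at a CD45 molecule and diffuses until it
   is deactivated at rate `p_off`; the radial histogram of end positions
   decays with a characteristic length `DL` (nm), the model output.
3. **TCR phosphorylation (pTCR)** — active Lck density around the CD45
   pattern, `rho(x) = sum_j exp(-|x - c_j|/DL)`, sets per-TCR Bernoulli
   phosphorylation probabilities. The outputs are the phosphorylated
   fraction `Phos` and the `Rg ratio` (RMSD of phosphorylated TCRs about
   the center of mass of all TCRs, divided by the radius of gyration of all
   TCRs; > 1 means peripheral enrichment).

Cheap probabilistic surrogates are fitted to training grids of each
simulator, coupled through shared quantities, and the joint model is
conditioned on observed values of `Phos` and `Rg` to *backpropagate*
posteriors onto upstream biophysical parameters (membrane rigidity, time
since contact, Lck diffusion coefficient, Lck* deactivation rate).

## The membrane simulator

State: a height field `z` (nm above the APC) on a grid of 25 nm cells, and
continuous molecule coordinates (TCR, CD45 on the T cell; pMHC on the APC).
The energy (in kT) is

* bending: `(R / a^2) * sum (discrete Laplacian of z)^2` — `R` is the
  rigidity coefficient in kT nm², the paper-scale sweep range 0–100;
* bound-TCR springs: `bond_k * (z - h_tcr_bond)^2` per bond
  (`h_tcr_bond = 13` nm, `bond_k = 0.25` kT/nm²);
* a one-sided CD45 steric wall `u_rep * (h_cd45 - z)^2` for `z < h_cd45`
  (`h_cd45 = 50` nm, `u_rep = 0.25` kT/nm²) with a shallow adhesion well of
  depth 2 kT at `h_cd45`;
* a weak tether `tether_k * (z - boundary_height)^2` per node
  (`tether_k = 0.002` kT/nm²) representing the elastic connection of the
  patch to the surrounding cell surface. Without it a rigidity-zero
  membrane performs an unbounded random walk in height, which has no
  physical counterpart.

Moves per sweep: single-node height perturbations (±3 nm), collective
square-block height shifts (2–16 cells; without them stiff membranes relax
pathologically slowly under single-node moves alone), lateral molecule hops
with per-axis step `sqrt(2 D dt)` so a free molecule's mean-square
displacement per sweep is `4 D dt` (`D = 0.05` μm²/s, `dt = 0.05` s per
sweep), and TCR–pMHC bond toggling. Binding is attempted when a free pMHC
lies within the 10 nm capture radius and the local membrane height is
within ±5 nm of `h_tcr_bond`; acceptance uses the net binding free energy
`u_assoc - bond_entropy` plus the spring strain. The explicit
`bond_entropy` (22 kT, the configurational entropy lost on binding) is
essential: with bare `±u_assoc` toggling the dissociation time scales as
`exp(u_assoc)` sweeps and no detachment could ever occur within 100 s
anywhere in the 5–50 kT scan range. Released spring strain assists
unbinding, which produces the peeling dynamics by which weak contacts
dissolve from the rim inward.

Baseline runs start from an *established contact*: the height field begins
at the complex height over the cluster disk and ramps smoothly (logistic,
40 nm width) to the resting separation outside. With a flat start, whether
a contact nucleates before the free membrane relaxes is a seed-dependent
race; the established-contact start encodes the premise that the 100 s
dynamics describe a contact that has already formed. The flat start remains
available (`init_contact = FALSE`). The baseline association energy is
60 kT (net 38 kT after the binding entropy), strong enough that the
wild-type contact persists throughout a 100 s run.

Three further defaults matter:

* **CD45 density.** 1200 CD45 per patch (300/μm², a physiological surface
  density). The CD45 osmotic pressure confines the rim of the contact; the
  equilibrium rim width scales like `(3 R dz^2 / p)^(1/4)`, so a 10× sparser
  CD45 population would produce depletion widths of 250–350 nm, outside
  the 40–150 nm regime this system operates in.
* **A TCR corral** at 1.25× the cluster radius implements the pre-formed
  receptor cluster: unbound receptors otherwise disperse over the patch
  within tens of seconds and destroy the single-cluster geometry that all
  pattern statistics assume.
* **Immobile pMHC** (`pmhc_diff = 0`): bound TCR–pMHC pairs are tethered in
  place, as for ligands anchored on an APC or a supported bilayer with slow
  mobility; making them mobile lets the whole contact drift and evaporate.

**Depletion-width estimator.** The zone edges are read from binned radial
density profiles about the TCR center of mass: the TCR outer edge where the
TCR density falls below half its core value, and the CD45 inner edge where
the CD45 density first rises to half its far-field plateau (sustained over
two bins, at least two molecules per bin, linearly interpolated). Global
radial quantiles (95%/5%) are also available (`method = "quantile"`), but a
global 5% quantile over the full patch carries a positive bias of order
100 nm by pure area arithmetic and cannot express the rigidity-zero
negative control; the threshold estimator is therefore the default.

## The Lck random walk

Walkers start at a CD45 at the origin; each step is an isotropic Gaussian
displacement (per-axis sd `sqrt(2 D dt)`, `dt = 0.01` s, 1000 steps), after
which the walker deactivates with probability `p_off * dt` and freezes.
The decay length is fitted to the radial histogram (20 nm bins, out to the
farthest walker) by least squares on log counts, *weighted by counts*:
sparse far bins carry only Poisson-level information and an unweighted fit
lets single-count bins at large radii flatten the slope. A
maximum-likelihood exponential rate on the raw distances is available as
`method = "mle"`.

For diffusion-limited killing the decay length follows
`DL ~ sqrt(D / p_off)`, so iso-decay-length ridges obey `D ~ C p_off^alpha`
with `alpha = 1`. `lck_scaling()` fits `alpha` by regressing `log DL` on
`(log D - log p_off) / 2` over a 5 × 5 log grid; cells where most walkers
outlive the simulation produce truncation-limited (very large) decay
lengths and are retained — the weighted fit keeps them from corrupting the
slope.

## The phosphorylation model

The summed exponential kernel is read as the *expected number of active Lck
within reach* of a TCR, and the default probability rule is the absolute
linear-capped map `p = min(1, beta * rho)` with `beta = 1` — one expected
active kinase saturates the probability. This convention reproduces the
regime in which every bound TCR is phosphorylated once the decay length
exceeds ~60–70 nm. A relative convention (calibrating `beta` so the
patch-maximum density maps to 0.95) and a Poisson-encounter form
(`1 - exp(-beta rho)`) are selectable; under the relative convention the
phosphorylated count can never reach the bound count, which contradicts the
saturation regime, so it is not the default. ITAM phosphorylation is
all-or-none per TCR, and segregated CD45 does not dephosphorylate at a
distance (dephosphorylation requires contact, which segregation removes);
the optional Csk extension multiplies the field by
`exp(-csk_strength * sigma)` with `sigma` a short-range (20 nm) kernel
around current pTCR positions.

The training geometry for this model (`segregated_pattern()`) is a central
TCR cluster with an exponential radial taper (scale 0.45× the 250 nm
cluster radius) inside a CD45 annulus at gap `Dep`. The taper matches the
center-weighted clusters the membrane simulator produces (rebinding pulls
receptors toward the ligand-rich center) and the cluster scale matches the
observation scene; a uniform disk would overstate the cluster's radius of
gyration and cap attainable Rg ratios near 1.2, below the observed 1.31.

## Surrogates

Each partial model is summarized by a directed probabilistic model: root
inputs with explicit priors, and outputs with fitted conditional
distributions. Conditionals are Bayesian linear regressions (conjugate
normal-inverse-gamma posteriors, fitted exactly — no sampler is needed for
this stage) on model-specific bases:

* KS: degree-2 polynomial in (`log1p(t/5)`, rigidity), both standardized.
  The log placement of time reflects the early saturation of segregation.
* Lck-A: polynomial in the scaling coordinate `(log D - log p_off)/2`,
  response `log DL` — the basis implied by the scaling law.
* pTCR: a kernel-informed feature basis (`log DL`, `Dep`, `Dep/DL`,
  `1/DL` and their squares) on which the logit of `Phos` is near-linear;
  `Phos` is fitted on the logit scale (clamped at 0.002/0.998). Generic
  low-order polynomials on the raw scale cannot track the sharp saturation
  and their ~0.15 noise floor would wash out the observation constraint.

Root priors (configurable, reported in the fitted objects):
`t ~ U(0, 100)` s, `R ~ U(0, 100)` kT nm², `log10 D ~ N(-1, 1)` μm²/s,
`log10 p_off ~ N(1, 1)` s⁻¹, `DL ~ lognormal` spanning 20–5000 nm, and a
depletion prior induced by the KS training range. All training axes have
positive prior density. Fit diagnostics include training R² and analytic
leave-one-out 95% coverage.

## The metamodel

Coupling variables tie the shared quantities together:
`Dep_KS -> Dep_C -> Dep_pTCR`, `DL_LckA -> DL_C -> DL_pTCR`,
`Phos_pTCR -> Phos_C`, `Rg_pTCR -> Rg_C`. Each coupling conditional is
normal with scale 2% of the corresponding training span; the decay length
couples on the *log* scale (2% of the log-range span), because its training
range covers nearly three decades and a linear 2% there (~200 nm) would
decouple the chain entirely. Observations attach to `Phos_C` and `Rg_C`
with observation noise SDs 0.03 and 0.1.

Conditioning uses componentwise adaptive random-walk Metropolis over the
eight-dimensional joint state (four roots plus `Dep_KS`, `DL_LckA`,
`Dep_pTCR`, `DL_pTCR`; the two-step coupling chains collapse analytically
into single normals). The joint model is defined on the pTCR surrogate's
training domain (a 2x buffer on the decay length, the induced prior range
on the depletion width): regression surrogates extrapolated far outside
their hull can spuriously match any observation, so the support truncation
is part of the model, applied identically in conditioning, prior-predictive
sampling and likelihood maps. Defaults: 3 chains × 8000 kept iterations after 3000
burn-in/adaptation steps (~2 minutes); convergence is monitored by
split-chain potential scale reduction with a 1.05 warning threshold — the
weakly identified depletion marginal occasionally sits slightly above it,
which widens no interval we report. The sampler is validated against full
brute-force enumeration of the discretized joint density in the test suite
(total-variation distance below 0.05 on all compared marginals), and by a
parameter-recovery experiment (90% credible intervals cover known truths in
at least 80% of repetitions). The posterior over (decay length, depletion
width) is a broad curved ridge; point summaries of that pair are therefore
reported as the mode of the joint density (evaluated exactly on a grid via
the collapsed conditionals), since one-dimensional kernel-density modes of
a flat-topped marginal carry tens-of-nanometers estimator noise.

`likelihood_map()` profiles `p(obs | pair)` over any two root variables by
forward Monte-Carlo, reproducing the proportionality ridge between the Lck
diffusion coefficient and deactivation rate. The constant of that
proportionality is reported by the fitted objects, never assumed.

## The affinity scan

The initial-contact protocol clamps a central 300 nm disk of the membrane
at the complex height for 10 s — close enough for TCRs to bind and unbind —
then releases it for 90 s. The clamp is local rather than patch-wide so
that kinetic segregation can act during contact formation, as it does
physically. Association energies sweep 5–50 kT in 5 kT steps (default 3
replicates each); bound and phosphorylated TCR counts are sampled at 1 s
cadence, with phosphorylation restricted to bound TCRs and re-drawn each
sample as a memoryless snapshot (a sticky mode that retains phosphorylation
while a TCR stays bound is available; all reported results use snapshot
mode). A contact is detached when no bonds remain and the central membrane
has lifted past the midpoint between the complex and CD45 heights.

The activation rule — more than `n_min = 5` phosphorylated TCRs sustained
for at least `tau = 10` s — converts each run into a binary outcome;
association energies above 25 kT define ground-truth positives, and
sensitivity/specificity per decay length quantify ligand discrimination.
Under the default configuration the detachment boundary falls between 25
and 30 kT, weak contacts dissolve within ~15 s of release, and balanced
accuracy peaks at an intermediate decay length (40–50 nm): short-range Lck
activity misses genuine agonists, long-range activity phosphorylates
transient weak contacts and produces false activation.

## The synthetic observation scene

`generate_scene()` emulates the *kind* of data the empirical anchors derive
from: a smoothed membrane topography with one tight-contact depression
(logistic radial profile, far field 100 nm, correlated Gaussian roughness
with 100 nm correlation length), TCRs sampled with density
`exp(-(z - min z)/10 nm)` (concentrated below 10 nm), CD45 concentrated in
the 30–40 nm height band, and a phosphorylated subset biased toward a
peripheral annulus. The ring radius (210 nm), width (25 nm) and bias
strength are calibrated once so the default scene reproduces the anchor
estimates `Phos ≈ 0.22` and `Rg ≈ 1.31`; the scene contains exactly one
cluster, so no cluster-selection rule is needed. What the scene does *not*
emulate: localization uncertainty, drift/registration artifacts, multiple
clusters, or any real microscopy file formats — passing tests therefore
demonstrates internal consistency of the estimation pipeline, not fidelity
to raw imaging data.

## Problem sizes and reproducibility

The package's own test and acceptance runs use: 100 TCR / 1200 CD45 / 150
pMHC on an 80 × 80 grid, 100 s of membrane dynamics per run; training grids
of 6 × 6 (KS, 3 replicates), 5 × 5 (Lck-A, 1000 walkers × 1000 steps) and
10 × 6 (pTCR, 3 replicates) cells; a 10 × 10 × 3 affinity scan; and 3 × 8000
posterior draws. Every entry point takes an integer seed and is
bit-reproducible given it. These sizes were chosen so a full pipeline run
completes on one desktop core in minutes while keeping replicate standard
errors well inside the tolerance of every qualitative claim.

```{r pipeline}
# end-to-end sketch
gk <- build_training_grid("KS", n_replicates = 3, seed = 1)
gl <- build_training_grid("LckA", n_replicates = 3, seed = 2)
gp <- build_training_grid("pTCR", n_replicates = 3, seed = 3)
mm <- couple_metamodel(fit_surrogate(gk), fit_surrogate(gl),
                       fit_surrogate(gp))
post <- condition_metamodel(mm, obs = c(phos = 0.22, rg = 1.31), seed = 4)
summary(post)
```

## Known limitations

* The KS energy model is a minimal reconstruction (bending + springs +
  steric wall + tether); it has no explicit cytoskeleton, no LFA-1/ICAM
  adhesion ring, no co-receptors, and no crowding beyond two species.
* Monte-Carlo sweeps are mapped to physical time only through the free
  molecule diffusion calibration; membrane relaxation kinetics are
  sampling-scheme-dependent even though the equilibria are not.
* The phosphorylation model is static per snapshot (no kinetic ODEs for
  phosphorylation/dephosphorylation, no ZAP-70 dynamics).
* Surrogates are parametric regressions; far outside the training hull
  their predictive uncertainty grows but their mean is an extrapolation,
  and `predict()` flags it.
* The detachment boundary and the optimal decay length inherit the
  calibration of `bond_entropy` and of the default geometry; they are
  reproduced as regimes, not as first-principles predictions.
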