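# kinseg

Simulation and Bayesian metamodeling of the nanoscale organization of early
T-cell receptor (TCR) triggering.

When a T cell touches an antigen-presenting cell (APC), three coupled
mechanisms shape the first seconds of signaling:

* **Kinetic segregation.** The TCR–pMHC complex holds the membranes ~13 nm
  apart while the CD45 phosphatase ectodomain needs ~50 nm; bending
  elasticity turns this mismatch into spatial segregation, opening a
  CD45-free *depletion zone* of width `Dep` (nm) around the TCR cluster.
* **Lck activity range.** CD45 activates the kinase Lck; active Lck (Lck*)
  diffuses (coefficient `D`) and deactivates stochastically (rate
  `P_off`), so its density decays around CD45 with a characteristic length
  `DL ≈ sqrt(D / P_off)` (nm).
* **TCR phosphorylation.** The summed Lck* field
  `rho(x) = Σ_j exp(-|x − c_j| / DL)` over CD45 positions `c_j` sets the
  probability that each TCR is phosphorylated, summarized by the fraction
  `Phos` and by the `Rg ratio` — RMSD of phosphorylated TCRs about the
  center of mass of all TCRs divided by the radius of gyration of all TCRs
  (> 1 = peripheral enrichment).

The package implements the three simulators, fits cheap probabilistic
surrogates (exact conjugate Bayesian regressions) to training grids of
each, couples them through shared quantities into one Bayesian metamodel,
and conditions that metamodel on observed pattern statistics
(`Phos = 0.22`, `Rg = 1.31`) to *backpropagate* posteriors over upstream
biophysical parameters — membrane rigidity, time since contact, Lck
diffusion and deactivation. An affinity-scan experiment additionally sweeps
the TCR–pMHC association energy (5–50 kT) through an initial-contact
protocol and scores the sensitivity/specificity of a threshold activation
rule across Lck decay lengths.

For whom: quantitative immunologists and biophysical modelers who want a
tested, seeded, configurable re-implementation of this pipeline that runs
on a single core in minutes, entirely from synthetic inputs.

## Worked example

```r
library(kinseg)

# 1. membrane simulation: segregation opens a depletion zone
traj <- run_ks(ks_config(rigidity = 50, seed = 3))
depletion_width(traj$states[[6]])
#> depletion width 142.6 nm (TCR outer 151.2 nm, CD45 inner 293.7 nm)

# ... and none opens at zero rigidity (negative control)
depletion_width(run_ks(ks_config(rigidity = 0, seed = 3))$states[[6]])$width
#> [1] 0

# 2. Lck random walk: decay length and the scaling law
fit_decay_length(run_walk(diff = 0.1, p_off = 10, seed = 1))
#> decay_fit (loglinear): decay length 167.1 nm (log-residual 0.632)
lck_scaling(seed = 7)$alpha
#> [1] 1.011542

# 3. phosphorylation pattern on a segregated geometry
set.seed(1)
pp <- segregated_pattern(depletion = 100)
assign_phosphorylation(pp, pp, phos_config(decay_length = 70, seed = 2))
#> phos_pattern: 83/100 TCRs phosphorylated (Phos = 0.830), Rg ratio 1.065

# 4. surrogates + metamodel: backpropagate the observed statistics
gk <- build_training_grid("KS",   n_replicates = 3, seed = 3)
gl <- build_training_grid("LckA", n_replicates = 3, seed = 3)
gp <- build_training_grid("pTCR", n_replicates = 3, seed = 3)
mm <- couple_metamodel(fit_surrogate(gk), fit_surrogate(gl),
                       fit_surrogate(gp))
post <- condition_metamodel(mm, obs = c(phos = 0.22, rg = 1.31), seed = 4)
posterior_mode(post$draws$DL_pTCR)   # Lck* decay length, nm
#> [1] 47.03306
posterior_mode(post$draws$Dep_pTCR)  # depletion width, nm
#> [1] 149.4853
```

The posterior concentrates both the Lck* decay length and the depletion
width in the tens-to-~150 nm range: the observed peripheral, partial
phosphorylation pattern is only consistent with an Lck activity range
comparable to the depletion-zone width.

The affinity scan (three to four minutes):

```r
scan <- affinity_scan(ks_config(log_every = 0),
                      contact_protocol(n_replicates = 3, seed = 2))
transition_u(scan)                    # detachment boundary, kT
#> [1] 27.5
ss <- sensitivity_specificity(scan, activation_rule(n_min = 5, tau = 10))
ss$decay_length[which.max(ss$balanced_accuracy)]  # optimal Lck range, nm
#> [1] 50
```

Contacts with association energies at or below ~25 kT detach within tens of
seconds while stronger ones persist, and ligand discrimination under the
"≥ 5 phosphorylated TCRs for ≥ 10 s" rule is best at an intermediate decay
length — long-range Lck activity triggers on transient weak contacts,
short-range activity misses agonists.

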