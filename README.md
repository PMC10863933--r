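# banditmsm

Adaptive sampling of rare-event dynamics with a multi-armed bandit, plus a
complete Markov state model (MSM) analysis stack — on toy systems with exact
ground truth.

## The scientific problem

Molecular processes such as protein–ligand binding or the coupled
binding-and-folding of disordered proteins are dominated by rare transitions
over free-energy barriers. Plain ("brute force") simulation spends almost all
of its budget re-sampling the states it started in, so with a fixed budget it
may never see the interesting transition at all.

*Adaptive sampling* splits the budget into epochs: run a few short
trajectories, build an MSM from everything collected so far, use the model to
decide where the next batch of trajectories should start ("respawning"), and
repeat. The decision rule is an *acquisition policy*, and this package frames
it as a multi-armed bandit problem: each conformational state is an arm, and
launching a trajectory from a state yields a reward. Following the
upper-confidence-bound rule **UCB1**, the policy starts trajectories from the
state maximizing

```
score(a) = Q(a) + c * sqrt(ln t / N(a))
```

where `Q(a)` is the running mean reward of state `a`, `N(a)` the number of
times it has been picked, `t` the total number of picks, and `c` the
exploration constant. The reward of a trajectory is **minus the MSM free
energy averaged over its frames** (the free-energy minimum is anchored at 0,
so the best possible reward is 0). This aims the sampler at the equilibrium
distribution: states that look artificially high in free energy only because
they are undersampled produce large rewards, get picked, and are corrected.

Because the bandit's estimates come from a model that is itself re-estimated
every epoch, the package rebuilds the bandit each epoch from the current
discretization and free-energy profile ("recompute" mode; an "incremental"
mode that carries statistics across epochs is available as a toggle).

The analysis stack turns the pooled data into observables: reversible MSM
estimation with maximum-likelihood detailed balance, free-energy profiles,
implied timescales, TICA projections, PCCA-style coarse-graining,
transition-path theory (committors, reactive flux, flux decomposition,
bottleneck pathways), mean first passage times, association/dissociation
rates (`kon`, `koff`) and standard-state binding free energies with the
volume correction split out.

Everything is validated against systems where the truth is known in closed
form: overdamped Langevin dynamics in 1-D potentials (analytic Boltzmann
distribution) and explicit discrete Markov chains (exact stationary vectors,
committors, MFPTs).

## Running the tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "banditmsm", load_package = "installed")'
```

The suite takes roughly 2–3 minutes. `tests/testthat/test-acceptance.R`
holds the end-to-end statistical checks (oracle agreement, free-energy
recovery, policy contrast, regret growth, bit-for-bit determinism); the other
files are per-module unit and property tests.

## Worked example

A 5 kT double well is a hard target for short trajectories started in the
left well: the right well is essentially never reached by chance in a few
hundred steps. An adaptive campaign climbs out of the start basin epoch by
epoch.

```r
library(banditmsm)

## 1. A toy system with exact ground truth: 5 kT symmetric double well
sys <- make_double_well(barrier_height = 5)

## 2. An adaptive campaign: UCB1 bandit over 15 epochs of 4 x 250 steps
camp <- campaign(epochs = 15, sims_per_epoch = 4, traj_length = 250,
                 policy = "bandit", c = 0.01, x0 = -1,
                 lag = 5, k = 40, seed = 2)
rec <- run_campaign(sys, camp)

## Did the sampler discover the second well (x > 0.5)?
max(vapply(rec$trajectories, function(tr) max(tr$x), numeric(1)))
#> [1] 1.304209

## 3. MSM analysis of all campaign data on a 30-bin grid
edges  <- seq(-2, 2, length.out = 31)
dtrajs <- lapply(rec$trajectories,
                 function(tr) findInterval(tr$x, edges, rightmost.closed = TRUE))
m <- estimate_msm(count_matrix(dtrajs, lag = 5, n_states = 30),
                  reversible = TRUE, lag = 5)
#> Warning: trimming to largest strongly connected component: 21 of 30 states retained
F <- free_energy(m, kT = sys$kT)
round(range(F$F), 2)
#> [1] 0.00 7.74

## RMSE against the analytic Boltzmann profile (in kT)
free_energy_rmse(rec, sys)$rmse
#> [1] 2.788479

## 4. Kinetics: MFPT from the left well into the right well
mid   <- edges[-31] + diff(edges) / 2
left  <- match(which(mid < -0.5), m$active_set)
right <- match(which(mid >  0.5), m$active_set)
left  <- left[!is.na(left)]; right <- right[!is.na(right)]
tau_on <- mfpt(m, source = left, target = right)$mfpt
tau_on
#> [1] 10159.27

## Pseudo association rate if frames were ns and the "ligand" were at 3.2 mM
kon_from_mfpt(tau_on, conc = 3.2e-3, unit = "ns")
#> [1] 30760093

## 5. Transition-path theory: committor and net reactive flux
flux <- reactive_flux(m, A = left, B = right)
round(flux$q_plus[seq(1, length(flux$q_plus), by = 3)], 3)
#> [1] 0.000 0.000 0.000 0.269 0.959 1.000 1.000
flux$total_flux
#> [1] 1.714213e-05
```

Note how state sets for `mfpt()` and `reactive_flux()` are given in the
indices of the trimmed model (`match(..., m$active_set)`), since weakly
sampled bins are removed before estimation.

The same campaign with `policy = "random"` (non-adaptive restarts from the
initial coordinate) discovers the second well in only ~10% of seeds, versus
~30–40% for the bandit at the identical budget — that contrast is asserted
statistically in the acceptance tests.

Campaigns can also be configured from YAML (`load_config()`,
`campaign_from_config()`, `system_from_config()`), saved to a plain-text
trajectory store (`trajectory_store()`, `save_batch()`, `load_batch()`) and
summarized to JSON (`make_report()`, `write_report()`). A thin command-line
wrapper around these functions is installed at `inst/cli/banditmsm.R`.

## Vignette

A methods write-up covering the estimators, the acquisition policies, the
campaign design choices and the validation strategy is in
`vignettes/adaptive-sampling.Rmd` (source form).
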