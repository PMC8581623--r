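# oligokin

Quantifying membrane-receptor oligomerization from multi-copy
coarse-grained trajectories.

Class A GPCRs such as the adenosine A2a receptor form transient dimers and
higher-order oligomers in the membrane. Multi-copy coarse-grained MD
simulations sample many association and dissociation events, but turning
those trajectories into kinetics and structures requires a dedicated
analysis chain. `oligokin` implements that chain end to end, for
computational biophysicists analysing such simulations:

* **Oligomer detection** — per-frame grouping of receptor copies by
  single-linkage clustering of minimum inter-protein bead distances at a
  0.75 nm cutoff (minimum-image convention in the membrane plane), event
  counting from smoothed distance crossings, and oligomer-order
  distributions.
* **Configuration clustering** — permutation-invariant clustering of
  oligomer quaternary structures: member orderings are canonicalized by
  exhaustive minimum-RMSD reordering against a pool reference, then
  clustered by KMeans; clusters are labelled `A.b` (order `A`, cluster
  `b`). Per-structure metrics: dimer binding angles (θ₁, θ₂), trimer
  bending angle (ϕ), tetramer/pentamer principal-axis spans (D₁, D₂).
* **Residence-time kinetics** — dwell durations of continuous appearances
  (gaps < 100 ns bridged) feed a normalized survival function σ(Δt), fitted
  by a biexponential

      σ(Δt) = A·exp(−k₁Δt) + B·exp(−k₂Δt),  A + B = 1, k₁ ≥ k₂ > 0,

  with k_off = k₂ (the slow rate) and residence time 1/k_off; uncertainties
  by bootstrap over durations.
* **Lipid binding sites** — dual-cutoff contact detection (enter < 0.55 nm,
  exit > 1.0 nm) per (residue, lipid), residue-interaction graphs weighted
  by shared-lipid frame counts, Louvain community detection to define
  binding sites, site-level residence times and lipid counts, and in-plane
  radial distributions.
* **Markov state models** — whole-membrane composition states labelled
  `A^a-B^b-C^c`, sliding-window transition counts, maximum-likelihood
  transition matrices on the largest strongly connected state set, implied
  timescales k = −τ/ln(μ), mean first passage times, state lifetimes
  τ/(1 − P_ii), and Monte Carlo state trajectories.
* **Synthetic ground truth** — a 2D Brownian association/dissociation
  simulator (rigid bodies in a periodic membrane patch, capture-radius
  binding, exponential bond lifetimes) plus generators for exponential
  dwell mixtures, planted lipid-contact series, and discrete Markov chains.
  Every generator records its ground truth, so the whole analysis chain is
  validated against known answers.

## Worked example

Simulate 9 receptor copies in a 45 × 45 nm periodic membrane patch for
20 µs at the default rates, then recover the dissociation rate and the
oligomerization network from the trajectory alone:

```r
library(oligokin)

cfg <- sim_config(n_copies = 9, n_frames = 20000, seed = 7)
sim <- simulate_association_dynamics(cfg)
sim$trajectory
#> Multi-copy trajectory: 9 copies x 20000 frames, box 45.0 x 45.0 nm, 1-20000 ns

# dwell durations of pair contacts, detected from minimum distances
pairs <- which(upper.tri(diag(9)), arr.ind = TRUE)
iv <- lapply(seq_len(nrow(pairs)), function(k)
  bound_intervals(min_distance_series(sim$trajectory, pairs[k, ])))
ds <- collect_durations(iv, gap_tolerance = 0, total_time = 36 * 20000)
ds
#> Duration set: 1062 appearances, mean 19 ns, max 136 ns

fit <- bootstrap_koff(ds, n_boot = 200, seed = 1)
fit
#> Biexponential survival fit
#>   sigma(dt) = 3.37e-17 exp(-1.021 dt) + 1 exp(-0.05176 dt)
#>   koff = 0.05176 ns^-1   residence time = 19.32 ns   (bootstrap sd of koff: 0.0124)
cfg$k_off_true
#> [1] 0.05
```

The fitted k_off (0.0518 ns⁻¹) recovers the simulator's true bond
dissociation rate (0.05 ns⁻¹) within 4%; the residence time 1/k_off is
19.3 ns against a realized mean dwell of 19.0 ns. (The 100 ns flicker
tolerance used for coarse-grained force-field trajectories is switched off
here because the synthetic demo's dwells are themselves shorter than
100 ns.)

A Markov state model over membrane composition states:

```r
mem <- partition_trajectory(sim$trajectory)
m <- estimate_msm(label_states(mem, frame_dt = 1), lag = 100)
m
#> Markov state model: 12 states, lag 100 frames (tau = 100 ns)
#>   stationary distribution:
#>         1^9     1^7-2^1     1^6-3^1     1^5-2^2 1^4-2^1-3^1     1^5-4^1
#>      0.3383      0.3909      0.0669      0.1357      0.0317      0.0114
#>   ...
round(head(sort(state_lifetimes(m), decreasing = TRUE), 3))
#>     1^9 1^7-2^1 1^5-2^2
#>     193     172     124
```

`1^9` is the all-monomer state, `1^7-2^1` seven monomers plus one dimer,
and so on; lifetimes are in ns at this lag. Configuration clustering and
metrics come from `characterise_oligomers()`, lipid binding sites from
`generate_lipid_distance_series()` / `lipid_contact_intervals()` /
`detect_binding_sites()` / `site_kinetics()`.

## Package layout

* `R/synthetic-data.R` — simulator and ground-truth generators
* `R/trajectory.R` — trajectory/body containers (internal array format)
* `R/oligomer-detection.R` — distances, partitions, events, distributions
* `R/oligomer-structures.R` — canonical ordering, clustering, metrics
* `R/kinetics.R` — survival functions, biexponential fits, bootstrap
* `R/lipid-sites.R` — dual-cutoff contacts, interaction graph, sites, g(r)
* `R/msm.R` — composition states, transition matrices, MFPTs, lifetimes
* `vignettes/oligomerization-analysis.Rmd` — methods and design notes
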