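---
title: "Quantifying membrane-receptor oligomerization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-receptor oligomerization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligokin)
```

`oligokin` turns multi-copy membrane-protein trajectories into
oligomerization kinetics, quaternary-structure statistics, lipid binding
sites, and Markov state models. This vignette explains the underlying
models and estimators, the tunable parameters, what the synthetic-data
generators do and do not emulate, and the numerical and design choices
made where more than one reasonable option existed.

## Oligomer detection

Two receptor copies are considered in contact when the minimum distance
over all their inter-protein bead pairs is at most the association cutoff
(default **0.75 nm**, the value that separates the contact peak of the
pooled minimum-distance density, near 0.55 nm, from its first trough near
0.7 nm; `distance_density()` recomputes this diagnostic for any data set so
the cutoff can be overridden when the bead model calls for it). Oligomers
are the connected components of the per-frame contact graph. At a fixed
threshold this single-linkage rule is exactly equivalent to cutting a
hierarchical single-linkage dendrogram at that height, which is why it can
be tested verbatim against an independent graph-components oracle.

Distances use the minimum-image convention in the membrane (xy) plane
only; membranes are not periodic in z, and the analysis here is purely
in-plane. Coordinates are in nm, times in ns.

Association/dissociation **events** are counted as downward/upward
crossings of the *smoothed* minimum distance through the cutoff
(`smooth_series()`, centered moving average, default window 31 frames,
shrunken symmetrically at the edges). The smoothing default suppresses
single-frame contact flicker at typical coarse-grained output strides; it
is a display/counting choice and is exposed, not hard-wired. Partition
assignment, in contrast, uses raw frame distances, with flicker handled at
the *duration* level: `fill_flickers()` bridges gaps strictly shorter than
the tolerance (default **100 ns**, the conventional threshold below which
a broken contact in coarse-grained force fields is not a real
dissociation). Whether event counting should use smoothed or raw distances
is genuinely underdetermined; we document this split (smoothed for events,
raw plus duration-level flicker handling for partitions and dwells) as the
package's convention.

## Configuration clustering and metrics

Structures of order 2–5 are pooled per order ("oligomer pools"); order ≥ 6
is counted but not clustered (the shape space is too sparse to cluster
meaningfully at the pool sizes that occur). Because coordinate RMSD
between oligomers of identical protein copies depends on the arbitrary
copy numbering, every structure is first put into a canonical member order
by exhaustively testing all permutations (≤ 5! = 120) against a pool
reference and keeping the one with the lowest RMSD after optimal in-plane
rigid superposition (rotation + translation, **no reflection** — a
reflected dimer is a different stereo-configuration in a membrane).
Superposition is 2D: the analysis is of in-plane arrangements, and the
bodies are effectively prisms normal to the membrane, so in-plane
superposition is the natural reading. Ties are broken by the
lexicographically smallest permutation.

Two conventions make the whole pipeline independent of protein numbering,
which is an explicit contract (`shuffle_copies()` + tests verify
bit-identical output):

* the pool **reference** is the pool's first-occurring structure, with its
  internal member order fixed by geometry (members sorted by the clockwise
  angle from their own reference axis to the oligomer centroid, then by
  centroid distance) rather than by protein index;
* within a frame, oligomers enter the pool in order of their centroid
  coordinates, not their group ids, and periodic unwrapping of an
  oligomer's members is anchored at its geometrically first member.

Clustering is KMeans on the flattened, reordered, superposed coordinates.
The cluster count is inherently data-dependent (the original practice is a
manual scan); the default is a mean-silhouette scan over k = 2..15 under a
fixed seed, overridable per pool. Labels `A.b` are assigned by descending
cluster size.

Metrics (all rotation- and translation-invariant):

* **Dimers**: binding angles θ₁, θ₂ — for each protomer, the clockwise
  angle (viewed from the extracellular side, i.e. from +z) from its
  in-plane reference axis (centre → orientation bead; the stand-in for the
  helix-8-parallel axis) to the direction of the partner's centre of
  geometry, in [0°, 360°). The "interface direction" is formalized as the
  partner-centre direction; a contact-centroid definition was considered
  and rejected because it is noisier for loosely touching dimers and
  changes discontinuously as beads cross the cutoff.
* **Trimers**: bending angle ϕ at the vertex protomer (the one in contact
  with both others). Cyclic trimers have no unique vertex; the smallest of
  the three vertex angles is reported, making ϕ a continuous measure of
  departure from a linear chain (180°) toward a closed triangle (60°).
* **Tetramers/pentamers**: spans D₁ ≥ D₂ of protomer centres projected on
  the principal axes of their in-plane covariance; an isotropic
  (equal-eigenvalue) covariance falls back to the x/y axes.

## Residence-time kinetics

For each configuration (or residue, or binding site) the durations of its
continuous appearances are collected, pooled across replicates (never
bridged between replicates), and summarized by the empirical survival
function σ(Δt) = fraction of appearances lasting at least Δt, normalized
so σ(0) = 1 and evaluated on 200 logarithmically spaced points from the
shortest to the longest duration. The start-time formulation of the
survival time-correlation function (a double sum over appearance start
times with a 1/(T−t) window factor) double-counts within long appearances;
the duration-based empirical survival implemented here has the same decay
shape, is standard in the contact-kinetics literature, and keeps σ a true
survival curve (non-increasing, in [0, 1]). This is a documented reading,
not an approximation we can calibrate away.

The survival curve is fitted by unweighted nonlinear least squares with

σ(Δt) = A·e^(−k₁Δt) + B·e^(−k₂Δt),  A, B ≥ 0, A + B = 1, k₁ ≥ k₂ > 0,

through an unconstrained reparameterization (logistic amplitude, log
rates, k₁ = k₂ + e^δ). **k_off = k₂** (the slow rate), residence time =
1/k_off, exactly by definition. Initialization: k₂ from a log-linear fit
to the tail (last 30% of the grid with σ > 0), k₁ = 10·k₂, A = 0.5, plus a
fixed dispersed set of multi-starts; the lowest residual sum of squares
wins. One numerical subtlety deserves note: on near-exponential data the
objective is almost flat between the physical solution and a degenerate
one in which a vanishing slow rate with a tiny amplitude models the
empirical tail plateau (the plateau at 1/N created by the single longest
duration). Among solutions whose SSR differ by less than 0.1% the fit
therefore prefers the larger slow rate; this tie-break removes the
degenerate branch without affecting genuine two-component fits, whose slow
component improves the SSR far more than 0.1%.

A survival curve that never decays over its window is rejected as
unidentifiable (k_off is then only bounded by 1/T). Durations truncated by
the trajectory end are included as-is — no censoring correction — matching
common practice for these estimators; the bias is toward shorter
residence times and vanishes as T grows past 1/k_off.

Uncertainties come from bootstrap resampling of the durations
(`bootstrap_koff()`, default 1000 resamples): SD and 2.5/97.5 percentile
interval of k_off, with a warning if more than 20% of refits fail.
Per-order summaries (`mean_residence_by_order()`) average configuration
residence times within an oligomeric order with a 1000-sample bootstrap
interval over configurations.

## Lipid binding sites

Contacts between a lipid head group and a residue use a **dual cutoff**:
a contact opens when the distance drops below 0.55 nm and closes only when
it exceeds 1.0 nm. The hysteresis band absorbs boundary flicker without a
time-based tolerance. Residue residence times run the contact durations
through the same survival/biexponential machinery.

Binding sites are communities of the residue interaction graph: nodes are
residues, and the weight of edge (i, j) is the number of frames in which i
and j were simultaneously in contact with the *same* lipid molecule,
normalized by the trajectory length (the normalization is a convention;
modularity-based community detection is invariant to a global scale).
Residues with occupancy below 10⁻⁴ are dropped as noise. Louvain
modularity maximization (resolution 1.0, seeded) defines the sites;
site-level contacts are detected by running the dual-cutoff machine on the
per-lipid minimum distance over the site's residues, so a lipid hopping
between residues of one site without fully leaving counts as a single long
site contact — which is why site residence times are bounded below by the
residence times of their member residues. The mean lipid count of a site
is the time-average number of distinct lipids simultaneously bound.

Radial distributions (`radial_distribution()`) are in-plane g(r) of lipid
head groups about the receptor's centre of geometry, normalized by
ideal-density annulus areas in the periodic box; the centre (rather than
the protein surface) is used as the reference because it admits an exact
ideal-gas normalization (uniform lipids give g ≡ 1), at the cost of
smearing structure over the body radius.

## Markov state models

The state of the membrane at a frame is its oligomer composition, labelled
`A^a-B^b-C^c` (orders present, ascending, with their counts: `1^9` is nine
monomers, `1^7-2^1` seven monomers and one dimer). Specific oligomer
geometries are deliberately not part of the state: that extra degree of
freedom would prevent MSM convergence at realistic sampling.

Transitions are counted with a sliding window at lag τ (maximal data use;
replicates are summed, never bridged), and the transition matrix is the
maximum-likelihood row normalization of the counts, restricted to the
largest strongly connected state set (excluded states are reported, never
silently dropped). The default estimator is **non-reversible**; a
reversible MLE (detailed-balance fixed-point iteration, 10⁻¹⁰
convergence) is available because the established MSM toolchains default
to it — the two differ measurably only when sampling is far from
equilibrium, and the non-reversible estimator is the more transparent
default for validation against known chains.

From the model: stationary distribution π (leading left eigenvector,
polished by power iteration), implied timescales k = −τ/ln(μ) per
non-unit eigenvalue (complex pairs enter by modulus; μ ≤ 0 yields an
undefined timescale, reported as NA), mean first passage times solving
m_i = τ + Σ_{k≠j} P_ik·m_k with m_j = 0, and reaction rates 1/mfpt.
Implied-timescale scans over lags (`implied_timescales()`) are always
available so the lag can be chosen where the timescales flatten; for the
synthetic systems in this package the dynamics are Markovian by
construction and the scan is a validation, not a tuning step.

The **state lifetime** is implemented as the first-exit time
τ/(1 − P_ii), i.e. the mean first passage time from i to the set of all
other states. A per-target mfpt table is always available, so a
mean-over-targets or specific-target reading of "lifetime" remains
recoverable if preferred.

## The synthetic-data generators

The generators replace unavailable raw simulation data with systems whose
ground truth is known exactly; their defaults define the package's study
conditions and are not tuned per test.

`simulate_association_dynamics()` propagates N rigid copies of a
disc-like body (12-bead ring of radius 1.5 nm plus centre bead) by 2D
Brownian dynamics in a periodic box (default 45 × 45 nm, the standard
membrane-patch size for such systems; 9 or 16 copies). Two copies in
different oligomers bind when their centres come within the capture radius
(3.9 nm) and are snapped to a fixed contact distance (0.9 × capture);
bound groups move as rigid units with 1/size-scaled diffusion; bonds break
independently at rate k_off, and fragments are separated to just outside
the capture radius so a dissociation is a real excursion rather than an
instant recapture. Geometry is chosen so detection is unambiguous: bound
pairs always have minimum bead distance below the 0.75 nm cutoff and
unbound pairs above it, so the ground-truth partition and the detected
partition must agree exactly — a property the tests assert frame by frame.
Defaults (D = 0.05 nm²/ns, k_off = 0.05 ns⁻¹, 1 ns frames) put the system
in a dilute regime (~15% of copies bound at any instant) with hundreds to
thousands of events per 100 µs run: the regime in which protein–protein
association is a second-order reaction, which is the property the 9- vs
16-copy scaling validation measures. The rotational diffusion coefficient
reuses the translational value in rad²/ns — only relative in-plane
geometry feeds the metrics, so the two need not be tuned independently.

What the simulator does *not* emulate: force fields and energetics,
orientation-dependent binding (any approach within the capture radius
binds), membrane lipids as particles, preferred dimer interfaces, and
state-dependent kinetics. Passing tests therefore demonstrate the
correctness of the *analysis machinery* — detection, reordering,
clustering, kinetics, MSM estimation — on data with the assumed
statistical structure, not the biology of any particular receptor.

`generate_dwell_durations()` draws i.i.d. mixtures
w₁·Exp(k₁) + (1−w₁)·Exp(k₂) for the survival-fit validations.
`generate_lipid_distance_series()` plants binding sites: each site
alternates unbound stretches (mean gap twice the mean dwell, i.e. ~1/3
occupancy) with bound epochs of exponential duration, one fresh lipid id
per epoch, all member residues below the entry cutoff during an epoch;
lipids are never shared across sites, so planted sites are exactly the
communities of the interaction graph. Epoch lengths are realized on the
frame grid (ceiling to whole frames), and the recorded ground truth is the
realized dwell, so recovery comparisons are free of discretization bias.
`generate_markov_chain()` samples a chain from any row-stochastic matrix.
All generators consume a single integer seed.

## Problem sizes and degenerate inputs

The shipped validations use 10⁵-frame simulations (5 seeds per copy
number) for the association-scaling check, 10³–5·10³ durations for rate
recovery, 10³ random frames for the assignment oracle, 6·10⁴-frame
planted lipid systems (~2000 dwell events per site), and 10⁵-step chains
for the MSM round trip — sizes at which the statistical tolerances (10–20%
for rates, 0.02 per matrix entry) are comfortably resolved on a single
CPU in a few minutes.

Degenerate inputs are handled explicitly rather than silently: empty
duration sets survive collection but are refused by the fit; constant
distance input flags a spike density; a survival curve with no decay is an
error naming the 1/T bound; identical durations get a widened survival
grid so the step is representable; `P_ii = 1` yields an infinite lifetime;
reducible transition matrices name the unreachable states; isotropic
covariance in the span metrics falls back to fixed axes; coincident
centres in the angle metrics are geometry errors.

## Known limitations

* The Brownian simulator is a kinetic stand-in, not a physical membrane
  model; absolute rates carry no biological meaning.
* No censoring correction for end-truncated dwells (option considered;
  deliberately off to match standard practice).
* KMeans with a silhouette scan can under-split elongated configuration
  clusters; the cluster count is overridable per pool for exactly this
  reason.
* Louvain communities depend on the resolution parameter; 1.0 is the
  conventional default, and well-separated sites (the validated regime)
  are insensitive to it.
* Trajectory input is the package's documented array format; readers for
  external trajectory formats are intentionally out of scope here.
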