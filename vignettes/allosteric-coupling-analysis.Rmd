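---
title: "Quantifying allosteric coupling between a ligand site and the channel pore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying allosteric coupling between a ligand site and the channel pore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopath)
```

## The problem

Large-conductance Ca²⁺- and voltage-activated K⁺ (BK) channels open in
response to two stimuli sensed in different domains: membrane voltage,
sensed by the transmembrane voltage-sensor domain (VSD), and
intracellular Ca²⁺, bound in the cytosolic tail domain (CTD). How a
binding event tens of Ångströms from the pore promotes gate opening is
an allosteric-coupling question: which residues carry the mechanical
and dynamical communication from the Ca²⁺ site to the pore-lining
residues?

`allopath` implements the trajectory-network machinery used to answer
that question, together with the patch-clamp analyses used to validate
candidate pathway residues by mutagenesis:

1. **Residue interaction networks** from conformational ensembles:
   persistent-contact edges weighted by dynamic cross-correlation.
2. **Optimal and suboptimal coupling paths** between a chosen source
   (e.g. a Ca²⁺-coordinating residue) and sink (a pore residue).
3. **Current-flow "information flow"**: a global, per-residue measure
   of participation in source→sink coupling on a mutual-information
   conductance network.
4. **Gating analysis**: Boltzmann GV fits, Hill dose-response fits,
   NPo estimation and channel counting.

Because full-scale atomistic simulations are out of reach for a test
suite, the package ships a synthetic-data module whose outputs have
*closed-form ground truth*, so every estimator in the chain is
validated quantitatively, not just smoke-tested.

## The network model

### Contacts and path weights

Two residues are connected when the minimal distance between their
non-hydrogen atoms stays below **5 Å for strictly more than 75%** of
frames. Each contact edge carries the weight

$$w_{ij} = -\log |C_{ij}|,$$

where $C_{ij}$ is the normalized dynamic cross-correlation of the two
nodes' displacement vectors about their mean positions. Strongly
correlated contacts are "short", so the shortest source→sink path is
the most strongly coupled chain of interactions. The path length
$D_{ij}$ is the sum of edge weights along the route.

We normalize the cross-correlation (a Pearson-style dot-product
correlation of 3-D deviations) so $|C_{ij}| \le 1$ and the weight is
guaranteed non-negative; an unnormalized covariance would make
$-\log$ ill-defined. Note one subtlety of the formulation this package
deliberately disambiguates: the correlation matrix that weights path
edges and the *binary contact map* that masks the flow network are
different objects, and they are named `C` and `contact` respectively
throughout the API.

### Optimal and suboptimal paths

All-pairs distances use Floyd–Warshall. The ranked list of the top
*k* = 20 loopless paths (optimal plus suboptimal) uses a deviation
(Yen-style) enumeration over a deterministic Dijkstra; ties in length
are broken lexicographically by node sequence so results are
reproducible to the bit. The choice of *loopless* paths is the
standard reading of "additional top paths"; an optional
`max_offset` argument restricts the list to paths within a length
offset of the optimum instead.

Residues that recur across many near-optimal routes
(`residue_frequency()`) and residues within a strict **< 6 Å** of any
path node (`path_vicinity()`) summarize which side chains carry or
abut the coupling.

### Information flow

The complementary global picture treats the network as a resistor
mesh. Pairwise mutual information of the scalar fluctuation variable
$x_i(t)$ — the distance of node $i$ from its equilibrium position —
is estimated as

$$M_{ij} = H_i + H_j - H_{ij}, \qquad
H = \tfrac{1}{N}\sum_n [-\ln \hat\rho(x_n)],$$

with densities $\hat\rho$ from Gaussian mixture models (1-D marginals,
2-D joints). The conductance network is $A_{ij} =
\mathrm{contact}_{ij} \cdot M_{ij}$, its Laplacian $L = D - A$ with
$D_{ii} = \sum_j A_{ij}$. Fixing all sink nodes at potential zero and
injecting one unit of current at the source, the potentials solve
$P = \tilde L^{-1} b$ on the reduced Laplacian, and the per-node flow
is

$$f_i = \tfrac{1}{2} \sum_j |P_i - P_j| A_{ij}.$$

At interior nodes this equals the through-current (source/sink cuts
sum to 1); at the terminals the formula as written yields half the
through-current, and both the raw and a terminal-normalized column
are reported. Multiple sinks are merged into a common ground — the
reduced system deletes all sink rows/columns and the supply vector
has +1 only at the source — which realizes "one unit in at the
source, out at the sinks" as a well-posed SPD linear solve (Cholesky;
a singular reduced Laplacian, i.e. a floating subgraph, is an error,
never a silent least-squares fallback).

### GMM entropy estimation: numerical choices

* Components are selected by BIC over `1:max_components` (default cap
  5). 1-D fits consider equal- and free-variance models; 2-D fits use
  full covariances.
* EM initialization uses model-based hierarchical clustering on an
  **evenly spaced subset of at most 1000 points**, which makes the
  estimator fully deterministic without consuming RNG state.
* The plug-in entropy averages $-\ln\hat\rho$ over the input samples
  themselves.
* Negative MI estimates (possible through model-selection noise) are
  clamped at 0 so the Laplacian never receives a negative
  conductance. The clamp floor is configurable: the pipeline defaults
  to a tiny positive floor (`1e-4` nats) on computed contact pairs so
  that a weak but genuine edge zeroed by estimator noise cannot
  disconnect the conductance network; set `floor = 0` for the strict
  clamp.
* The joint entropy is computed on 2-D $(x_i, x_j)$ distance pairs.
  This is one reading of the method description (which defines
  $\rho_i(x)$ only for marginals); it is the natural one and is
  flagged here as an interpretation.

## The synthetic-data module

### Bead-model trajectories

`make_bead_model()` builds Gaussian-network-model (GNM) spring
networks — chain, ring, or **two-branch** (a source bead connected to
a sink bead via two disjoint chains, emulating the two coupling
branches of a sensor-to-pore pathway: one covalent linker, one domain
interface; per-branch spring constants let one branch dominate).
`sample_trajectory()` draws i.i.d. frames whose per-coordinate
node–node covariance is exactly

$$\Sigma = a^2\, \Gamma^{+},$$

the (amplitude-scaled) pseudoinverse of the Kirchhoff matrix, applied
isotropically to x, y, z. Isotropy keeps distance-to-mean statistics
tractable and makes the analytic correlation matrix the oracle for
`correlation_matrix()` (agreement within 0.05 at 5000 frames is part
of the test suite). With `rigid_body = TRUE`, random global
rotations/translations contaminate each frame; the same seed produces
the same internal displacements either way, giving a paired oracle
for `superpose()`.

Two caveats the tests respect:

* Least-squares superposition absorbs whatever part of the *internal*
  fluctuations overlaps global rotations. For these toy models the
  softest GNM modes overlap rotations substantially, so analytic
  ground-truth comparisons are run on the raw (generated-aligned)
  ensembles, and superposition is validated by its own contract:
  a rigid-body-contaminated ensemble superposes to the same
  statistics as its clean twin, idempotently.
* The bead geometries are laid out so that spring-connected beads sit
  at 3.8 Å and all other pairs beyond ~7 Å; at the default 5 Å / 75%
  contact rule the recovered network topology equals the spring
  topology (the two branches of the two-branch fixture are laid on
  the two semicircles of a circle for this reason).

What the generator does **not** emulate: anharmonicity, time
correlation between frames (frames are i.i.d., real trajectory
snapshots are not), solvent/membrane coupling, and periodic-boundary
artifacts. Passing tests therefore validate the estimators and
algorithms, not force-field realism.

### Synthetic electrophysiology

`make_gv_dataset()` and `make_dose_response()` evaluate the Boltzmann
activation curve

$$G/G_{max} = \frac{1}{1 + \exp((V_{1/2} - V)/b)}$$

and the Hill curve

$$\theta = \frac{\theta_{max}}{1 + (EC_{50}/X)^n}$$

exactly, then add i.i.d. Gaussian noise per replicate and report the
replicate mean with $SEM = \sigma/\sqrt{n}$. `simulate_channel_trace()`
runs N independent two-state Markov channels by exact binomial
transitions per sampling step (stationary start), summing to a current
$N_{open}\,\gamma (V - E_K)$.

`bk_reference_designs()` packages four published reference designs
(BC5 activation EC₅₀ 2.5 µM; inhibition IC₅₀ 1.1 µM; E219R and T245W
GV curves at 0 Ca²⁺) with the concentration/voltage grids and
per-point replicate counts of those datasets. Where the published
record does not pin a generator constant we fixed one realistic value
and kept it:

* the maximal GV shift of the activation design is −60 mV, a
  magnitude comparable to activation by ~1 µM intracellular Ca²⁺;
* per-replicate noise scales are 4 mV for ΔV½ points, 0.05 for
  fractional inhibition, and 0.1 normalized-conductance units for
  single GV curves, chosen to reproduce the error-bar scale typical
  of such recordings.

## Gating analysis: fitting choices

* **Weights**: points are weighted $1/SEM^2$ when SEMs are available
  (configurable) — whether published fits weighted by SEM is usually
  unstated, and the weighted default is the conservative choice.
* **Initialization** is derivative-free and deterministic: $V_{1/2}$
  from the interpolated half-maximum crossing, $b$ from the 25–75%
  span divided by $\ln 9$, $EC_{50}$ from the 50%-response crossing.
* **Gmax** is fixed at 1 by default because the response is already
  normalized to its maximum; with a free amplitude and a protocol
  that stops short of saturation, $V_{1/2}$ and $G_{max}$ are heavily
  confounded and the SEs balloon. `fix_gmax = FALSE` restores the
  free-amplitude fit for un-normalized data.
* **Hill coefficient** is fixed at 1 by default (freed with
  `fix_n = FALSE`), matching common practice when initial fits find
  $n \approx 1$.
* **Standard errors** come from parametric Monte-Carlo resampling:
  500 seeded draws perturb every point by $\mathcal N(0, SEM^2)$ and
  refit; the SE is the SD of the refitted parameters. This mirrors
  SE estimation "directly from the SEMs of the input data".
* **NPo** uses rectangular integration (sum × Δt) divided by the
  unitary current and total time, with no interpolation assumptions;
  a 20-batch batch-means SE is attached. Channel counts invert
  $I = N \gamma P_O (V - E_K)$ with γ in pS and voltages in mV
  (so γ(V−E_K)/1000 is the unitary current in pA).

## Worked example

```{r example, eval = FALSE}
library(allopath)

# a two-branch coupling fixture: source bead 1, sink bead 10
res <- run_pipeline(demo_config(n_frames = 2000L, seed = 1))
res$paths           # ranked coupling paths
res$flow            # per-node current flow, sums to 1 across any cut

# gating analysis on a published-design synthetic dataset
d <- bk_reference_designs()$activation
dr <- make_dose_response(d$ec50, d$max_response, d$concentrations,
                         noise_sd = d$noise_sd, n_reps = d$n_reps,
                         seed = 1)
fit_hill(dr)
```

## Problem sizes and determinism

The validation suite runs on deliberately small instances: path
enumeration is checked against exhaustive simple-path enumeration on
100 random graphs of up to 8 nodes; flow against hand-solved resistor
networks plus Kirchhoff conservation on 100 random graphs; entropy
calibration on $10^5$ Gaussian samples (|error| < 0.05 nats of
$\tfrac12\ln 2\pi e$, Gaussian MI at $r = 0.9$ within 0.07 of
$-\tfrac12\ln(1-r^2)$); GNM correlation recovery at 5000 frames
(max-abs error < 0.05); and parameter recovery of all reference-design
fits within 2 recovered SE. Every stochastic step takes an explicit
seed, and the pipeline writes a manifest that is bit-identical across
reruns of the same config.

## Known limitations

* No periodic-boundary imaging in contact distances: inputs must be
  whole-molecule ensembles.
* Binary trajectory formats (DCD/XTC) are not read natively; convert
  to multi-model PDB or XYZ first.
* Mutual information on the 1-D distance-to-mean variable discards
  directional information, so weakly coupled pairs sit near the
  estimator noise floor — hence the configurable conductance floor.
* Whether to pool replicas before computing correlations is left to
  the caller (compute per replica and average, or concatenate); the
  package provides simple unweighted means only.
* The current-flow solver is dense (Cholesky on the reduced
  Laplacian), appropriate for residue networks up to a few thousand
  nodes.
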