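# allopath

Allosteric coupling pathways and gating analysis for ion channels.

## What it does

BK-type channels open when Ca²⁺ binds in a cytosolic domain tens of
Ångströms from the pore gate. Which residues carry that coupling?
`allopath` answers the question from conformational ensembles and
validates candidates with the standard electrophysiology analyses:

* **Residue interaction networks** — persistent contacts (minimal
  non-hydrogen distance < 5 Å for > 75% of frames) weighted by
  dynamic cross-correlation, `w_ij = -log|C_ij|`.
* **Optimal + suboptimal coupling paths** — Floyd–Warshall distances
  and the top-k loopless source→sink paths (deterministic Yen-style
  enumeration), plus per-residue path frequency and a strict < 6 Å
  pathway-vicinity flag.
* **Information flow** — current-flow analysis on a
  mutual-information conductance network `A_ij = contact_ij * M_ij`
  (GMM entropies, `M_ij = H_i + H_j - H_ij`): ground the sinks, inject
  one unit of current at the source, solve `P = L̃⁻¹ b` on the reduced
  Laplacian, and report `f_i = ½ Σ_j |P_i - P_j| A_ij` per residue.
* **Gating analysis** — Boltzmann GV fits
  (`G/Gmax = 1/(1+exp((V½−V)/b))`), Hill dose-response fits
  (`θ = θmax/(1+(EC50/X)^n)`, n fixed at 1 by default), ΔV½ with
  propagated SE, NPo from traces, channel counts from
  `I = NγP_O(V−E_K)`; standard errors by seeded parametric
  Monte-Carlo resampling of the input SEMs.
* **Synthetic data with analytic ground truth** — Gaussian network
  model bead trajectories whose covariance is exactly the Kirchhoff
  pseudoinverse, plus synthetic GV curves, dose-response tables and
  multi-channel Markov current traces, so every estimator is tested
  against closed form.

## Worked example

```r
library(allopath)

# synthetic two-branch coupling system: source bead 1, sink bead 10,
# branches through beads 2-5 and 6-9
res <- run_pipeline(demo_config(n_frames = 2000L, seed = 1), quiet = TRUE)
res$paths
#> <path_set> 2 path(s) A:1 -> A:10
#>    1  L=6.1624  A:1 - B:6 - B:7 - B:8 - B:9 - A:10
#>    2  L=6.2347  A:1 - B:2 - B:3 - B:4 - B:5 - A:10
round(res$flow$node_flow, 3)
#>   A:1   B:2   B:3   B:4   B:5   B:6   B:7   B:8   B:9  A:10
#> 0.500 0.551 0.551 0.551 0.551 0.449 0.449 0.449 0.449 0.500
```

Both branches are structurally equivalent here, so the ranked path
lengths are close and the unit current splits near 50/50 between the
branch midlines (`f` at the terminals is half the through-current by
the flow formula; a terminal-normalized column is in
`flow_report()`). Strengthen one branch
(`demo_config(branch_k = c(2, 1))`) and both analyses shift toward
it.

Gating side:

```r
d <- bk_reference_designs()$activation        # published WT design
dr <- make_dose_response(d$ec50, d$max_response, d$concentrations,
                         noise_sd = d$noise_sd, n_reps = d$n_reps,
                         seed = 1)
fit_hill(dr)
#> <hill_fit> EC50 = 2.43 +/- 0.2 uM, max = -59.3 +/- 1.2 (n = 1)
```

The recovered EC50 agrees with the generating value (2.5 µM) within
its Monte-Carlo standard error.

A thin command-line wrapper with subcommands (`run-all`, `synth`,
`contacts`, `paths`, `flow`, `fit-gv`, `fit-dose`, `npo`) is installed
at `inst/scripts/allopath.R`.

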