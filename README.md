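# motifstdp

Self-organization of recurrent excitatory networks under the **minimal
triplet rule** of spike-timing-dependent plasticity (STDP), analyzed
through a **structural motif expansion** of the synaptic drift.

Neural activity is modeled as a linear mutually exciting (Hawkes) point
process, `lambda_i(t) = mu_i + sum_k W_ik (E * S_k)(t)`, whose stationary
rates and second-/third-order spike-train cumulants are exact functions
of the connectivity `W` through the resolvent `(I - E~(w) W)^-1`.
Depression is driven by post-before-pre spike pairs (window `L2`, area
`-A- tau-`), potentiation by pre-post-post triplets
(`L3(t1, t2) = A+ exp(-t1/tau+) exp(-t2/tau_y)`). Expanding the cumulants
in powers of `W` expresses the mean drift of each synapse as a sum over
connectivity paths — motifs — weighted by scalar coefficients
`M_{alpha,beta}` (plus delayed-path and loop coefficients unique to the
triplet rule), which the package computes by adaptive quadrature of
kernel-transform products in the frequency domain. Integrating the
truncated drift together with heterosynaptic competition and balanced
inhibition yields steady-state connectivity whose assembly structure is
quantified with graph metrics (directed clustering, global efficiency,
modularity, connection fractions).

The package is for computational neuroscientists studying how precise
spike-timing correlations — rather than structured input — can wire
assemblies, and how neuromodulation of the learning window or of the
EPSC kernel shifts the motif balance that controls this.

## Worked example

```r
library(motifstdp)

kp  <- default_kernel_params()            # tau_eps = tau_iota = 5 ms
cfg <- default_network_config()           # N = 48, mu = 150 Hz, ...

# motif coefficients under strong modulation of the depression window
ms <- motif_set(kp, default_stdp_params(eta_minus = 13), rate = 150)
ms$M01
#> [1] 0.0009720958
ms$M10
#> [1] 0.01587152

# the reciprocal coefficient M01 turns positive near eta- ~ 5.6
find_crossing(function(e)
  motif_set(kp, default_stdp_params(e), 150)$M01, 1, 13)
#> [1] 5.560059

# integrate the weight dynamics from a seeded random initial matrix
sim <- integrate_weights(initial_weights(cfg, seed = 1), cfg, kp,
                         default_stdp_params(eta_minus = 13),
                         on_nonconvergence = "warn")
glance(sim)
#> # A tibble: 1 x 7
#>   steps converged mean_clustering global_efficiency modularity ...
#> 1 16500 TRUE                0.271             0.438      0.470
```

`M10 > 0` says every feedforward connection self-amplifies; the sign of
`M01` decides whether a reciprocal connection competes with (negative)
or reinforces (positive) its partner — the switch point of assembly
formation. The `glance()` row summarizes the binarized steady state:
under strong modulation roughly 5% of pairs become bidirectional, the
graph splits into 4-6 modules (modularity ~ 0.5) and directed
clustering rises to ~ 0.27, versus purely unidirectional wiring at
`eta_minus = 1`. Multi-trial experiments with standard errors:

```r
sw <- run_sweep("eta_minus", c(1, 5, 9, 13), trials = 10, seed = 1)
autoplot(sw)
```

A thin command-line front end is installed as `exec/motifstdp`
(subcommands `motifs`, `evolve`, `simulate`, `sweep`, `metrics`).

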