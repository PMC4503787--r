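# ssadyn

Slow-switching assembly (SSA) dynamics in structured spiking networks:
tools to *predict from connectivity* — and *measure from spike trains* —
epochs of elevated firing that live on groups of neurons and wander slowly
between groups.

`ssadyn` is aimed at computational neuroscientists who want to know whether
a given synaptic wiring diagram can sustain assembly switching before (or
without) running long simulations. It packages the full chain:

1. **Network generators** for balanced excitatory–inhibitory weight
   matrices: unclustered; excitatory clustering by connection probability
   (ratio `R_EE`) or by synaptic weight (`W_EE`); excitatory-to-inhibitory
   feedback co-clustering (`R_IE`, `W_IE`, and inverse ratios `R_EI`,
   `W_EI`); Watts–Strogatz-like small worlds; preferential-attachment
   scale-free graphs; and two-level hierarchies. Every construction
   conserves the unclustered average connectivity and weight exactly while
   the clustering ratio varies, and all weights scale as `2000/N`.
2. **A leaky integrate-and-fire simulator** (compiled core): threshold 1,
   reset 0, `τ_m` = 15/10 ms (E/I), refractory 5 ms, exponential synapses
   `τ_E` = 3 ms / `τ_I` = 2 ms, step 0.1 ms.
3. **Linear rate models** `τ dr/dt = −(I − W) r + ξ` for a 3-node clustered
   circuit and a 4-node E–I feedback circuit, with closed-form eigenvalues,
   analytic Schur decompositions `W = U Q Uᵀ`, stability thresholds and
   stochastic integration.
4. **Spectral diagnostics** for arbitrary weight matrices: the eigengap
   `Δλ` separating the `c − 1` slow eigenvalues from the bulk, the
   dominant (Schur) invariant subspace, a block-localization score of that
   subspace on a partition, the winner-takes-all indicator `λ_max ≥ 1`,
   and the damped global-activation ("balance") eigenvalue pair.
5. **Spike-train metrics**: group-rate matrices in 100 ms windows; the
   spike-rate variability scores `S, Ŝ = S − ⟨S_shuff⟩` (across groups)
   and `S_T, Ŝ_T` (across time) with 10-shuffle baselines; PCA firing
   patterns in 250 ms bins; and the first principal angle θ between the
   observed pattern subspace and the dominant Schur subspace.

The organizing result: a network supports SSA when its weight matrix has a
set of eigenvalues separated from the bulk by a gap **and** the associated
Schur vectors are block-localized on groups of neurons. The gap sets the
slow time scale (`τ_i = 1/(1 − λ_i)`); `λ_max ≥ 1` marks the transition to
a single dominant assembly.

## Worked example

The reference clustered network: `N = 2000` neurons (1600 E / 400 I), 20
embedded groups of 80 excitatory neurons, probability clustering
`R_EE = 3.4`.

```r
library(ssadyn)

net <- generate_network(network_spec("clustered_prob", N = 2000, c = 20,
                                     R_EE = 3.4, seed = 21))
ss <- spectral_summary(net)
ss
#> <spectral_summary> N = 2000
#>   gap: m = 19, delta_lambda = 0.1485; lambda_max = 0.5592
#>   block-localization of leading basis: 0.736
#>   balance pair: -0.4577 +/- 2.3327i
```

The gap detector finds `m = 19 = c − 1` slow eigenvalues without being told
`c`, and the leading invariant subspace is strongly block-localized
(score 0.74 against ~0.01 for bulk vectors), so the wiring *predicts*
assembly dynamics. The simulation confirms it:

```r
raster <- simulate_lif(net, lif_params(duration = 10, seed = 3))
spike_rate_variability(raster, net$partition, seed = 5)
#> <variability_scores> S = 7.7978 Hz, shuffled = 1.0102, S_hat = 6.7875
temporal_rate_variability(raster, net$partition, seed = 5)
#> <variability_scores> S_T = 6.3982 Hz, shuffled = 1.0465, S_hat_T = 5.3517

P <- pca_firing_patterns(raster, bin_ms = 250, n_components = 19)
principal_angle(P, ss$dominant_basis)
#> <alignment_result> theta = 21.10 deg (cos = 0.9330)
```

`Ŝ = 6.8 Hz` (an unclustered control gives `Ŝ ≈ 0`) and the observed firing
patterns align with the dominant Schur subspace (θ = 21°). Parameter sweeps
over any clustering ratio run through `run_sweep()`; a command-line front
end for generate/simulate/analyze/metrics/sweep lives at
`inst/cli/ssa.R`, reading and writing Matrix Market weight matrices with
JSON sidecars and CSV rasters.

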