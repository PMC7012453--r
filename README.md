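# popcoupling

Tools for asking what explains the trial-to-trial variability of visual
cortical neurons within single trials: the stimulus, the animal's running,
or the coactivity of each neuron's local **functional group** — and whether
knowing that local coupling helps decode the stimulus from the population.

The package targets trial-structured population fluorescence recordings
(neurons × frames traces, per-frame grating-direction labels, running
speed, repeated identical stimulus blocks) and ships a synthetic population
simulator with planted ground truth so every stage can be validated without
imaging data.

## The model at its core

**Functional weights.** For neurons *x*, *y* within one trial, the coupling
is the partial correlation computed from the precision of the 5×5
correlation matrix Ω of: the two trial traces, each neuron's leave-one-out
trial-mean trace, and the within-trial population mean excluding the pair,

ρ<sub>xy</sub> = −(Ω⁻¹)₁₂ / √((Ω⁻¹)₁₁ (Ω⁻¹)₂₂),

averaged across trials — a noise-correlation-like measure with stimulus and
population-wide (running-driven) coactivity conditioned away. The lag
maximizing the cross-correlogram of the pair's block-mean traces gives each
edge a direction (lag 0 = bidirectional); edges with weight magnitudes in
the pooled top quartile are "strong".

**Coupled linear models.** Per neuron *i*,

r̂ᵢ(t) = c + β₀·Wᵢ⁰ᵀr(t) + β₁·Wᵢ¹ᵀr(t−1) + Ψ·s(t) + Γ·v(t),

where the incoming-weight vectors Wᵢ⁰, Wᵢ¹ are *measured*, not fitted.
Restricted variants (drop stimulus, running, coupling; keep one lag; split
by weight sign) are compared by percent change in test-set MSE. Strong-
weight and strong-edge permutation nulls quantify how much predictions
depend on the precise strong-edge structure.

**Decoders.** Coupled (LM-predicted mean per candidate condition, full
shrinkage-regularized per-condition covariance) versus uncoupled
(conditionally independent neurons) Bayesian MAP decoding over 13
conditions with a uniform prior, compared by accuracy, confusion and
plug-in mutual information in bits.

## Worked example

```r
library(popcoupling)

sim   <- simulate_default_population(seed = 1)   # 100 neurons, 10 blocks
graph <- build_functional_graph(sim$dataset)
print(graph)
suite <- run_model_suite(sim$dataset, graph)
print(suite)

coupled   <- fit_coupled_decoder(sim$dataset, suite, graph)
uncoupled <- fit_uncoupled_decoder(sim$dataset, suite$split$train)
evaluate_decoding(decode_coupled(coupled, sim$dataset, graph))$accuracy
evaluate_decoding(decode_map(uncoupled, sim$dataset))$accuracy
```

Output:

```
Functional graph: 100 neurons, 4950 edges (1238 strong, |w| >= 0.0994)
  bidirectional: 16.5%; lags 0-1: 27.9%; lag filter: {0,1}
Encoding-model comparison (percent change in test MSE vs unrestricted)
              variant subset median_pct_change iqr_pct_change median_test_mse
1 coupling_restricted    all         85.238453       176.8227          0.9485
2           lag0_only    all          0.133012         1.9950          0.5351
3           lag1_only    all         80.172990       149.7374          0.9097
4       negative_only    all         80.138078       159.5102          0.9027
5       positive_only    all          2.960969         9.6743          0.5538
6      run_restricted    all         -0.001389         0.3982          0.5071
7     stim_restricted    all          0.333635         2.8470          0.5038
8        unrestricted    all          0.000000         0.0000          0.5066
[1] 84.18889   # coupled accuracy (%)
[1] 54.37778   # uncoupled accuracy (%)
```

Reading the numbers: the coupling-restricted model's large median MSE
increase means the functional group explains single-trial variance that the
stimulus and running terms cannot; the near-zero stimulus- and
run-restricted changes mean those global descriptions add little once
coupling is conditioned on; and the coupled decoder's higher accuracy shows
the same coupling structure is useful for reading the stimulus back out.

## Package layout

- `R/synthetic.R` — protocol, ground-truth coupling, tuning, simulator
- `R/network.R` — partial correlations, correlograms, graph assembly
- `R/encoding.R`, `R/suite.R` — regressors, least squares, model ladder
- `R/permutation.R` — strong-weight / strong-edge shuffles
- `R/decoding.R` — coupled and uncoupled MAP decoders, confusion, MI
- `R/pipeline.R` — end-to-end orchestration and reporting
- `vignettes/coupled-population-models.Rmd` — methods and design choices
- `inst/scripts/run_pipeline.R` — shell entry point for the full pipeline
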