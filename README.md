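# mpnet

Simulation and population-dynamics analysis of **multi-plasticity
networks (MPNs)** — feedforward networks that process sequences with no
recurrent connections at all, storing and updating information instead in
fast, decaying **synaptic modulations** — together with the recurrent
baselines (Vanilla RNN, GRU) they are compared against.

The package is aimed at computational neuroscientists who want to study
what synaptic plasticity alone can compute, and how its neural-population
signature (input-locked activity clusters, activity-silent delays, a
single point-like attractor) differs from the attractor dynamics of
recurrent networks.

## The model

The MPN is a two-layer network whose input weights are element-wise
modulated by a synapse-modulation matrix *M*:

```
h_t = tanh[ ((M_{t-1} + 1) ⊙ W_inp) x_t + b ],      y_t = W_RO h_t + b_RO
M_t = λ M_{t-1} + η h_t x_tᵀ                        (associative rule)
```

with `M_0 = 0`, learned plasticity scalars `η` (size/sign of modulation)
and `λ ∈ [0, λ_max]` (decay, `λ_max = 0.95`). Variant update rules:
presynaptic-only (`η 1 x_tᵀ / n`), postsynaptic-only (`η h_t 1ᵀ / d`),
and an additive variant (`M` adds to the weights). Everything — batched
compiled forward/backward passes, Adam + L1 training with rolling
validation stopping, generative integration tasks (delay, retrospective /
prospective context, continuous, true–anti), analytical approximations of
the dynamics, and the analysis suite (participation-ratio dimensionality,
variance decomposition, linear / cross-time decoding, readout alignment,
go-signal projection, readout difference, activity-silence diagnostics) —
is in this package; there are no external data dependencies.

## Worked example

Train an MPN on the two-class integration task (sequence length
`T = 20`, input size `d = 50`, hidden size `n = 100`, 10% input noise)
and look at its population dynamics:

```r
library(mpnet)

cfg  <- model_config("mpn", d = 50, n = 100, N = 2)
task <- task_spec("simple", N = 2, T = 20, d = 50)

count_trainable_params(cfg)$core     # 5102 core parameters (+200 readout)

fit <- train(cfg, task, train_config(), seed = 1)
fit
#> <mpn_fit> mpn on simple task: 2000 batches, stop = accuracy, final val acc 0.996

evaluate_accuracy(fit, n_examples = 1000, seed = 99)
#> [1] 0.998

fit$params$eta; fit$params$lam       # learned plasticity: 2.94, 0.95 (at ceiling)

st <- collect_states(fit, m = 1000, which = "hidden", seed = 101)
participation_ratio(fit_pca(st))
#> [1] 2.245245
variance_explained(st, "present_input")
#> [1] 0.7855463
variance_explained(st, "accumulated_evidence")
#> [1] 0.2509151
```

Reading the numbers: the trained network classifies essentially
perfectly; its hidden activity is ~2-dimensional (participation ratio
2.2); and that activity is dominated by the *current input symbol*
(~0.79 of per-neuron variance) rather than by the accumulated evidence
(~0.25) — the opposite of a recurrent integrator, whose state tracks
evidence along a line attractor. The evidence lives instead in the
modulation state `M_t`: `collect_states(fit, which = "modulation")`,
`go_signal_projection()`, and `novel_class_probe()` expose it.

Experiment-level drivers (`sweep_capacity()`, `sweep_noise()`,
`long_time_behavior()`, `activity_silent_report()`,
`sequential_learning_protocol()`, `bounded_modulation_comparison()`, and
the `reproduce("<preset>")` pipelines) script the full comparisons
against the RNN baselines.

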