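---
title: "Computing with synaptic modulations: models, tasks and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing with synaptic modulations: models, tasks and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpnet)
```

## The model family

Recurrent networks hold task information in persistent neural activity.
The multi-plasticity network (MPN) holds it somewhere else: in fast,
decaying modulations of its synapses. Architecturally the MPN is nothing
but a two-layer feedforward network — input layer of size $d$, hidden
layer of size $n$, linear readout with $N$ outputs — whose input weights
$W^{\mathrm{inp}}$ are element-wise modulated by a synapse-modulation (SM)
matrix $M_t$ that changes at every time step:

$$
h_t = \phi\!\big[\big((M_{t-1} + 1) \odot W^{\mathrm{inp}}\big)x_t + b\big],
\qquad y_t = W^{RO} h_t + b^{RO},
$$

with $\phi = \tanh$ by default, $b = b^{RO} = 0$, and $M_0 = 0$ (so an
unmodulated MPN is exactly the feedforward network). The SM matrix decays
and is incremented by a local Hebbian-style rule:

* **associative** (the default; pre- and postsynaptic):
  $M_t = \lambda M_{t-1} + \eta\, h_t x_t^{\top}$,
* **presynaptic only** ("MPNpre"): $M_t = \lambda M_{t-1} + \tfrac{\eta}{n}\mathbf{1}x_t^{\top}$,
* **postsynaptic only**: $M_t = \lambda M_{t-1} + \tfrac{\eta}{d}h_t\mathbf{1}_d^{\top}$,
* **additive**: associative update, but the SM matrix *adds to* rather
  than multiplies the weights, $h_t = \phi[(M_{t-1}+W^{\mathrm{inp}})x_t + b]$.

The two plasticity scalars are learned: $\eta \in (-\infty, \infty)$ sets
the size and sign of modulations, and $\lambda \in [0, \lambda_{\max}]$
their decay, with $\lambda_{\max} = 0.95$ by default so memory fades over
tens of steps ($0.95^{20} \approx 0.36$, $0.95^{40} \approx 0.13$). We
project $\lambda$ back into its box after every optimizer step; in
practice it saturates at $\lambda_{\max}$, as expected for an
integration task that rewards long memory. An optional element-wise bound
$|M_{iI}| \le m_b$ (clipped after the full decay-plus-increment update,
which keeps the state inside the bound by construction) models the
biological ceiling on how far a synapse can be modulated.

Because the classification is read out from $h_T$, which depends on
$M_{T-1}$, every "final state" analysis in this package uses $M_{T-1}$.

The recurrent baselines are a Vanilla RNN,
$h_t = \phi(W^{\mathrm{rec}}h_{t-1} + W^{\mathrm{inp}}x_t + b)$, and a
standard GRU (update gate $u_t$, reset gate $r_t$, candidate state). For
these the hidden bias is trainable (their standard parameterization); for
the MPN it is zero unless requested. Core parameter counts follow the
usual conventions: $n(d{+}1){+}2$ for the MPN against $n(n{+}d{+}1)$ and
$3n(n{+}d{+}1)$ for the RNN and GRU — at the package's reference sizes
($d = 50$, $n = 100$) the MPN trains roughly a third of the RNN's and a
ninth of the GRU's parameters.

## Tasks

All data are generative; there is no external dataset. In the N-class
integration task each sequence is $T$ steps of $d$-dimensional inputs: a
stimulus period whose steps are evidence symbols for one of $N$ classes
or a null symbol, an optional delay (zero input), and a final go signal.
Each symbol maps to a fixed random binary codeword with elements drawn
uniformly from $\{0, \sqrt{2/d}\}$, which fixes three moments the
analysis relies on: $E\|x\|^2 = 1$, $E(x \cdot x') = 1/2$, and
$E\|x \odot x'\|^2 = 1/d$. The last of these is why modulation effects
are *subleading*: any term carrying a Hadamard product of two codewords
is $O(1/d)$ relative to a bare codeword term.

Sequences are sampled uniformly over *evidence vectors* (per-class
counts with a unique maximum; ties are rejected), then uniformly over
orderings of the implied symbol multiset. Small supports are enumerated
exactly; large ones are sampled by stars-and-bars unranking, which is
uniform without materializing the support. Isotropic Gaussian noise with
expected squared magnitude `noise_mag`$^2$ (default $0.1^2$, a
signal-to-noise ratio of 10) is added to every step, delay and go
included.

Variants: the **contextual** task concatenates two independent two-class
streams on complementary halves of the input and cues (after the
stimuli, mid-delay, in the retrospective case; before them in the
prospective case) which stream's label to report — layout
19 stimulus + 10 delay + 5 context + 5 delay + go at $T = 40$; the
**continuous** task replaces discrete counts by a scalar signal
$s_t \sim \mathcal{N}(\mu, T/750)$, $\mu \sim U[-0.1875, 0.1875]$,
multiplying a single codeword, labelled by the sign of $\mu$ (we read
$T/750$ as a variance; the alternative reading — a standard deviation —
would make the per-step noise independent of $T$, defeating the stated
purpose of keeping difficulty comparable across lengths); the
**true-anti** task adds a cue codeword to every stimulus step that tells
the network to report the argmax or the argmin of the evidence. A fixed
random affine map (`make_input_projection()`) adapts external
low-dimensional task streams, so delay periods with zero external input
still drive the modulations.

## Training

Networks minimize softmax cross-entropy of the final-step output plus an
L1 penalty ($10^{-4}$) on all trainable parameters, with Adam (constant
rate $10^{-3}$, standard moment defaults), gradients clipped to a global
norm of 10 (the conventional reading of a clipping threshold in
through-time training), and fresh generated batches at every step —
there is no finite training set to overfit. Validation accuracy and loss
are measured every 10 batches on freshly drawn examples; stopping is by
a rolling average over the last 10 measurements, either reaching an
accuracy threshold (98% for the main runs, with a minimum of 2000
batches) or a loss plateau. We operationalize "validation loss
saturated" as best-so-far early stopping — the rolling loss failing to
improve on its running minimum for 30 consecutive checks — because the
naive alternative (comparing the rolling average to its value ten
checks earlier) is a near-coin-flip whenever the loss slope is shallow
relative to validation noise: in piloting it routinely stopped
context-task runs at a transient one-subtask saddle (~72% accuracy)
that a few hundred more batches escape. Even so, loss-noise saturation
detection is intrinsically fragile, so the contextual and
bounded-modulation reproductions stop by the accuracy rule with a hard
batch cap (5000 / 4000), which reaches the same end state
deterministically; capped runs report the accuracy they attained.
Cross-entropy needs a distribution, so a softmax is applied to the
outputs; classification itself is just the argmax.

Problem sizes are deliberately desk-scale and are stated here as the
package's defaults: batch size 32 (the one minibatch size the protocol
states explicitly; the sequential-learning protocol uses batch size 1
as specified, with L1 reduced to $10^{-6}$ and a cap of $10^5$ training
samples), 250 validation examples per measurement (a stopping decision
therefore averages 2500 fresh examples, giving a rolling-accuracy
standard error near 0.3%), and 5 initialization seeds for every
averaged statistic. Training is bitwise reproducible for a given seed:
all randomness flows through R's RNG, and the compiled forward/backward
passes are deterministic double-precision code verified against the
pure-R reference steps and against central finite differences.

One interaction deserves a warning. An L1 subgradient fed through Adam
exerts a *scale-free* pull: any parameter whose task gradient falls below
the L1 coefficient is driven toward zero at the full learning rate. On
the short tasks this is harmless (it is part of why solutions are
sparse), but on the $T = 40$ integration-delay tasks the GRU's initial
through-time gradients are small enough that every weight collapses to
the pure-regularizer fixed point within a few hundred batches and
accuracy never leaves chance — for any seed we tried, while the MPN
(whose final go step drives its gradients directly) trains unharmed.
The GRU's delay-task experiments therefore run at `l1 = 1e-5`, the
largest coefficient at which it learns (reaching ~99%); the default
stays `1e-4` everywhere else, and the sequential-learning protocol uses
its prescribed `1e-6`. The same mechanism makes very small MPNs
($n \sim 8$, $d \sim 10$) fragile: their only task-signal pathway is the
$O(1/d)$ modulation term, and the regularizer can crush $\eta$ before
learning bootstraps, which is why the micro-scale unit tests probe
training mechanics with the quickly-converging RNN and the full-scale
MPN claims live in the acceptance suite.

Two findings from piloting the training scale are worth recording.
First, the learned $\eta$ of the associative MPN — and with it the
balance between input-driven and evidence-driven hidden variance — is
sensitive to the total number of training examples, which the protocol
does not pin down; our defaults give $|\eta| \approx 3$ and a
present-input variance share near 0.79. Second, the presynaptic-only
variant needs $\eta$ of order $n$ for its $\eta/n$-scaled modulations to
matter, and Adam raises $\eta$ by roughly the learning rate per step, so
MPNpre approaches its ceiling much more slowly than the other variants;
the same consideration is milder for the postsynaptic variant (scale
$\eta/d$), which trains to ~99% under the default protocol.

## Analyses

All state-space analyses run on a test population: `collect_states()`
stacks hidden activity $h_t$ ($t = 1..T$) or flattened SM matrices $M_t$
($t = 0..T$) over fresh sequences, with per-row annotations (label,
present symbol, running class-1 minus class-2 evidence count, inclusive
of the current step — the convention consistent with $M_t$ containing
$x_t$).

* **Dimensionality**: centered PCA (component signs fixed by making the
  largest loading positive) and the participation ratio
  $\mathrm{PR} = (\sum_\alpha v_\alpha)^2 / \sum_\alpha v_\alpha^2$ of
  the variance ratios.
* **Variance decomposition**: multi-output OLS of the states on either
  the scalar accumulated-evidence predictor or indicator coding of the
  present input (null as reference); the reported $r^2$ is the uniform
  average over state features of per-feature $r^2$, matching the default
  multi-output score of the regression tooling the protocol names.
  Both are in-sample fits with an intercept, so the value is in [0, 1].
* **Decoding**: balanced-class-weight linear max-margin classifiers
  (one-vs-rest beyond two classes) under 10-fold cross-validation, per
  time step and across time steps (train at $t_1$, test at $t_2$, folds
  held fixed so train and test examples never overlap).
* **Activity silence**: mean absolute hidden activity
  $\bar h_t = \tfrac1n \sum_i |h_{i,t}|$ and a normalized time
  variability — per neuron, the variance over a $\tau$-step rolling
  window divided by the window's mean square (population variance, so an
  alternating $\pm c$ window scores exactly 1); windows with zero energy
  are excluded.
* **Go-signal projection and readout difference**: any stored $M$ maps
  to the hidden activity it *would* produce if the go signal arrived
  now; on the contextual task the projected outputs, grouped by (subtask
  label, subtask, context), give the mean readout margin per subtask —
  the readout difference — whose collapse for the un-cued subtask after
  context onset is how the network discards irrelevant information.
* **Attractor geometry**: the angle between top principal directions
  (absolute cosine, removing sign ambiguity) measures how much an RNN's
  line attractor reorients, e.g. across sequential learning.

## Analytical approximations

Unrolling the associative update gives
$M_t = \eta \sum_{s=0}^{t-1} \lambda^s h_{t-s} x_{t-s}^{\top}$ — an
exact identity used as an oracle for the recursion (invalid under
bounds, where clipping breaks linearity). Because modulation effects are
$O(1/d)$, replacing $h$ by its feedforward approximation yields the
leading-order state
$\hat M_t = \lambda \hat M_{t-1} + \eta\,\phi(W x_t + b)x_t^{\top}$ and
the leading-plus-subleading hidden activity

$$
\hat h_t = \phi\Big(W x_t + b + \eta \sum_{s=1}^{t-1} \lambda^{s-1}
\phi(W x_{t-s} + b) \odot \big(W (x_t \odot x_{t-s})\big)\Big).
$$

The $\lambda^{s-1}$ weighting follows from substituting the unrolled
$M_{t-1}$ into the hidden-activity map (term $s$ carries the decay
accumulated since input $t-s$ entered the state); we re-derived it and
verified numerically against the exact recursion that it, and not
$\lambda^{s}$, is correct. For the presynaptic variant the corresponding
forms are exact, not approximate, since its modulations never feed back
through $h$. Prediction error is the relative norm
$\|\hat h_t - h_t\|/\|h_t\|$ (Frobenius for matrices); it decreases
with both $d$ and $n$, as the Hadamard scaling predicts, and the package
checks that monotonicity on random-weight networks with representative
plasticity values ($\eta = 1$, $\lambda = 0.95$) — the scaling is a
property of the architecture and codebook statistics, not of training.
For RNNs the comparison point is the standard linearization about a
slow point under zero input (`find_slow_point()` runs a quasi-Newton
descent on $\|h - F(h,0)\|^2$; tolerance $10^{-8}$), whose
near-unit-modulus eigenmodes are the integrator directions.

## What the generator does and does not emulate

The synthetic tasks reproduce the statistical structure the analyses
need — codebook moments, uniform evidence vectors, controlled
signal-to-noise, delay and context timing — but they are still
caricatures of behaving-animal data: inputs are i.i.d. across steps
given the evidence vector, noise is isotropic Gaussian, classes are
uncorrelated, and timescales are abstract steps rather than
milliseconds. Tests passing on these tasks show the implementation is
faithful to the model and protocol; they do not certify behavior on
correlated stimuli, structured noise, or continuous-time data.

## Numerical choices and degenerate inputs

Double precision everywhere; compiled passes are plain deterministic
loops (no threading), so results are bitwise reproducible per seed.
Zero-variance populations are flagged degenerate by `fit_pca()` rather
than fit; zero-norm references make the relative error `NA` with a
warning; evidence sampling rejects ties by construction and errors if
the support is empty; `train()` reports divergence (non-finite loss)
with the last valid state instead of crashing. Decoder regularization is
left at the conventional cost of 1 (only the iteration cap and balanced
weights are specified by the protocol); fold assignment is seeded.
λ clamping, not reparameterization, enforces the decay ceiling — the
simplest projection consistent with the observed saturation at
$\lambda_{\max}$; the clamp means no gradient distinguishes values at
the boundary, which is immaterial in practice since the optimum sits
there.

## Known limitations

The LSTM appears only in the parameter-count rule; there is no all-step
training mode (it exists only for external task batteries, for which
this package provides just the input adapter); no continual-learning
mitigations, learning-rate schedules, or curriculum training; no
fixed-point continuation beyond the single slow-point descent; and the
trained-statistics targets that depend on the learned $\eta$ scale
(present-input variance share, the RNN's evidence share) reproduce the
protocol but remain sensitive to training-scale choices the protocol
leaves open, as discussed above.
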