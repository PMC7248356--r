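---
title: "Contextually adaptive G-networks: model, learning and experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextually adaptive G-networks: model, learning and experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cannets)
```

## The model

A G-network (random neural network) is a network of spiking units whose
interactions are Poisson streams of excitatory (+1) and inhibitory (−1)
impulses. Each directed edge carries two non-negative rate weights,
`w⁺(i,j)` and `w⁻(i,j)` (events per unit time). A neuron with positive
potential fires at rate

\[ r_i = (1 - d_i)^{-1} \sum_j \left[w^+(i,j) + w^-(i,j)\right], \]

routing each impulse to target `j` with probability `w±(i,j)/r_i` or out of
the network with the departure probability `d_i`; these probabilities sum
to one by construction (`check_conservation()` verifies the identity to
1e-12). Neurons without outgoing weights (output units) take an explicit
firing rate `r_sink`, because the rate formula is 0/0 for them; the
default is 1.

The stationary distribution has product form,
\(P(k) = \prod_y (1-q_y)\, q_y^{k_y}\), with excitation probabilities
solving

\[ q_i \;=\; \frac{\Lambda_i + \sum_j q_j\, w^+(j,i)}
                 {r_i + \lambda_i + \sum_j q_j\, w^-(j,i)}, \]

where `Λ, λ` are the external excitatory/inhibitory Poisson arrival rates.
The product form requires every `q_i < 1`; a fixed point touching 1 means
the network has left this regime, and the solver treats it as an error
rather than silently clipping (prediction is the one exception, below).

Assumptions inherited from the formalism: impulses are unit-valued
("bipolar trains" are read as the standard ±1 semantics), negative
impulses floor potentials at zero, and self-loops are excluded (zero
weight-matrix diagonals).

### Solver

`solve_steady_state()` uses damped successive substitution from `q = 0`
(damping 0.5, tolerance 1e-10, at most 10 000 iterations; the inner loop is
compiled). The map is monotone from below, so iteration from zero converges
to the least fixed point, and damping prevents oscillation in strongly
inhibitory networks. The residual is the unrelaxed update norm
`max |T(q) − q|`.

### Simulator as oracle

`simulate_network()` is an exact event-driven simulation of the
continuous-time Markov chain, with competing exponential clocks for the
external arrival streams and the firing of every excited neuron. It shares
no code path with the solver, which makes it an independent oracle: the
time-weighted activation frequencies must converge to `q`, and the
occupancy histogram of a small network must match the product form (both
are asserted in the tests, the latter within total-variation distance 0.02
at 10⁶ events).

The reported standard error is binomial-style per neuron,
`sqrt(p(1−p)/N_i)` with `N_i` the number of events that addressed neuron
`i` (its arrivals, firings and received impulses) — each such event is one
observation of that neuron's state process. Two caveats are deliberate:
the total event count would overstate `N_i` by roughly the network size,
and autocorrelation of the time average inflates the true error near
saturation. The oracle-agreement test therefore uses random networks with
moderate excitation (`q ≤ 0.35`), where the approximation is adequate; at
`q` near 1 the 3-standard-error band is not trustworthy at any event
count.

## Architecture

`cann_config()` declares the network: parallel CAN-carrying streams ×
layers × CANs per cell, fed by RF and LCF input fields (streams 1 and 2),
with the UCF units forming a broadcast stream of their own (so
`n_streams = 3` means two CAN streams plus the UCF stream). The default
configuration — 2 CAN streams × 3 layers × 2 CANs, 4 RF + 4 LCF inputs,
8 UCF units, one output — expands to exactly 29 neurons.

Connection rules: inputs feed the first-layer CANs of their stream;
consecutive layers are fully connected within a stream; every CAN connects
laterally to all CANs of adjacent streams in its own layer (for two
streams each is the other's neighbour; for more, neighbours are adjacent
indices, non-circular); UCF units broadcast to every CAN; last-layer CANs
feed the output. Every structural connection, including those from the
input fields, carries an independent excitatory and inhibitory learnable
weight — the inhibitory input weights are what give contextual units
divisive gain control over a stream, since they enter the denominators of
the network equations.

### Initial weights and stability

Weights are drawn uniformly from `(0, init_weight_scale]` with the
configuration seed and then row-normalized: input rows to total rate 2 and
CAN rows to `can_row_mass` (default 6). The draws set the proportions; the
normalization sets the scale, for a stability reason: an input neuron
receiving external drive up to the encoding rate scale `ρ ≤ 1` has
`q = Λ/(r + λ) ≤ ρ/2` when its service rate is 2, and a CAN with service
mass 6 stays well below saturation under the worst-case excitatory load of
the default fan-in. A single global draw scale cannot satisfy both the
input neurons (which need `r ≥ ρ`) and the deep layers simultaneously,
which is why the row masses, not the draw scale, carry the units.

### Input encoding

`encode_features()` min-max scales each feature to `s ∈ [0, 1]` (clipping
outside the bounds) and emits the arrival pair `Λ = s·ρ`, `λ = (1−s)·ρ`:
total exogenous drive per input neuron is constant and the balance encodes
the value. UCF bits are encoded directly (`Λ = ρ` for a 1, `λ = ρ` for a
0). Feature vectors longer than an input field are block-averaged onto it.

## Learning

The cost is `C = Σ 0.5 (q_out − target)²`. Gradients with respect to every
rate weight are exact, by implicit differentiation of the steady state:
linearise the fixed-point map (`J[i,k] = ∂q_i/∂q_k`), solve the adjoint
system `(I − J)ᵀ λ = ∂C/∂q` once per sample, and chain through both the
direct weight effect and the weight's effect on its own row's firing rate.
The tests hold these gradients to central finite differences within
relative error 1e-5 on random networks. One subtlety the finite-difference
oracle confirmed: the gradient of a weight that is its neuron's *only*
outgoing edge is exactly zero, because the firing-rate dependence cancels.

Training is per-sample stochastic gradient descent in a freshly shuffled
order each epoch (seeded, hence bit-reproducible), with plain GD or
RMSProp (decay 0.9, epsilon 1e-8 — conventional values; default learning
rate 0.01, default 150 epochs). After every update the weights are
projected onto the feasible set:

* non-negativity (weights are rates);
* a service floor on trainable rows of `1.1 × max_samples(Λ_i)` (never
  below 0.05), which provably keeps input neurons inside the product-form
  regime whatever the optimizer does;
* reactively, if a solve still saturates after an update, the saturated
  neuron's departure probability is raised (inflating its service rate
  without injecting extra downstream excitation) and the step is retried;
  a saturated fixed-rate output instead has its excitatory in-column
  damped. An earlier design enforced a conservative worst-case floor on
  every row; it guaranteed stability but measurably distorted
  optimization, so the minimal-plus-reactive scheme replaced it.

When validation samples are supplied, the returned network is the epoch
snapshot with the lowest validation MSE — the experiments use a
64/16/20 train/validation/test split by sequence, mirroring the standard
protocol for this task family.

For prediction (`predict_gnetwork()`, `predict_cann()`) a saturating input
is clipped rather than raised as an error: an unstable neuron's activation
fraction tends to one, so `q = 1` is the physically sensible limit, and
held-out evaluation stays defined.

## Information decomposition

All quantities are in bits with `0·log 0 = 0`, computed on a discretized
4-way table over (X = RF, Z = LCF, U = UCF, Y = output). Entropies of
marginals, conditional entropies via the chain rule, mutual information
`I(A;B) = H(A) − H(A|B)` and conditional mutual information
`I(A;B|C) = H(B|C) − H(B|A,C)` are exact on the table.

The four-way interaction term is canonically
`I(X;Y;Z;U) = I(X;Y) − I(X;Y|Z,U)`. The other four pair-anchored
expressions of the same shape are *not* equal to it for general
distributions; `four_way_interaction()` evaluates all five and reports the
maximum pairwise discrepancy as a diagnostic instead of assuming zero.
Consequently the output-entropy decomposition

`H(Y) = I₄ + I(Y;X|Z,U) + I(Y;Z|X,U) + I(Y;U|X,Z) + H(Y|X,Z,U) + residual`

carries a residual, which equals `I(Y;Z|X) − I(Y;Z|X,U)` analytically
(verified on random tables); for Y = Z⊕U with X independent it is −1 bit.
In the weighted objective `F`, the weight `φ₀` multiplies the four-way
term; with `φ₀ = φ₁ = 1` and the rest zero, `F = I(Y;X)` is an exact
identity (the term is Y,X-anchored), while the analogous LCF/UCF cases
hold only up to the four-way discrepancy.

`estimate_pmf()` is the plug-in estimator: equal-width bins per variable
over the observed range (default 8; a constant column collapses to one
degenerate bin). Equal-width binning trades bias for simplicity: for a
bivariate Gaussian with ρ = 0.9 the discretization loses ≈ 0.13 bits at 16
bins and ≈ 0.06 bits at 24, which is why the estimator-accuracy tests use
24 bins for a 0.1-bit tolerance at 10⁵ samples. Finer binning raises the
small-sample plug-in bias instead (roughly `cells/(2N ln 2)`), so the bin
count is a genuine trade-off the user owns.

## The synthetic multimodal generator

`generate_dataset()` emulates the statistical structure of an
audio-visual-style task directly in feature space:

* **clean**: per-dimension stationary AR(1) sequences (smoothness 0.9,
  unit variance) — smooth trajectories standing in for log-filterbank
  tracks;
* **RF**: clean mixed with broadband Gaussian noise at a nominal SNR, so
  the empirical per-sequence SNR equals the nominal one exactly. Sequences
  rotate through the nine mixing levels −12, −9, …, 12 dB, the standard
  multi-condition design, which gives every environment balanced coverage;
* **environments**: five equal-width SNR bands over [−12, 12]
  (restaurant, cafe, public transport, pedestrian area, home, noisiest to
  quietest), each mapped to a fixed 8-bit UCF codeword. The codewords have
  pairwise Hamming distance ≥ 4 and constant weight (four active bits), so
  the pattern injects the same total drive in every environment and only
  its shape is environment-specific;
* **LCF**: a fixed random linear map of the clean features plus Gaussian
  noise with `lcf_noise_sd = 0.7`. The noise is independent of the
  acoustic SNR — visible articulators are unaffected by acoustic noise —
  and its level deliberately places the visual stream's reliability
  *between* the acoustic extremes, so the streams cross over near
  mid-range SNR: visual beats audio in loud environments and loses to it
  in quiet ones, the regime audio-visual perception studies describe;
* **target**: one chosen clean coefficient, min-max scaled into
  [0.05, 0.95] so it is attainable by an output excitation probability.

Default sizes (30 sequences × 20 frames, 4 feature dimensions) are desk
scale: small enough for the full ablation to run in minutes on one CPU.
What the generator does **not** emulate: real spectro-temporal structure,
speaker variability, non-stationary noise, the visual feature extraction
chain, or corpus scale (the real task trains on hundreds of thousands of
coefficient samples). Passing tests on this generator exercise the
machinery and the qualitative structure, not corpus-level performance.

`frame_signal()` and `mix_at_snr()` provide the framing/SNR arithmetic for
waveform-like inputs (e.g. 50 kHz × 16 ms → 800-sample frames; the
"increment rate" is read as the hop fraction of a frame, so 62.5% means
37.5% overlap).

## Experiments

`run_ablation()` compares three variants per seed — RF-only, RF+LCF,
RF+LCF+UCF — built by removing the unused input fields while keeping the
CAN fabric identical, trained identically, and scored on the held-out test
split. `modulation_analysis()` quantifies LCF influence per environment
two ways, because "amplification/suppression" has no single canonical
metric: (a) perturbation sensitivity — the mean absolute output change per
unit shift of the scaled LCF inputs (±0.05) — and (b) the plug-in
conditional mutual information `I(Y;Z|X,U)` between output and LCF given
RF and environment; both are summarised by their Spearman rank correlation
against the environments' mean SNR.

### What emerges at desk scale, and what does not

Two results are robust in the test suite: the two-stream model beats the
audio-only model on every seed (the visual stream is genuinely
disambiguating), and a *hand-built* teacher whose LCF path is gated by
quiet-band UCF units shows exactly the expected signature (strongly
negative Spearman correlation, quiet-band sensitivity an order of
magnitude below the noisy bands) — the architecture can express
environment-gated modulation, and the analysis detects it.

Two further properties are asserted in the acceptance suite and currently
fail, deliberately left red rather than weakened: that the three-stream
median MSE beats the two-stream one, and that *trained* models show the
gating signature. Trained networks do recruit the UCF units heavily (their
inhibitory mass grows by an order of magnitude during training) but with
nearly uniform weights across the codewords, i.e. as a constant divisive
bias rather than an environment discriminator; the environment-conditional
signal that would differentiate them sits below the stochastic-gradient
noise floor at desk-scale sample sizes (hundreds of records, versus the
hundreds of thousands used in the corpus-scale version of this task).
The conclusion from the diagnostics is a capacity-of-learning limit, not a
capacity-of-model limit.

## Known limitations

* Steady state only: no transient (time-dependent) distributions.
* Single signal class; no batched-signal G-network extensions.
* The plug-in information estimator has the usual histogram bias; no
  continuous (differential) estimators are provided.
* The stability projection guarantees the product-form regime only for
  input neurons; interior saturation is handled reactively during
  training and by clipping during prediction.
* The modulation metrics are surrogates; neither is claimed to be the
  definitive operationalisation of contextual amplification/suppression.
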