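---
title: "Modeling familiarity training and manifold compression in a recurrent cortical circuit"
author: "famcirc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling familiarity training and manifold compression in a recurrent cortical circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Repeated exposure to a set of visual stimuli suppresses the population-averaged
neural response to those stimuli while sharpening the tuning of individual
neurons — the familiarity effect observed from early visual cortex to IT.
famcirc implements a mechanistic account: a retinotopic sheet of
excitatory-inhibitory (E-I) rate neurons, driven by a convolutional
sparse-coding front end, whose horizontal excitatory connections are plastic.
Hebbian-family learning on those connections suffices to produce familiarity
suppression, tuning sharpening, and — the package's second theme — a
*manifold transform*: the steady-state representations of noisy variants of a
familiar image are compressed relative to the distances between different
familiar images, yielding noise-robust encoding. A linearization of the
trained attractor dynamics decomposes this compression into *collective
modes* of the recurrent gain and asks whether learning modulates their
spectrum or their alignment with signal directions.

# The circuit model

One hypercolumn sits at every position of an `nRows x nCols` grid and holds
`nChannels` excitatory neurons (one per sparse-coding feature channel) plus
the same number of inhibitory neurons. With `r = (re, ri)` the rate state,
the dynamics are forward-Euler integrations of

    tauE * dre/dt = -re + sigma(Wee re + Wei ri + alpha)
    tauI * dri/dt = -ri + sigma(Wie re)

with the squared rectifier `sigma(z) = max(z, 0)^2` (a supralinear,
stabilized-network-style activation) and the sparse code `alpha` as
feedforward drive to the excitatory population only. The inhibitory update
uses the pre-update excitatory rates; one integration step advances both
populations by `dt`.

Connectivity is built from two neighborhood rules:

* every excitatory neuron receives plastic E-E projections from all channels
  of the hypercolumns within Chebyshev radius `radiusE` of its own (clipped at
  the grid border), initialized uniformly so each row of `Wee` sums to the
  synaptic resource `wEE`;
* every inhibitory neuron collects from the *same-channel* excitatory neurons
  within radius `radiusI` (surround suppression) and from the other channels
  of its own hypercolumn (divisive normalization), with total strength `wIE`
  spread uniformly over the actual (clipped) presynaptic set; it inhibits
  every excitatory neuron with the fixed weight `-1/Ni`.

For interior neurons these sets have the textbook sizes
`nChannels * (2*radiusE + 1)^2` and `(2*radiusI + 1)^2 + nChannels - 1`; at
borders the package keeps row sums exact by normalizing over the clipped
sets rather than the printed formulas.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `tauE`, `tauI` | 40, 20 | time units | membrane time constants; inhibition twice as fast |
| `dt` | 1 | time unit | Euler step; a 300-step presentation is "300 ms" |
| `wEE` | 5 | weight | per-neuron E-E synaptic resource (conserved) |
| `wIE` | 20 / 30 | weight | total E-I strength; the stability knob (below) |
| `radiusE`, `radiusI` | 2, 1 | hypercolumns | excitatory / inhibitory reach |
| `inputScale` | 30 | — | drive multiplier, accelerates learning |
| `tauW` | 2e9 | time units | synaptic time constant (both rules) |
| `tauXi` | 2e7 | time units | BCM threshold time constant |

`wIE` deserves emphasis: with a supralinear activation, runaway mutual
excitation of a learned cell assembly is the failure mode of this circuit,
and the total inhibitory strength is the one parameter that is tuned to keep
the network stable rather than derived from physiology. The package treats
it exactly that way (see *Scaled profile* below).

# Plasticity

Only `Wee` is plastic, and only on its initial support. Two rules are
implemented, applied at every integration step during a stimulus
presentation using the current-step rates:

* **BCM**: `dW[k,l] = dt/tauW * r[l] * r[k] * (r[k] - xi[k])`, with the
  sliding threshold `xi` an exponential moving average of the squared rate
  (`tauXi`). Each neuron's threshold starts at its time- and
  stimulus-averaged response in the pre-trained network. Weights are clipped
  at zero from below after each update — E-E synapses stay excitatory; the
  alternative (transient negative weights) is not biologically interpretable
  here and the clipped rule still reduces exactly to the Hebbian rule when
  `xi = 0`.
* **general Hebbian**: `dW[k,l] = dt/tauW * r[l] * r[k]^2`, always
  potentiating.

After every presentation each row of `Wee` is rescaled multiplicatively to
its resource `wEE` (synaptic scaling). Under the Hebbian rule this
normalization is what implements depression: potentiating the most
correlated inputs forces compensatory weakening of the rest, as in Oja's
rule. Normalizing per presentation rather than per step keeps the cost of
training low; the conservation invariant (row sums equal `wEE` to 1e-10)
holds at every probe either way, and within a presentation the accumulated
update is of order 1e-4 of the resource, so the cadence is immaterial. Rows
that decay to zero (never observed in practice) are reset to the uniform
initial profile rather than left undefined.

# Sparse-coding front end

Images are encoded by a convolutional sparse-coding model: a dictionary of
`nFilters` square filters (default 64 filters of 9 x 9 px) applied at every
stride-3 placement with no padding, coefficients inferred by ISTA on the L1
penalized reconstruction objective. A 32 x 32 image yields an 8 x 8 grid of
placements — a 4-times overcomplete code of 4096 coefficients, matching the
circuit's 8 x 8 x 64 excitatory sheet. Design choices where the underlying
description is ambiguous:

* the constraint form is written as L0 but described as an L1 penalty; we
  implement L1 (convex, and the standard inference for this front end).
  The penalty weight defaults to 0.5, calibrated once so that 5-10% of
  coefficients are nonzero on the synthetic textures;
* coefficients are signed; rectification is the neuron activation's job;
* dictionary learning alternates batch ISTA with a least-squares (MOD)
  dictionary update and unit-norm renormalization, on 50,000 (reference) or
  2,000 (scaled) random patches, per-patch mean subtracted, no whitening;
* learned filters are serializable (plain-JSON checkpoints) and held fixed
  during all circuit experiments.

The code is scaled by `inputScale = 30` before driving the network, at
training and at probe time alike.

# Stimuli

The package generates its own stimuli so that every experiment runs without
downloads. Targets are spatially correlated Gaussian textures: white noise
low-pass filtered at a correlation length of 3 px (a value in the range of
pixelwise correlation lengths of downsampled photographs), min-max
normalized to [0, 1]. Occluded variants replace `round(n * P)` distinct
pixels with independent U(0, 1) draws; each (target, level, sample) triple
hashes its own seed from the base seed, so the variant set is a *fixed*
ensemble across epochs rather than fresh noise. What the textures emulate is
the second-order spatial statistics and bounded range of grayscale natural
images; what they deliberately do not contain is higher-order structure
(edges, objects, heavy-tailed filter statistics). Passing tests therefore
demonstrate the circuit mechanisms, not performance on natural images; the
PNG loader accepts user-supplied 32 x 32 grayscale images when the original
stimuli are available.

# Protocols

Two training protocols are configured by `experimentConfig()`:

* **familiarity** (`wIE = 20`): clean targets only; each epoch presents every
  image once for 300 time units, state reset to zero before each
  presentation; probes every `probeInterval` epochs record steady states for
  all stimuli. Statistics: per-neuron suppression index
  `SI = (post - pre)/(post + pre)` (computed per stimulus then averaged;
  neurons below 1e-3 stimulus-averaged rate in both phases are excluded as
  non-responsive), Vinje-Gallant lifetime sparsity, peak responses, and the
  rank-ordered population tuning curve.
* **association** (`wIE = 30` at reference scale): targets plus the occluded
  variants; each epoch presents every clean target `targetReps` times and
  every variant once, shuffled. Probes build the fixed-point table over the
  whole stimulus set and the distance table: level distance (to the
  adjacent-lower-level samples of the same target, the clean image serving
  as the single level-0 sample), residual distance (same target and level),
  signal distance (other targets, same level), and the relative distances
  `Rlev`, `Rres` obtained by dividing by the signal distance.

Fixed points are found by integrating from the zero state until the
max-norm step change stays below 1e-6 for 20 consecutive time units, then
averaging the final 20 time units; the convergence criterion is a numerical
choice, set strict enough that the residual bound
`|r* - sigma(W r* + alpha)| < 1e-5` holds at every converged record.
Probes cap integration at 3000 time units: at the scaled profile's
inhibition strength a minority of attractors decay to tolerance only after
~2000 steps, and a shorter cap misclassifies them as non-converged.
Non-converged stimuli are flagged, logged, and excluded from distance
averages (their distances become NA rather than poisoning means).

## Scaled profile

The "reference" profile — 8 x 8 x 64 network, 25 or 155 stimuli,
80 or 350 epochs — is hours of compute. The default "scaled" profile keeps
every mechanism and every dynamical constant but shrinks the problem to
minutes on one core: a 4 x 4 x 32 circuit on 18 x 18 textures (18 px is the
smallest side giving a 4 x 4 placement grid at 9/3 filter geometry), 32
filters, 10 targets / 20 epochs (familiarity) or 4 targets x 3 levels x 4
samples, 10 target repetitions per epoch, 19 epochs with a probe after
every epoch (association).

One setting does not transfer across scale: the drive multiplier of the
association protocol. The x30 input scale exists to accelerate learning,
and at 512 excitatory neurons that acceleration is too much of a good
thing: the synaptic resource concentrates onto so few partners that mutual
excitation outruns inhibition and the integration diverges within a
handful of epochs — for any total inhibitory strength we tested between
the reference value and several times it (too little inhibition lets the
excitatory runaway win; too much drives violent relaxation oscillations).
The scaled association profile therefore keeps the reference `wIE = 30`
and runs at drive scale 10, where the same learning dynamics unfold
smoothly: the relative distances decrease steadily, the signal distance
grows while the level/residual distances hold, a minimum is reached at
epoch 18, and an abrupt partial rebound follows at epoch 19 as one
attractor restructures. Training past that point destabilizes the scaled
circuit (by about epoch 24), which is why the protocol stops at 19: the
protocol length is chosen to span the compression minimum and the onset
of the rebound while staying inside the stable regime. The restructuring
is a weight-space bifurcation, not an integration artifact — halving the
per-epoch repetitions reproduces it at the same accumulated weight
change. At full scale the rebound is gradual and the network remains
stable; the abruptness (and the eventual instability) is the price of the
512-neuron surrogate, and is the main caveat when reading scaled results.
The familiarity profile is stable at the reference drive (x30) and
inhibition (`wIE = 20`) and keeps both.

# Linear analysis

Around each converged attractor the stacked system `r = (re, ri)`,
`W = [Wee, Wei; Wie, 0]` is linearized: local sensitivities
`S' = diag(sigma'(W r* + alpha))`, recurrent gain `M = (I - S'W)^{-1}`,
Jacobian `J = M S'`. Eigendecomposing `M` gives gain modes
`(mu_i, w_i, v_i)` with biorthonormal left/right vectors and effective
input filters `vtilde_i = S' v_i`. The Gram matrix of the output patterns
is diagonalized into collective modes `(lambda_k, q_k)` with effective
input filters `phi_k`, so that the mean squared linear response to input
differences decomposes as `sum_k lambda_k |phi_k^H dalpha|^2`.

Numerical choices the derivation leaves open:

* **complex modes.** Nonsymmetric `M` has complex conjugate eigenpairs; all
  inner products are Hermitian (`G_ij = w_i^H w_j`), keeping `G` Hermitian
  positive semidefinite, its spectrum real, and the decomposition identity
  exact; outputs that must be real (alignments, distances) are real by
  construction.
* **excitatory projection.** Manifold distances use excitatory rates only,
  so the Gram matrix is formed from the excitatory blocks of the output
  patterns (`outputIdx = 1:nExc`); the decomposition then reproduces
  `||P_e J dalpha||^2` exactly, which is what the full-network distances
  measure.
* **mode tracking.** Comparing modes across training requires a
  correspondence; none is prescribed. The default matches top-`K` modes
  greedily by normalized input-filter overlap `|phi_pre^H phi_post|`;
  rank-order matching is available to check sensitivity to this choice.
* **truncation.** Linearized distances use the top `K = 10` collective
  modes by spectrum; alignments `g_k = phi_k^H <dalpha dalpha^T> phi_k` use
  unit-normalized input differences enumerated over exactly the same
  pairings as the distance classes.
* **orientation and inclusion.** A mode is signal-oriented
  (noise-oriented) when its pre-training signal alignment exceeds (falls
  below) its noise alignment — the mean of level and residual alignments —
  by more than 10% of the maximum absolute difference; change statistics
  exclude modes whose change magnitude is below 10% of the maximum change.
* **sensitivities.** With `D = sum_k lambda_k g_k`, the sensitivities of
  the fractional distance change are `dDtilde/dlambda_k = g_k,pre / D_pre`
  and `dDtilde/dg_k = lambda_k,pre / D_pre`; the weighted sums
  `sum lambda_pre * dDtilde/dlambda` and `sum g_pre * dDtilde/dg` are
  identically 1, which the tests assert to 1e-12. Attractor coordinates
  with zero drive have zero rows in `S'` and are retained (they contribute
  nothing) rather than pruned.

# Degenerate inputs and failure modes

* all-zero drive: the zero state is exactly fixed and reported as such;
* rates exceeding 1e6 raise an instability error naming the population —
  the squared rectifier is unbounded and runaway excitation must fail
  loudly;
* an ill-conditioned `(I - S'W)` (condition number above 1e12) aborts the
  linearization; a numerically defective eigenbasis falls back to a
  tolerance-truncated pseudoinverse for the left vectors and flags the
  result;
* all-zero tuning curves have undefined lifetime sparsity (NA), zero
  denominators give NA relative changes, and a zero signal distance warns
  and yields NA relative distances.

# Known limitations

* The synthetic textures lack natural-image structure; effect sizes on
  real photographs will differ (the mechanisms, not the magnitudes, are
  what the tests pin down).
* Only the excitatory horizontal connections are plastic; inhibitory
  plasticity, conductance-based neurons and cell-type diversity are out of
  scope.
* The scaled profile's statistics rest on a 512-neuron circuit; the
  magnitude (not the sign) of suppression and sparsification depends on
  the texture ensemble.
* The linearization is first-order; at high occlusion (50%) input
  differences leave the locally linear regime and the linearized distances
  are not expected to track the full ones.
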