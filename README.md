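# famcirc

Familiarity training in a plastic recurrent cortical circuit, and the
manifold transform it induces.

Repeated exposure to a set of images suppresses the population-averaged
response of visual cortical neurons while sharpening their tuning. famcirc
implements a mechanistic model of this effect for users studying recurrent
cortical computation: a retinotopic grid of hypercolumns, each with `N_d`
excitatory and inhibitory rate neurons, driven by a convolutional
sparse-coding front end and coupled by plastic horizontal excitatory
connections. The package simulates the circuit, trains it with Hebbian or
BCM plasticity, and analyses what training does to the geometry of its
attractor representations.

## The model

Rates follow forward-Euler integrations of

```
tau_e dr_e/dt = -r_e + sigma(W_ee r_e + W_ei r_i + alpha)
tau_i dr_i/dt = -r_i + sigma(W_ie r_e)
```

with the squared rectifier `sigma(z) = max(z, 0)^2` and the sparse code
`alpha` of the stimulus as drive. `W_ee` is plastic under either

* the BCM rule `dW_kl ~ r_l r_k (r_k - xi_k)` with a sliding threshold
  `xi_k` tracking the squared rate, or
* the general Hebbian rule `dW_kl ~ r_l r_k^2`,

both under synaptic-resource normalization (every neuron's total E-E
weight is held at `w_ee`), which supplies the depression that the Hebbian
rule lacks. Inhibition implements surround suppression (same feature
channel, nearby hypercolumns) and divisive normalization (all channels,
same hypercolumn).

The analysis side computes:

* **familiarity statistics** — per-neuron suppression index
  `SI = (post - pre)/(post + pre)`, Vinje-Gallant lifetime sparsity
  `S = n/(n-1) (1 - (sum r / n)^2 / (sum r^2 / n))`, peak responses,
  rank-ordered population tuning curves, PSTHs;
* **manifold metrics** — level, residual and signal distances between
  steady-state representations of occluded image variants, and the
  relative distances `R_lev = D_lev / D_sig`, `R_res = D_res / D_sig`
  whose decrease is manifold compression;
* **collective-mode linearization** — around each attractor, the recurrent
  gain `M = (I - S'W)^{-1}` is eigendecomposed, the Gram matrix of output
  patterns diagonalized into collective modes `(lambda_k, phi_k)`, and the
  squared linear response distance decomposed as
  `sum_k lambda_k |phi_k^H dalpha|^2` — separating spectrum changes from
  alignment changes, with first-order sensitivities of the compression to
  each.

Everything runs on synthetic spatially-correlated textures with
salt-and-pepper occlusion variants, so no data downloads are needed; PNG
loading is supported for real stimuli.

## Worked example

A scaled-down familiarity experiment (4 x 4 hypercolumns x 32 channels on
18 px textures, 10 target images, 20 epochs, Hebbian rule):

```r
library(famcirc)
cfg <- experimentConfig("familiarity", "scaled", seed = 101)
run <- runFamiliarity(cfg)
fs  <- familiaritySummary(run)
final <- fs$stats[[length(fs$stats)]]
round(c(meanSI = mean(final$si, na.rm = TRUE),
        meanSparsityChange = mean(final$sparsityChange, na.rm = TRUE)), 3)
#>             meanSI meanSparsityChange
#>             -0.607              0.114
```

The negative mean suppression index says the average steady response to
the now-familiar images decreased over training; the positive mean
lifetime-sparsity change says individual tuning curves became more
selective — together, the familiarity-suppression-with-sharpening
signature. `runAssociation()` runs the occluded-variant protocol and
`distanceTable()` / `aggregateDistances()` then quantify how much the
variant manifolds compressed relative to the concept manifold;
`linearize()`, `gainModes()`, `collectiveModes()` — or the one-call
`analyzeAttractor()` — dissect the mechanism mode by mode.

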