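---
title: "Quantum metric learning: model, training and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum metric learning: model, training and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmetric)
```

## The model

qmetric trains a *quantum embedding* for binary classification of tabular
data. Each sample's feature vector $f \in \mathbb{R}^n$ is first reduced to
two angles by a trainable linear map,
$(x_1, x_2) = W f$ with $W \in \mathbb{R}^{2 \times n}$ (no bias), and the
angles drive a two-qubit variational circuit
$\Phi(x_1, x_2, \theta)$ acting on $|00\rangle$. The circuit repeats four
ansatz blocks — a data-encoding pair $R_x(x_1) \otimes R_x(x_2)$, a ZZ
entangler $e^{-i\theta/2\, Z \otimes Z}$, and a trainable pair
$R_y(\theta_a) \otimes R_y(\theta_b)$ — and closes with one more encoding
layer, re-uploading the data between trainable blocks for expressivity.
That is 13 gate layers (a sequence of 14 states including $|00\rangle$) and
$3 \times 4 = 12$ circuit angles, so the full model has $2n + 12$ trainable
parameters: 72 for a 30-feature table, 1036 for 512 features, 28 after
reduction to 8 principal components.

Training minimizes the Hilbert–Schmidt cost between the two class
ensembles. With $\rho = \frac{1}{M_a}\sum_{a}|a\rangle\langle a|$ and
$\sigma = \frac{1}{M_b}\sum_{b}|b\rangle\langle b|$,

$$
D_{\mathrm{hs}}(\rho, \sigma) = \mathrm{tr}\!\left[(\rho - \sigma)^2\right]
\in [0, 2], \qquad
C = 1 - \tfrac{1}{2} D_{\mathrm{hs}} \in [0, 1],
$$

so $C = 0$ means the class ensembles are orthogonal pure states and
$C = 1$ means they coincide. A trained embedding is used by a *fidelity
kernel classifier*: the decision value of a test sample $x$ is the
difference of its mean squared overlaps with the training ensembles,

$$
f(x) = \frac{1}{M_a}\sum_a |\langle a|x\rangle|^2
     - \frac{1}{M_b}\sum_b |\langle b|x\rangle|^2
     = \langle x|\rho - \sigma|x\rangle \in [-1, 1],
$$

and the predicted class is $\mathrm{sgn}\, f(x)$.

## Circuit conventions and an inferred structure

The amplitude order is $|00\rangle, |01\rangle, |10\rangle, |11\rangle$
with qubit 1 the left position, and the rotation conventions are
$R_x(\varphi) = e^{-i\varphi X/2}$, $R_y(\varphi) = e^{-i\varphi Y/2}$,
$ZZ(\theta) = e^{-i\theta\, Z\otimes Z/2}$ — the unique sign convention
under which the layer-by-layer closed-form amplitude updates used as test
oracles hold (the ZZ gate multiplies even-parity amplitudes by
$e^{-i\theta/2}$ and odd-parity ones by $e^{+i\theta/2}$).

The gate-by-gate order of the published circuit is printed only through its
fourth state. The repetition structure used here — four blocks of
(encode, entangle, rotate) plus a closing re-encoding — is the unique
layout consistent with both the 14-state count and the 12-angle total, and
is therefore adopted as the default; `embedding_config(final_encoding =
FALSE)` gives the 12-transition variant for sensitivity checks. The
simulation is an ideal statevector evolution: no sampling noise, no gate
noise, matching a simulator-based study.

## Training protocol and its open parameters

Defaults follow the published protocol exactly: 1500 RMSProp steps, batch
size 10, step size 0.01. Choices the protocol leaves open, fixed here and
recorded in every run's metadata:

* **Batch composition.** `batch_mode = "per_class"` draws 10 samples from
  *each* class per step, because the cost requires both ensembles at every
  step; `"total"` (10 overall, redrawn if a class is empty) is available
  for sensitivity analysis. Classes smaller than the batch are sampled
  with replacement.
* **RMSProp internals.** Decay 0.9 and $\epsilon = 10^{-8}$, the
  optimizer's standard values (only the step size is stated in the
  protocol).
* **Initialization.** Not stated in the protocol; the `"normal"` scheme
  draws linear weights from $N(0, 0.1^2)$ — small enough that the initial
  encoding angles for standardized features stay within a period — and
  circuit angles uniformly on $[0, 2\pi)$, the natural uninformative choice
  for angles. Because of this, any quantitative replication carries
  stochastic (seed-to-seed) spread.
* **Gradients.** Exact forward-mode differentiation through the circuit
  (each state carries tangent vectors for $x_1$, $x_2$ and the angles; the
  overlap-form cost is differentiated pair by pair). Central finite
  differences with $h = 10^{-6}$ serve as the independent contract in the
  tests, at $10^{-4}$ relative tolerance. The trace form of
  $D_{\mathrm{hs}}$ is kept as the oracle for the pairwise-overlap
  expansion used in the training loop.
* **Reported costs.** Training and test costs are computed on the *full*
  split ensembles after training, not on the final mini-batch; the batch
  estimates appear only in the recorded cost trace.

## Preprocessing

Standardization and PCA are fitted on the training split only and applied
to held-out data (`fit_on_all = TRUE` reproduces the pooled alternative;
whether the original study pooled is unstated, and train-only is the
honest default for a generalization estimate). Standardization uses the
population (1/N) convention, matching the standard machine-learning
scaler; constant features get sd 1 with a warning rather than an error so
degenerate synthetic inputs pass through. PCA is an eigendecomposition of
the training covariance — directly tied to the explained-variance
contract, and numerically equivalent to an SVD at these scales — with each
loading column sign-fixed so its largest-magnitude entry is non-negative,
making results independent of the eigensolver's sign choices.

## What the synthetic generator emulates

`generate_two_class_table()` draws two Gaussian classes with a shared
low-rank covariance $W W^\top + \text{noise\_sd}^2 I$ (rank `cov_rank`,
giving PCA genuine structure to find) and mean vectors separated by
`separation` along a random direction. The defaults (285 per class, 30
features, separation 3, rank 5, unit noise) emulate the shape of the
clinical dataset: a few hundred samples, ~30 correlated features, classes
that overlap but are largely separable.

Two named regimes are used by the acceptance checks, with parameters fixed
a priori:

* **Overparameterized** (`n_features = 200`, 40 training samples,
  separation 1): with $2n + 12 = 412$ parameters against 40 samples and a
  mean separation far below the noise scale, training can separate the
  training ensembles almost perfectly while test ensembles stay
  unseparated — the image-data failure mode (train cost near 0, test cost
  near 1).
* **Well-conditioned** (`n_features = 10`, 400 training samples,
  separation 3): 32 parameters against 400 samples; train and test costs
  track each other.

What the generator does *not* emulate: heavy tails, mixed feature scales,
class imbalance, label noise, or the deep-feature covariance structure of
image embeddings. A green synthetic test therefore establishes that the
pipeline reproduces the *bias–variance mechanism* — not that it would
reproduce any particular dataset's numbers.

## Evaluation choices

* **Positive class.** The published tables never state which class was
  scored positive. The printed recall denominators are only consistent
  with the *majority (benign)* class being positive under a proportional
  3:2 split, so the clinical replication scores benign as positive; the
  package default remains the lexicographically second label, and the
  choice is configurable and recorded per run.
* **Tie rule.** $f(x) = 0$ predicts class B (the negative,
  lexicographically first class) deterministically; configurable. Ties are
  measure-zero in practice but constructed fixtures hit them.
* **Split.** A 3:2 split of 569 samples gives 341/342 training rows;
  stratified by default (not stated in the source protocol; both modes
  exist) so small test sets always contain both classes.

## Numerical tolerances

Unit norms hold to $10^{-12}$ through any gate sequence; circuit
amplitudes match dense tensor-product oracles to $10^{-10}$ over thousands
of random instances; the trace and overlap forms of the cost agree to
$10^{-10}$; density-matrix validation (Hermiticity, unit trace) uses
$10^{-8}$. Constant-feature detection uses an sd threshold of $10^{-12}$.

## Known limitations

The circuit is fixed at two qubits; only the depth is configurable.
There is no hardware backend, no shot noise, and no swap-test estimate of
the overlaps — overlaps are exact inner products. The classifier weights
all training points (`k = M`); no true k-nearest-neighbor truncation or
probability calibration is provided. Wall-clock cost of training scales
with the square of the batch size through the pairwise-overlap gradient.
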