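---
title: "Modeling stimulation-evoked iEEG with switched-linear and bilinear dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling stimulation-evoked iEEG with switched-linear and bilinear dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimdyn)
```

## The model

`stimdyn` models the one-step change of each intracranial EEG channel
during and around direct electrical stimulation. For channel $k$ with
signal $y_k(t)$ sampled at 1000 Hz (1 sample = 1 ms), the increment
$\Delta y_k(t) = y_k(t+1) - y_k(t)$ is predicted from

$$
\Delta y_k(t) =
\left(\mathbf{a}_k + \mathcal{U}(t)\,\mathbf{c}_k\right)^{\!\top}
\mathbf{y}_k^L(t)
+ \mathbf{b}_k^{\top} \mathbf{u}^M(t)
+ \sum_{i \neq k} \mathbf{d}_{k,i}^{\top} \mathbf{y}_i^P(t),
$$

where $\mathbf{y}_k^L(t) = [y_k(t-1), \dots, y_k(t-L)]^\top$ is the
channel's own history, $\mathbf{u}^M(t)$ the history of the pulse-encoded
stimulation input $u(\cdot)$ (mA at pulse samples, 0 elsewhere), and
$\mathbf{y}_i^P(t)$ the history of every other channel (the network
blocks). The gating series $\mathcal{U}(t)$ defines the model family:

* **linear** (`AR`/`ARX`/`VAR`/`VARX`): $\mathcal{U} \equiv 0$, no
  interaction block;
* **switched-linear** (`SL_*`, gating `"switched"`): $\mathcal{U}=1$
  inside each 500 ms stimulation span, so the autoregressive law switches
  between an OFF regime $\mathbf{a}_k$ and an ON regime
  $\mathbf{a}_k + \mathbf{c}_k$;
* **amplitude-weighted switched-linear** (gating `"amplitude"`):
  $\mathcal{U}=a$, the delivered amplitude;
* **fully bilinear** (gating `"bilinear"`): $\mathcal{U}=u$, the input
  itself multiplies the output history.

All free parameters $\theta$ are estimated by ridge regression,
minimizing $\tfrac1N\sum_t (\Delta y_k(t) - \theta^\top x_k(t))^2 +
\lambda \lVert\theta\rVert_2^2$, i.e. solving
$(X^\top X + N\lambda I)\,\theta = X^\top \Delta y$. The $N$ factor comes
from the $1/N$ in the MSE term — many library implementations omit it, so
`fit_ridge()` is deliberately explicit, and an oracle test checks the
normal equations directly. No intercept is fitted because signals are
z-scored in preprocessing. The pipeline-wide default is $\lambda = 0.1$.

## Data layout and cross-validation

Recordings are windowed around each stimulation delivery: 1500 ms windows
(500 pre / 500 stim / 500 post for pulse trains; 750 / 750 for single
pulses), each split into five contiguous 300 ms folds, four for training
and a seed-drawn one for testing. Two bookkeeping rules matter:

* lag histories never cross a *window* boundary (windows are
  non-contiguous excerpts), but may cross *fold* boundaries within a
  window — fold membership is decided by the target sample;
* when several lag orders are compared (`grid_search_orders`,
  `select_network_lags`), all candidates are scored on a common row set
  valid at the largest order, otherwise candidates see different samples
  and their errors are not comparable. This is implemented by building one
  feature matrix at the largest orders and sub-setting Gram-matrix blocks.

Model comparison uses the test MSE/NMSE per channel (`NMSE` = MSE divided
by the population variance of the test targets, so 1.0 is the
predict-no-change baseline), the *win rate* (fraction of channels on
which a model is strictly best, ties to the fewest parameters), a
Wilcoxon signed-rank *median criterion* with Bonferroni correction over
model pairs, and the *statistical win rate* (an order suffices when its
mean MSE is within 2 SEM of the channel's best order).

## The synthetic world

The generator is the package's ground truth and the basis of every
acceptance property. Its defaults mirror the experimental design the
package targets: 500 ms biphasic pulse trains at
{single pulse, 10, 25, 50, 100, 200} Hz, three amplitude levels
$\{A_\text{safe}, A_\text{safe}-0.25, A_\text{safe}-0.5\}$ mA, each
combination repeated 20–30 times with at least 1000 ms between
deliveries, encoded by the integer-multiples-of-$1000/f$ pulse rule.
Innovations are i.i.d. Gaussian (default SD 0.1 on the z-scored scale),
the simplest noise model consistent with least-squares fitting.

Stability is enforced constructively: autoregressive blocks are built
from characteristic roots constrained to sum to one (the increment
parameterization pins the coefficient of $y(t)$ at exactly 1), with all
roots inside a companion spectral radius `margin` (default 0.95) for both
the OFF and ON regimes; network couplings are drawn uniform with random
sign and globally rescaled until the full coupled system respects the
margin in both regimes. One documented exception: a system with a
*detectable* coefficient at lag 50 necessarily has spectral radius
$\gtrsim |a_{50}|^{1/51} \approx 0.98$, so the long-memory world used by
the order-selection property passes `margin = 0.985`.

What the generator does **not** emulate: stimulation artifact waveforms,
epileptic discharges, volume conduction, nonstationary drift. A green
test therefore establishes correctness of the estimation and inference
machinery on data that satisfy the model assumptions — not robustness to
the artifact structure of clinical recordings.

## Causal inference

`bootstrap_input_test` asks whether the input lags carry predictive
information: the raw $u$ series is permuted across the in-window time
samples, input features are rebuilt, the model refit and retested, 100
times; $p = (1 + \#\{\text{null MSE} \le \text{observed}\})/(1 + n_\text{boot})$
(add-one rule, so $p \ge 1/101$ and never exactly 0), rejecting at
$\alpha = 0.05$. `bootstrap_network_test` permutes the stacked
network-history feature rows jointly. An identically-zero input is
reported as degenerate with $p = 1$ rather than tested.

The *indirect linearity test* splits the data into STIM OFF (fit
$\mathbf{a}^{(1)}$), one half of the STIM ON windows (fit a full ARX
$\{\mathbf{a}^{(2)}, \mathbf{b}^{(2)}\}$ and a constrained
$\{\mathbf{a}^{(1)}, \mathbf{b}^{(3)}\}$ with the autoregressive block
frozen), and the other ON half for evaluation; a one-sided signed-rank
across windows decides whether freezing cost anything.

## Numerical and design notes

These were genuinely open choices; each is exposed as an argument.

* **Ridge shrinkage interacts with order selection.** With strongly
  autocorrelated features, *deeper* lags of the same signal act as noisy
  copies of the true lags and can share the shrinkage burden: at
  $\lambda = 0.1$ the validation-MSE argmin systematically overshoots the
  true $L$ and $P$ (e.g. a true $L=50$ world selects $L=450$), while
  $\lambda \le 10^{-3}$ recovers the truth. Recovery-style tests
  therefore use a small penalty, as does the parameter-recovery
  criterion; the analysis default stays $\lambda = 0.1$. The same
  mechanism plausibly contributes to large selected orders on real data.
* **The indirect linearity test is tilted when regimes differ in
  variance.** The frozen $\mathbf{a}^{(1)}$ carries estimation error
  calibrated to the OFF-regime feature variance; scoring it under a
  much larger ON-regime variance inflates that error consistently across
  windows, and the signed-rank then declares "nonlinear" even for linear
  truth. The effect decays as $1/N_\text{OFF}$ and vanishes when regime
  variances are comparable; the test fixtures use modest amplitudes for
  that reason.
* **Notch filtering**: 4th-order Butterworth band-stop (±1 Hz) at 60,
  120, 180 Hz, applied forward-backward (zero-phase) with odd edge
  extension, so evoked shapes are not phase-distorted. Design verified
  against the standard scientific-stack implementation during
  development.
* **Onset correction**: threshold = 5 baseline SDs of
  $|\Delta y_\text{anode}|$, search ±50 ms; the detected response time is
  shifted back by the model's structural 2-sample input-to-output latency
  ($u$ enters at lag 1; the increment lands at $t+1$).
* **Single-pulse encoding**: one nonzero sample at the onset (the
  multiples-of-$1000/f$ rule has no $f$); single-pulse gating spans only
  that sample.
* **Delay embedding** (`select_tau`): first local minimum of the lagged
  auto mutual information, 16-bin equal-width histogram estimator, capped
  at 20 samples (a monotone profile returns the cap). This is a surrogate
  for the auto-embedding method cited by the source study, which that
  study does not specify.
* **Sparse models** delay-embed the autoregressive block only; the input
  block stays dense, matching the sparse model as printed (no interaction
  term).
* **Distance analyses**: moving average of the per-channel
  scalar-vs-vector MSE advantage over a 20 mm window on a 1 mm grid
  (windows with fewer than 3 channels masked); backward elimination uses
  20 mm distance bins *to the modeled channel* and the <2% relative NMSE
  increase rule; the elimination trend is summarized by a least-squares
  sigmoid $B + A/(1+\exp(-(x - x_0)/s))$ with an F-test against the
  constant model.
* **Frequency-subset generalization**: the "0 Hz" condition is
  stimulation-free 1500 ms windows drawn from schedule gaps. The
  stimulation-free-*only* training subset cannot identify the gated or
  input blocks at all; the flatness property for switched truth is
  therefore assessed over identifying subsets (every subset containing at
  least one true stimulation frequency).
* **Session generalization** fits STIM-OFF-only models, since
  stimulation sites differ across sessions.

## Limitations

Ridge with a fixed global $\lambda$ is a deliberate simplification (as in
the source methodology); no per-channel penalty tuning is attempted. The
bootstrap refits are exchangeable permutations, not block bootstraps, so
strong within-window dependence of $u$ is broken by design — that is the
null being simulated. The CLI covers the synthetic pipeline; readers of
external clinical formats are out of scope.
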