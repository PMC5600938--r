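---
title: "Recurrent convolutional networks and occluded digit recognition: models, stimuli, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent convolutional networks and occluded digit recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bltnet)
```

## The scientific question

Feedforward convolutional networks are the dominant model of rapid visual
object recognition, but the primate ventral stream is densely recurrent:
lateral connections within an area and feedback connections from higher to
lower areas are as numerous as the feedforward ones. A long-standing
hypothesis holds that this recurrence matters most when the feedforward sweep
is insufficient — notably when objects are partially occluded. `bltnet`
implements a family of small recurrent convolutional networks, a generative
model of occluded digit scenes on which to train and test them, and the
statistical machinery for deciding whether one architecture reliably
outperforms another.

## The model family

Every network has two hidden convolutional layers and a readout. Within a
hidden layer, the pre-activation of feature map $k$ at position $(i,j)$ and
time step $\tau$ sums up to three terms plus a single bias per feature map:

$$
z_{\tau,m,i,j,k} =
  (w^b_{m,k})^\top h_{\tau,\,m-1,i,j}
+ (w^l_{m,k})^\top h_{\tau-1,\,m,i,j}
+ (w^t_{m,k})^\top h_{\tau-1,\,m+1,i,j}
+ b_{m,k},
$$

where the *bottom-up* term convolves the layer below at the current step, the
*lateral* term convolves the same layer's previous-step output, and the
*top-down* term (layer 1 only) carries layer 2's previous-step output back
down. Turning the lateral and top-down sets on or off yields the four
architectures **B**, **BT**, **BL**, **BLT**; the feedforward controls
**B-F** (64 instead of 32 feature maps) and **B-K** (5×5 instead of 3×3
kernels) approximately match the recurrent models' parameter counts without
recurrence. `arch_spec()` constructs all six presets, and
`count_parameters()` / `count_units()` perform exact accounting (e.g. B has
9,898 parameters and 40,970 units; BLT has 37,546 parameters).

Between the layers sits a 2×2/stride-2 max pool, so layer 1 is 32×32×k and
layer 2 is 16×16×k. Because of the pooling, top-down input must be upsampled:
it is a transposed convolution with output stride 2×2 — implemented here as
the exact adjoint of the corresponding stride-2 convolution, which is what a
transposed convolution is. Every pre-activation passes through a ReLU and
local response normalization over the $n = 5$ nearest feature maps
($\omega(x) = x\,(1 + 10^{-4}\sum x^2)^{-1/2}$, feature order fixed); the
readout takes the spatial maximum of each layer-2 feature map, applies a
dense map to 10 units and a sigmoid, and the 10 outputs are read as
independent per-class presence probabilities. Feedforward networks run for
one time step; recurrent networks are unrolled for four with weights shared
across time, the input replicated at every step, and recurrent terms zero at
$\tau = 0$.

One formulation detail: as printed in the source material the normalization
window's upper limit would be `min(n-1, k+n/2)`, which for $n=5$ makes the
window empty for high feature indices; we use the standard
`min(K-1, k+n/2)` with $K$ the number of feature maps, which matches the
stated "n closest features" semantics.

## The stimuli

Scenes are composed at 512×512 and area-averaged down to 32×32 (`downsample()`
is an exact block mean, the correct antialiasing for an integer factor). All
digits use one built-in fixed-width typeface at one size, white on black, so
the only within-condition variation is digit identity and position (uniform
jitter in a central region chosen so glyphs always fit and multi-digit scenes
overlap with high probability).

* **Digit debris** (`compose_debris()`): one target digit, occluded by
  `n_fragments` square crops taken from renders of uniformly chosen digit
  classes at uniform offsets inside the glyph's bounding box, pasted at
  uniform positions. Fragments *add* ink — the occluders carry digit features
  that must be ignored — in contrast to deletion-style occlusion, which only
  removes target features. Difficulty levels are 10 / 30 / 50 fragments.
* **Digit clutter** (`compose_clutter()`): 3–5 overlapping target digits with
  pairwise-distinct classes placed sequentially (later = nearer); all must be
  reported. Classes are sampled without replacement because the multi-hot
  label encoding cannot represent duplicates.

Fragment size is the one generator parameter the source leaves fully open,
and it controls task difficulty directly. The package defaults to fragment
sides of 0.2–0.4 of the glyph height, which yields a mean occlusion of the
target's ink of roughly 18%, 44% and 62% at 10, 30 and 50 fragments. We
calibrated this by solvability: at the first size we tried (1/3–2/3 of the
glyph), 50 fragments buried ~95% of the target's ink and turned the frame
into a near-solid mass that no observer could classify, contradicting the
reported learnability of the heavy condition at full scale. The default keeps
heavy debris hard but recoverable.

Pixel-wise normalization (`fit_normalization()` / `normalize()`) maps each
pixel through $(x - \bar{x}_{ij}) / s_{ij}$ with moments estimated per
position on the training split only; zero-variance positions map to 0.
Additive Gaussian noise (`add_gaussian_noise()`) is applied after
normalization, so on the unit-variance signal $\sigma = 1$ and $\sigma = 2$
give signal-to-noise ratios 1 and 0.5; noise is drawn once per image and the
static noisy image is replicated across time steps.

`generate_dataset()` assembles labelled splits. Generation is a pure function
of `(config, seed, role)` — the train/validation/test streams are derived
independently, manifests are byte-identical across reruns, and datasets can
be archived as 8-bit PNGs plus a CSV manifest.

## Training and evaluation

The loss is cross-entropy between the sigmoid outputs and the multi-hot
ground truth, summed over **all** time steps and classes (so a recurrent
network is pushed to be right as early as possible), plus an L2 penalty
$\lambda\lVert w\rVert^2$ with $\lambda = 5\times10^{-4}$ over all trainable
parameters. Optimization is mini-batch momentum SGD (batch 100,
$\mu = 0.9$), with the learning rate decayed continuously as
$\varepsilon = \eta\,\delta^{e/d}$ ($\eta = 0.1$, $\delta = 0.1$, $d = 40$;
we read the exponent literally as continuous — at epochs 0/40/80 both
readings give 0.1/0.01/0.001). The reference regime trains 100 epochs on
100,000 images per condition. Gradients come from backpropagation through
the unrolled graph with shared weights; the analytic gradients are verified
against central finite differences at relative tolerance $10^{-4}$ in the
test suite. The per-image loss is averaged within a mini-batch (the source
does not state the batch reduction; the mean is its frameworks' convention
and the only reading under which $\eta = 0.1$ is a sane scale).

Two numerical choices worth knowing about. Outputs are clamped to
$[10^{-7}, 1-10^{-7}]$ inside the logarithms. Initialization, which the
source leaves unspecified, defaults to Glorot-style uniform
$U(\pm\sqrt{6/(f_{in}+f_{out})})$ for kernels with readout biases at the
logit of the class base rate ($\mathrm{qlogis}(n/10)$ for an $n$-digit
task). This matters: with a fan-in-only uniform init we found momentum SGD
at $\eta = 0.1$ oscillates and cannot even overfit 100 images, whereas with
the default init the unoccluded task trains to 0% error within 10 epochs.
Training is fully deterministic given `(spec, data seed, config seed)`;
the epoch shuffle and init draw from derived streams. The validation split
is used for monitoring only — the regime's hyperparameters are fixed, and
there is no early stopping.

One training-dynamics finding shaped the desk-scale design. Because the
cross-entropy is summed over time steps, a four-step recurrent network
receives gradients four times larger than its feedforward skeleton — with
shared weights and zero recurrent input at $\tau=0$, a recurrent network
whose recurrent kernels are zero follows *exactly* the trajectory of the
feedforward model at four times the learning rate. At the reference scale
that is evidently tolerable; at a few percent of it, we find momentum SGD at
$4\times0.1$ drives every recurrent architecture into a degenerate attractor
(constant base-rate outputs, loss pinned at $4 \times 10\,\bar{H}$) that it
never leaves, while the feedforward models train normally. No admissible
re-initialization can fix this — a learning-rate ratio survives any uniform
rescaling of the weights. `training_config(time_average_loss = TRUE)`
therefore averages the cross-entropy over time steps in the training
objective (identically, trains a T-step network at $\eta/T$), making the
per-update step size architecture-independent. Reduced-scale experiment
plans enable it by default; the default trainer configuration and the
exported loss function keep the literal time-summed objective.

Accuracy uses only the **final** time step: the `n` largest sigmoid outputs
(`predict_topn()`, ties broken by ascending class index) form the predicted
set, and an image counts as correct only when that set equals the label set.
`evaluate()` also records per-digit correctness for the clustered statistics
below. Note the asymmetry, tested explicitly: the loss sees every time step,
the reported accuracy only the last.

## Statistical comparison of trained models

Two trained networks are compared on the same test images, so the right unit
of inference is the image, not a retraining run. `mcnemar()` implements the
continuity-corrected $\chi^2 = (|b-c|-1)^2/(b+c)$ on the discordant counts
(exact binomial as an option). For multi-digit tasks, the per-digit records
within one image are correlated; `clustered_mcnemar()` uses the
cluster-adjusted statistic $T = (\sum_k d_k)^2 / \sum_k d_k^2$ with
$d_k = b_k - c_k$ per image, which reduces exactly to the uncorrected
McNemar statistic when every cluster has one record. Families of pairwise
tests (one image set = one family) are corrected with the Benjamini-Hochberg
step-up rule at FDR 0.05 (`bh_fdr()`, `pairwise_model_tests()`).

Robustness to increasing difficulty is compared through OLS slopes of error
rate on ordinal difficulty (light = 1, moderate = 2, heavy = 3;
`fit_error_slope()`). The difference between two models' slopes is tested by
a permutation test (`slope_permutation_test()`): under exchangeability each
image's pair of predictions may be swapped, so each permutation flips an
independent fair coin per image (all records of an image swap together),
recomputes both slopes and their difference, and the two-tailed p-value is
$(1 + \#\{|\Delta_{null}| \ge |\Delta_{obs}|\})/(1 + n_{perm})$ — the add-one
form avoids zero p-values. The implementation is vectorized over
permutations but is verified in the tests against an exhaustive enumeration
of all $2^8$ swap patterns on a tiny table, and its type-I error is checked
to sit at the nominal 5% over 1,000 simulated exchangeable model pairs.

## Desk-scale experiments

`experiment_plan()` / `run_experiment()` orchestrate the full grid
(conditions × architectures): data generation, training, evaluation, pairwise
tests with FDR control, and error-rate tables (`results_table()`,
`significance_matrix()`). A `scale` knob multiplies dataset sizes and epochs
jointly; `scale = 1` reproduces the reference regime (100,000/10,000/10,000
images, 100 epochs), which is supported but takes days of CPU time.

The test suite and the acceptance script run a deliberately small replication
chosen to fit interactive budgets: heavy debris, 3,000 training / 300
validation / 600 test images, 6 epochs, all six architectures — roughly 3% of
reference scale. At this scale the full-scale error *magnitudes* are not
reproducible (everything is far less trained and all models sit within a few
points of chance on heavy debris); the suite checks the qualitative
structure: the error *ordering* BLT < BL/BT < B-K < B-F < B up to adjacent
swaps, and the monotone growth of error with debris level. Monotonicity is
assessed by evaluating each heavy-trained model on light/moderate/heavy test
sets (`cross_condition_eval()` — the transfer design, which also supports
the train-on-debris/test-clean analysis) rather than training three models
per architecture, which would triple the compute for the same qualitative
signal. Be aware that these are strict checks of an asymptotic phenomenon
run in the early-training regime: in our desk-scale runs the ordering is
still dominated by learning *speed* — the feature-rich B-F control, for
instance, improves fastest at first, the opposite of its converged rank —
so the ordering check can fail at this scale even though every individual
component it exercises behaves correctly. Resolving the published ordering
requires training closer to the reference regime than an interactive session
allows.

What the synthetic stimuli do *not* emulate: natural image statistics,
occluders with different colour or depth cues from the targets, size or
orientation variation, and deletion-style occlusion. Passing tests therefore
speak to the models' behaviour on this controlled translation-invariant
recognition problem, not to natural-scene performance.

## Known limitations

* Single-threaded CPU implementation; full-scale training is supported but
  slow (the unrolled BLT costs ~1.8 s per 100-image batch here).
* The clustered McNemar variant assumes clusters are independent and
  identically structured; heavily unbalanced cluster sizes are handled but
  untested against external references.
* The permutation test's coin-flip swap reads "randomly shuffle predictions
  for a single image between a pair of networks" as an independent fair coin
  per image; within-matched-set permutation schemes are not implemented.
* Repeated digit classes within one clutter scene are excluded by design
  (the multi-hot encoding cannot express them).
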