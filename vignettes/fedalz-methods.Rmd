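---
title: "Federated learning with secure aggregation for AD detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated learning with secure aggregation for AD detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fedalz` simulates, end to end, a privacy-preserving federated learning (FL)
study for Alzheimer's disease (AD) versus cognitively normal (CN)
classification from structural-MRI-like volumes: synthetic cohorts, a 3D
convolutional network, federated averaging (FedAvg) with and without secure
aggregation (SecAgg), ten heterogeneous client-data scenarios, and a
shadow-model membership-inference evaluation. This vignette describes the
models, the tunable parameters, the numerical choices, and what the synthetic
experiments can and cannot show.

## The synthetic cohort generator

Real case/control neuroimaging studies of this kind pool preprocessed
(template-registered, skull-stripped) T1-weighted scans from a few hundred
subjects — the composition emulated by the defaults of `generate_cohort()`:
618 subjects, 166 AD / 452 CN, 345 women / 273 men. Subject counts are
allocated to the four (diagnosis, sex) cells deterministically (the AD/female
cell gets `round(n_ad * n_female / n_total)`, clipped to feasibility; the
margins fix the rest), so the composition is exact for every seed and exactly
testable, rather than a Bernoulli approximation.

Ages follow a truncated normal per diagnosis group (`age_model()`, defaults
AD 76 ± 8, CN 72 ± 8 years on [55, 95]). The AD–CN offset and the spread are
assumptions — the emulated study reports no age distributions — chosen so
that (a) AD cases run a few years older, as in typical cohorts of this kind,
and (b) a median split of the pooled ages produces two groups roughly a
decade apart in mean age, which is the condition the age-heterogeneous
scenarios need.

Each scan (`generate_volume()`) is a fixed smooth "brain-like" template
(Gaussian envelope with a low-frequency internal modulation, intensities in
[0, 1]) plus three signal components inside a designated ellipsoidal
"atrophy" region:

* a deterministic attenuation of strength `effect` for AD subjects,
  optionally modulated linearly by age (`age_slope`, off by default so that
  the AD–CN contrast equals `effect` exactly);
* a zero-mean Gaussian per-subject regional shift with standard deviation
  `subject_sd`, for *all* subjects — the biological between-subject
  variability that creates class overlap;
* i.i.d. Gaussian voxel noise (`noise_sd`) over the whole grid.

AD and CN volumes therefore differ in expectation only inside the region.
The defaults `effect = 0.10`, `subject_sd = 0.05`, `noise_sd = 0.1` put the
Bayes-optimal balanced accuracy of the region-mean statistic near
`pnorm(effect / (2 * subject_sd)) = pnorm(1) ≈ 0.84` — the mid-80s-percent
regime in which the emulated study's classifiers operate. These were fixed
once, from this calculation, as the package's study conditions.

What the generator does *not* emulate: anatomical variability and
registration error, scanner/site effects, spatially correlated noise,
longitudinal structure, and any preprocessing artifacts. Passing tests on
synthetic cohorts show that the *pipeline* (partitioning, federation, secure
aggregation, evaluation, attack) behaves correctly and reproduces the
study's qualitative orderings; they do not certify accuracy levels on real
MRI.

The default grid is 32×32×32 voxels at 1 mm spacing — a desk-scale stand-in
for a full ICBM-like grid (supported, but training at full resolution is not
a goal of this package).

## The 3D CNN

`cnn_spec()` follows the four-block volumetric architecture: each block is
convolution (kernel 3×3×3, padding 1, stride 1 — standard choices; the
source architecture diagram does not pin them down) → batch normalization →
ReLU → max-pooling, with 8, 16, 32, 64 feature maps and pooling windows
2, 3, 2, 3; then two fully connected layers of 128 and 2 units with dropout
0.4 before each. Training uses Adam with learning rate 1e-4 and (coupled L2)
weight decay 1e-4 and a class-weighted cross-entropy (inverse class
frequencies by default, switchable off; the emulated cohort is 2.7:1
CN-heavy and the rebalancing method used originally is unstated).

Numerical choices worth knowing:

* **Ceil-mode pooling.** Pooling keeps partial trailing windows, so an axis
  of 32 voxels survives the (2, 3, 2, 3) schedule as 16 → 6 → 3 → 1.
  Floor-mode pooling would require ≥ 36 voxels per axis and could not run on
  the package's default grid.
* **Batch-norm statistics are model state.** Running means/variances travel
  with `ModelParameters` and are averaged like weights during federated
  aggregation (the protocol exchanges the model state wholesale); they are
  excluded from the optimizer and from weight decay.
* **Optimizer state is local to a training call.** Adam moments are
  re-initialized per call — client optimizer state is not part of the
  exchanged model — and the centralized baseline follows the same
  round-blocked schedule, which is what makes a one-client federation
  bitwise identical to centralized training (a tested identity).
* **Seeding.** All randomness derives from one master seed via
  `derive_seed(seed, tokens...)` (multiply-add mixing modulo 2^31 − 1, exact
  in doubles); epoch shuffles are seeded by epoch index so that a run of
  `n` epochs equals `n` chained one-epoch runs.
* **Batch size 4.** Unstated in the emulated study; at the fixed learning
  rate, smaller batches give more optimizer steps per data pass, which is
  what desk-scale runs on one CPU need (batch 8 converges visibly slower per
  epoch in pilots at identical cost). Configurable.
* The convolution, pooling and batch-norm kernels are compiled
  (Rcpp/RcppArmadillo, im2col + BLAS GEMM). Convolution arithmetic runs in
  single precision — the customary precision for neural-network training —
  which halves memory traffic and roughly doubles throughput; all other
  arithmetic, including the optimizer and secure aggregation, is double
  precision. The kernels are verified in the test suite against a direct
  convolution oracle at single-precision tolerance.

## Federation

`run_session()` implements the five-phase round: broadcast the global model,
train each client `local_epochs` epochs locally, report, aggregate, iterate;
after every round the global model is scored on a server-held validation set
and the best round's model (highest validation balanced accuracy, earliest
on ties) is returned. Aggregation is the sample-size-weighted coordinate
mean (classic FedAvg; `uniform` available). All clients participate every
round — the study's settings have 2–4 clients. Defaults `rounds = 30`,
`local_epochs = 1`. The validation set is carved from the development set
(default 15–16%, diagnosis-stratified); its construction is unstated in the
emulated study.

## Secure aggregation

`secagg_config()` implements SPDZ-style additive secret sharing over the
integers modulo a prime `Q`. A client fixed-point encodes its weighted,
flattened model (`round(x * 2^f) mod Q`, negatives as `Q − |v|`), splits it
into `N` shares (the first `N − 1` i.i.d. uniform on `[0, Q)`, the last the
modular complement), and sends share `j` to client `j`; each client reports
only the sum of the shares it received; the server adds the `N` partial sums.
The sum is *exact* in the field; the only error relative to plaintext FedAvg
is one fixed-point rounding per client, bounded by `N * 2^-(f+1)` per
coordinate — a tested contract.

The default modulus is `Q = 2^31 − 1` with `f = 20` fractional bits and
magnitude bound `B = 64`. The choice is dictated by R's numeric type: all
field elements and sums of up to `N` of them must stay below 2^53 to be
exact in doubles; `2^31 − 1` leaves headroom for `N ≤ 15` clients under the
no-wrap-around condition `N·B·2^f < Q/2`, which is checked at configuration
time and never silently wrapped. Share randomness comes from a dedicated
seedable stream (`sample.int` rejection sampling, exactly uniform on the
field), separate from training randomness; production use can leave the seed
`NULL` to draw from the session RNG state.

The protocol refuses fewer than three clients: with two, one
honest-but-curious party can recover the other's update by subtraction.
SPDZ's MAC/authentication layers are omitted — the threat model is
honest-but-curious only, and the scheme is used purely as an additive-sharing
sum. Communication is simulated in-process; the transcript object records
exactly what each party observes, and `adversary_view()` exposes the
server's per-client view (the masked partial sum) for the privacy analysis.

## Client heterogeneity scenarios

`scenario_spec()` encodes ten scenarios in five environments: uniform
balanced over 3 or 4 clients (1.1, 1.2); size-skewed 60/20/20 (2);
sex-imbalanced — two all-female + one all-male (3.1), mirrored (3.2), one
all-female vs one all-male (3.3); age-imbalanced with groups split at the
development-cohort median age (4.1, 4.2); and diagnosis non-IID — two
all-CN clients + one all-AD (5.1), and two clients with a 25% admixture of
the opposite label (5.2). The published partition figures are not
machine-readable, so per-client proportions are configuration defaults that
realize each scenario's verbal description; within strata, assignment is
uniform-random under the seed, counts are deterministic (largest-remainder
rounding), and subjects unusable without violating a stratum target are
dropped and counted.

## Study protocol and the RPD statistic

`run_study()` repeats the whole pipeline over independent development/test
splits: the test set (default 50 AD + 50 CN; sex-balanced within diagnosis;
AD/CN mean ages greedily matched within 1 year) is created once per split
and frozen; each (scenario, approach) cell is trained with fresh seeds,
selected by validation, and scored on the frozen test set; cells aggregate
as mean ± sample (n−1) SD over splits × repetitions. The full design is
10 splits × 5 repetitions; the package's defaults are 3 × 2 with the full
design available — the scaled sizes are recorded in the output.

The comparison statistic is the relative performance decrease
`RPD = (acc_CL − acc_FL) / acc_CL × 100`, reported to two decimals with the
unrounded value kept. Secure aggregation cells for two-client scenarios are
reported `N/A`, since the protocol's privacy floor is three clients.

## Membership inference

The privacy evaluation follows the shadow-model construction: a shadow
replica of the target architecture is trained on data disjoint (by subject
id, enforced structurally) from the target's training set; its posteriors on
its own members versus held-out non-members train a binary attack classifier
(ridge-penalized logistic regression on sorted posteriors, true-class
indicator and per-sample loss — with two diagnosis classes, per-class attack
models collapse into one model with the class as a feature). The attack is
then scored against the real target: member recall (sensitivity), non-member
recall (specificity), and their mean (balanced accuracy).

Desk-scale targets generalize too well to leak by default, so the package
provides an "overfit mode" (small training set, many epochs, no weight
decay, no dropout) to make membership measurable — a deliberate surrogate
for the large, genuinely overfit models attacked in practice. Attacked
checkpoints default to the selected model for centralized training and to a
targeted client's last local update for FL. Against secure aggregation, the
honest-but-curious server sees only the targeted client's masked partial
sum; `attack_secagg_view()` decodes that uniform field vector into
pseudo-parameters and runs the same attack, whose decisions are then
independent of the client's data — balanced accuracy statistically
indistinguishable from 0.5. (Degenerate forward passes through such random
"parameters" are mapped to the uninformative posterior (0.5, 0.5).) Attacks
on the global aggregate model are out of scope.

## Problem sizes used in the shipped tests

The test suite exercises full 32³ study conditions where the claims require
them — the scenario 1.1 federated-vs-centralized comparison and the 5.1
non-IID degradation run on a 260-subject cohort (200 development subjects:
168 training + 32 validation; 30 + 30 frozen test), the centralized baseline
for 26 epochs and the federated sessions for 24 rounds of three local
epochs, so that a federated round's serial optimizer steps match a
centralized epoch — and 12³ grids with small cohorts for unit-level
properties, where the contracts are size-independent. These sizes are the
package's desk-scale protocol; the full design (10 × 5 splits ×
repetitions, more rounds, larger cohorts) is a configuration change, not a
code change.

A caveat this protocol makes visible: federated averaging needs
substantially more serial optimization than centralized training to reach
the same state — three clients training in parallel contribute a third of
the serial steps per unit of data seen, and model averaging adds its own
inefficiency early in training, before the diagnostic features have formed.
Within the desk-scale round budget the centralized model reaches its
validation plateau while the federated models can remain under-converged,
which overstates the federated accuracy deficit relative to what a
converged, large-scale comparison shows. The non-IID degradation ordering
(scenario 5.1 versus 1.1) is insensitive to this and reproduces robustly.

## Known limitations

* The synthetic signal is a single homogeneous regional attenuation; real
  atrophy patterns are spatially heterogeneous and correlated with age and
  disease stage.
* Balanced accuracy is the only performance metric, as in the emulated
  study; no significance testing across approaches is performed.
* FedAvg here is synchronous with full participation; stragglers, client
  sampling and dropout-tolerant masking are out of scope.
* The attack model family is fixed (logistic regression); stronger attacks
  would only widen the demonstrated plaintext-vs-SecAgg gap, but this is not
  verified here.
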