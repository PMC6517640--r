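---
title: "Decoding clinical scores from brain maps: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding clinical scores from brain maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpdecode)
```

## What the pipeline does

`gpdecode` predicts continuous anxiety/depression scores from per-subject
fMRI contrast volumes. One volume per subject enters; subjects with more
than 15% missing voxels are excluded (strictly greater — a subject at
exactly 15% is kept); the analysis mask keeps only voxels finite in every
remaining subject; the masked voxels become a subjects-by-voxels matrix;
Gaussian-process regression with a linear kernel is trained and tested
under scanner-balanced k-fold cross-validation; performance is Pearson's r
and the normalized MSE on the concatenated out-of-fold predictions;
significance comes from permutation tests that rerun the whole
cross-validated procedure on shuffled targets; and the fitted linear rule
is mapped back to voxel space and summarized over atlas regions.

## The regression model

For training features $X \in \mathbb{R}^{n \times V}$ and targets $y$, the
linear-kernel GP is $y \sim \mathcal{N}(\mu 1,\; \theta K + \sigma^2 I)$
with $K = X X^\top$. Its predictive mean is dual
($f(x_*) = \mu + \theta\, k(x_*, X)\,\alpha$ with
$\alpha = (\theta K + \sigma^2 I)^{-1}(y - \mu 1)$) and primal
($f(x_*) = \mu + x_*^\top w$, $w = \theta X^\top \alpha$) — the package
asserts both agree to $10^{-10}$, which is also the correctness oracle for
the weight maps. For fixed hyperparameters the predictor coincides with
ridge regression with penalty $\sigma^2/\theta$.

**Hyperparameters.** $\mu$ is fixed at the training-target mean and not
co-optimized (one fewer optimizer axis; matching common neuroimaging GP
toolboxes). $(\theta, \sigma^2)$ maximize the log marginal likelihood over
a deterministic $20 \times 20$ log-spaced grid spanning
$[10^{-4}, 10^{4}]$ — scaled by $\mathrm{var}(y)/\overline{\mathrm{diag}(K)}$
for $\theta$ and by $\mathrm{var}(y)$ for $\sigma^2$ so the grid is
invariant to the units of the features and the scale of the score — then
Nelder–Mead refinement in log space. No random restarts: the fit is a
deterministic function of $(K, y)$.

**Numerics.** A jitter of $10^{-8}\,\mathrm{tr}(K)/n$ is added before
factorization. Because the kernel does not depend on $(\theta, \sigma^2)$,
a single symmetric eigendecomposition $K = U \Lambda U^\top$ makes each
evidence evaluation $O(n)$; permutation tests reuse the eigenbasis across
thousands of refits, which keeps a 100-permutation run on $n = 154$,
$V \approx 2000$ around a second. Features enter the kernel raw — no
centring or scaling beyond confound residualization (the emulated analysis
does not mention kernel normalization); this is deliberate and documented
rather than switchable, and the classification results below show where it
matters.

## Cross-validation and confounds

Folds (k = 2 and 5) are built by seeded rejection sampling: each stratum of
the balance keys (scanner by default) is dealt round-robin across folds,
and an assignment is accepted only if fold sizes differ by at most one and
every pairwise Welch t-test on the target scale across folds has p > 0.05
(the conventional reading of "did not differ significantly"; `max_tries`
10000). This mechanizes what the emulated study did manually. A balance-key
level with fewer members than k is an error; joint strata smaller than k
are allowed and spread as evenly as divisibility permits. When n is not
divisible by k, earlier folds take the extra subjects after the seeded
shuffle. Only the scanner is a default balance key — gender balancing is
not named in the emulated procedure, so it is available but off.

Confounds are removed from the **features, never the targets**:
residualizing targets on confounds associated with the predicted variable
would delete label variance along with nuisance. The removal model —
least squares of every voxel on `[intercept, confounds]`, age z-scored,
binary confounds as 0/1 dummies — is estimated on training rows only and
applied unchanged to test rows. Whole-sample runs remove age only;
distressed-only runs remove age and scanner, mirroring the screening
outcome of the emulated study (scanner and gender associate with the
scores in the whole sample, so removing them there would delete signal).

Two properties of this design are worth stating plainly:

- **Concatenated CV r has a small negative finite-sample offset** (about
  −0.06 at n = 154 with 2-fold CV on null data): each fold's predictions
  carry that fold's training mean, which anticorrelates with the test
  fold's mean. The offset is identical with and without confound removal —
  it is not leakage — and the permutation null shares it, so inference is
  calibrated (the acceptance suite verifies the rejection rate under the
  null sits in the 95% band around 0.05).
- **The scanner offset is a real confound path.** With the generator's
  default scanner-B offset map, maps predict STAI-T through the
  group/scanner composition even with zero planted signal, and the
  permutation test correctly flags it — removing age alone does not remove
  it. The calibration tests therefore construct their null with the
  scanner offset disabled; the default world intentionally keeps this
  limitation of the emulated design visible.

## Inference

Pearson r needs at least 3 non-constant pairs; the normalized MSE is the
mean squared error divided by the range of the *predictions* (an
asymmetric definition, preserved as specified; constant predictions are an
error, never an infinity). Permutation p-values use the literal count/n
rule (`p_r` counts permutations with $|r_{perm}| \ge |r_{obs}|$; `p_mse`
counts signed $mse_{perm} \le mse_{obs}$), which can reach exactly 0; the
conservative $(count+1)/(n+1)$ variants are always reported alongside,
since a printed p = 0.001 at 1000 permutations cannot be told apart from a
floor. Folds are held fixed across permutations and only targets are
shuffled; re-balancing folds per permutation would change the null's
conditioning and is not part of the emulated procedure. The Bonferroni
threshold is $0.05/(5 \times 2) = 0.005$.

## Weight maps and localization

Per-fold weight vectors are averaged **un-normalized** and only the mean is
divided by its Euclidean norm (the stated order of operations). Weight
maps are not statistical maps and must not be thresholded; the package
only summarizes them. Two normalized-weight conventions are implemented
because the literal formula in the emulated description — regional
mean of $|w|$ divided *again* by the region size — double-normalizes
relative to the method it cites (a plain size-normalized mean):

- `literal` (default): $NW_R = \mathrm{mean}(|w_v|: v \in R)/|R|$,
- `mean`: $NW_R = \mathrm{mean}(|w_v|: v \in R)$.

They coincide only for equal-size regions; every output names its mode.
Unlabelled (label-0) voxels are excluded from the total, with their
absolute weight reported separately.

## The synthetic cohort: what it emulates, what it does not

Defaults are the stated world of the emulated study: 82 distressed + 72
healthy subjects; scanner split A/B = 119/35 arising from per-group splits
50/32 and 69/3 (which by itself induces the whole-sample scanner–score
association without any extra mechanism — within groups there is none,
matching the reported screening); per-group score means/SDs/ranges from
the published table, sampled from truncated normals whose parent
parameters are moment-matched so the *observed* distribution hits the
targets; clinician scales zero-inflated in healthy subjects at the
published 47/72 and 45/72 rates, with the continuous component calibrated
to the conditional nonzero moments so overall moments still match; scales
coupled through a Gaussian copula (latent correlation 0.7 — a stand-in,
as no inter-scale correlations are published); female score means shifted
up 0.25 SD on STAI-T, MASQ-D and HAM-A (the scales reported
gender-associated); age truncated-normal 21.6 ± 2.0 on 18–25.

Two specs sit outside the truncated-normal family: a truncated normal on
$[a,b]$ cannot exceed the uniform SD $(b-a)/\sqrt{12}$, and the healthy
MASQ-D target (sd 3.5 on [12, 24]) is above that bound (attainable ≈ 2.8;
distressed MASQ-D misses by 0.1). Calibration weights the mean so it stays
on target and takes the shortfall in the SD; `scale_calibration()` prints
target vs achieved for all ten specs, and the tests assert against the
achieved moments for these two cases.

Volumes are `z · a · W + scanner_offset[B] + noise`: `z` the
cohort-standardized STAI-T, `W` ±1 at `n_signal_voxels = 100` random
voxels outside the dropout octant (so the signal survives common-voxel
masking), amplitude `a = signal_snr × noise_sd` giving an exact per-voxel
SNR, an additive per-voxel scanner-B offset (SD 0.5 — strong enough to be
decodable, per the multi-scanner literature the emulated study cites, but
not signal-swamping), and unit Gaussian noise. The default
`signal_snr = 0.1` is the stated low-SNR, spatially distributed regime —
individually undetectable voxels, multivariately detectable pattern.
Recovery tests that need a voxel-level-detectable signal use
`signal_snr = 0.4`, the smallest value whose per-voxel correlation clears
the Bonferroni critical |r| over 2028 voxels at n = 154 — a rule fixed a
priori by detectability, not by the pipeline's output. Dropout: 20% of
subjects get a contiguous patch covering 5% of voxels, placed as the
raster prefix of a fixed "frontal" (low-index) octant box — the prefix
rather than a strict box so the NaN count equals
`round(dropout_extent × V)` exactly; identical across affected subjects,
standing in for consistent frontal susceptibility dropout.

Not emulated: hemodynamics, task structure, spatial autocorrelation of
noise, motion, multi-emotion conditions, registration error. A green test
therefore establishes the *statistical machinery* (no leakage, calibrated
inference, correct formulas, recoverable planted signal) — not that the
pipeline would reach any particular performance on real data.

## Classification

GPC uses a probit likelihood with the Laplace approximation (the toolbox
the emulated study used defaults to EP; Laplace is a deliberate,
documented deviation chosen for implementability — class probabilities and
balanced accuracies agree with chance/separability expectations in the
suite). The kernel scale is selected on a deterministic evidence grid.
Folds for classification are additionally stratified by group so both
classes appear in every training fold. Note that with a raw
(uncentred) linear kernel, a class sitting at the feature-space origin is
weakly identified; in the pipeline the confound-removal intercept centres
the training features, which is sufficient.

## Known limitations

- Exact numerical parity with GP neuroimaging toolboxes such as PRoNTo is
  not claimable: their kernel preprocessing conventions vary, and their GPC
  typically uses EP rather than Laplace.
- The 15% exclusion rule's denominator is a design decision (voxels inside
  a caller-supplied scope mask, defaulting to voxels usable in at least
  half the subjects); the emulated text does not state its denominator.
- Which NW convention produced the published region ranking cannot be
  determined from the text — hence the dual mode.
- The permutation p can be exactly 0 under the literal rule; both
  conventions are emitted so readers can choose.
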