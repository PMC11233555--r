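---
title: "Encoding models, coupling filters, and context-stable population codes: methods"
author: "spikecoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding models, coupling filters, and context-stable population codes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

When an animal navigates to a remembered target under different sensory
contexts — here, dense versus sparse optic flow — the population code for the
key latent variable (the evolving distance to the invisible target) can stay
stable even while the fine-grained statistical dependencies between neurons
reconfigure. Probing that dissociation requires three linked analyses:

1. a single-unit **encoding model** that separates stimulus-driven responses
   (tuning functions, the "signal correlations") from signal-independent
   unit-to-unit **coupling filters** (the time-resolved analogue of noise
   correlations);
2. **population-geometry** tools (condition-averaged PCA of time-warped
   trajectories, a d-prime permutation test) that ask whether latent dynamics
   are interchangeable across contexts; and
3. **decoders** (cross-validated lasso, a small feed-forward network) trained
   in one context and tested in the other, with a tuning-preserving shuffle
   that destroys noise correlations to test what the read-out relies on.

In natural closed-loop behavior no two trials are alike, so classical
trial-averaged noise correlations are unavailable; the coupling filters of the
encoding model take their place. This package implements the full pipeline
and, because deposited recordings are not required, pairs it with a synthetic
closed-loop session generator with known ground truth so that every stage is
testable by parameter recovery.

# The encoding model

For one unit with spike counts $y_t$ in 6 ms bins, the log rate is a sum of
smooth functions of continuous covariates $x_j$ and causal temporal filters
convolved with event trains $z_k$ (task events, the unit's own spike history,
and other units' spike counts — the coupling filters):

$$\log \mu_t = \sum_j f_j(x_{j,t}) + \sum_k (f_k * z_k)_t , \qquad
y_t \sim \mathrm{Poisson}(\mu_t).$$

Each $f$ is a B-spline expansion $f(\cdot) = \beta^\top b(\cdot)$ with an
integrated-squared-curvature penalty
$\mathrm{PEN}(f, \lambda_f) = -\tfrac12 \lambda_f \beta^\top S_f \beta$,
$S_f = \int b'' \, b''^{\top}$, so larger $\lambda_f$ means smoother $f$. The
penalized log-likelihood is maximized by Newton/IRLS with step halving
(tolerance $10^{-8}$ relative objective change; the gradient at the optimum is
checked against $10^{-6}(1+\lVert\hat\beta\rVert_\infty)$ in the tests). The
penalties act as improper Gaussian priors, so the inverse penalized negative
Hessian is a posterior covariance for $\beta$, from which tuning-curve
confidence bands are derived by the delta method.

**Identifiability.** A B-spline basis is a partition of unity, so every
continuous block is confounded with the intercept, and the constant lies in
the curvature-penalty null space — no $\lambda$ repairs it. Each continuous
block is therefore reparameterized onto the orthogonal complement of its
sum-to-zero constraint (the usual centering constraint of penalized GAMs);
tuning curves are reported in that centered parameterization, on the log-rate
scale.

**Smoothness selection.** $\lambda$ is chosen by minimizing mean held-out
Poisson deviance across 5 trial-wise folds on a log-spaced grid (8 points,
$10^{-2}..10^{4}$). Because the natural scale of $S_f$ varies by orders of
magnitude between a velocity tuning curve (domain hundreds of cm/s) and a
6-bin coupling filter, the grid is searched on the normalized scale
$\lambda_f = m / \overline{\mathrm{diag}(S_f)}$ — the rescaling used by
standard penalized-GAM software — with one multiplier $m$ per block class
("signal": continuous and event terms; "temporal": history and coupling
filters), selected by coordinate descent that alternates between the classes
until the choice stabilizes (at most 2 passes). Within a multi-unit analysis
the selected multipliers are typically shared across units
(`lambda_scale`), which is also how the studies below keep their runtime
proportionate.

**Train/test split and fit scores.** Trials are split 80/20; the likelihood-
ratio pseudo-$R^2$
$$1 - \frac{\mathcal L(y) - \mathcal L(\hat y)}{\mathcal L(y) - \mathcal L(\bar y)}$$
is reported on both train and held-out sets (pooled over held-out bins; a
per-trial variant would average the same quantities), and a unit with
negative held-out pseudo-$R^2$ is flagged excluded as overfit. A smoothed
$R^2$ — squared correlation between 20 ms-Gaussian-smoothed counts and the
predicted rate — is provided for comparability with correlation-based
reports.

**Inclusion test.** Whether a predictor belongs in the model is decided by a
block Wald chi-square on its coefficient block with degrees of freedom equal
to the block size. The covariance in the statistic is the asymptotic
(sandwich) covariance of the penalized estimator,
$V = V_b \, G \, V_b$ with $V_b$ the posterior covariance and $G$ the
unpenalized Fisher information: using $V_b$ directly makes the statistic's
null expectation the effective degrees of freedom rather than the block size,
i.e. conservative under penalization, whereas the sandwich form is calibrated
— the package verifies a false-inclusion rate consistent with the nominal
level on null simulations. Downstream coupling analyses call a filter
significant at $p < 0.001$.

**Defaults and degenerate inputs.** Continuous terms: cubic B-splines, 10
interior knots at empirical quantiles, deduplicated and kept strictly
interior so point masses in a covariate (velocity pinned at zero before
movement) cannot create coincident knots. Temporal terms: raised-cosine-
spaced knots over the lag window, denser at short lags; coupling and spike-
history windows default to 36 ms (6 bins), strictly causal (lags 1..L), and
never reach across trial boundaries; event filters are causal over 300 ms.
Constant covariate columns are dropped with a warning; an all-zero spike
train in the training trials is a flagged error; non-convergence is flagged,
never silent.

# The synthetic task and ground-truth populations

The generator emulates a closed-loop navigation-to-target task: targets
uniform over 1–4 m and ±45°, joystick limits 200 cm/s and 90 deg/s, two
randomly interleaved optic-flow density contexts, a 7 s trial cap, and a
reward boundary of 60 cm (65 cm also appears in the source literature for
this task; it is accepted as configuration and never silently reconciled).
About 13% of trials abort early (displacement < 0.5 m) and 5% never stop —
the two exclusion rules applied by `filter_trials()`.

The steering agent is a noisy proportional controller with an explicit
endpoint-gain parameter: its aim point is gain × target (in polar
coordinates) plus per-trial endpoint noise, applied radially in cm and
angularly as the matching arc length — so `endpoint = gain × target + noise`
holds exactly per dimension and the behavioral regression is unbiased by
construction. Defaults are radial gain 0.85 and angular gain 0.80 (the
accuracy regime reported for trained macaques on this task) with endpoint
noise 20 cm in the high-density and 30 cm in the low-density context,
encoding the reduced-reliability signature of sparse optic flow. The
controller carries continuous AR(1) joystick jitter on both axes; besides
realism, this keeps mid-range angular velocities sampled, which matters for
identifying angular-velocity tuning. Covariates derived per 6 ms bin:
velocities, accelerations, distances travelled, distance to target, a smooth
gaze proxy, and wrapped LFP band phases synthesized as band-limited phase
oscillators (theta 8, alpha 11, beta 20 Hz) — phases enter the encoding
model only as covariates, so no raw LFP is simulated.

Ground-truth populations carry per-unit baselines (default 3–12 Hz), smooth
random tuning kernels on the same B-spline family the fitter uses,
suppressive spike-history kernels, and directed coupling kernels on random
ordered pairs. Spiking is sampled bin-sequentially: coupling and history
terms see already-sampled past counts only, the log rate is clipped at ±7
(natural log) to forestall runaway excitation, and dynamic terms reset at
trial boundaries. All randomness descends from one session seed through
documented sub-seeds (`derive_seed`), so identical configurations reproduce
sessions bitwise.

Context manipulations transform a population without touching the original:
`tuning_gain` and `coupling_gain` scale the respective kernels;
`coupling_remap` redraws coupling-kernel shapes, optionally at exactly
preserved per-pair norm — the strength-versus-shape dissociation used
throughout the coupling analyses.

# Coupling analyses

Coupling strength is the L2 norm of the coupling coefficient block (the
integral of the absolute kernel is provided as a secondary metric — both
conventions appear in the field). Stability is the Pearson correlation of a
pair's kernels across contexts, computed on kernels evaluated at every lag
bin rather than on raw coefficients so that it is comparable across basis
choices. Reference distributions: **chance** correlates kernels of pairs from
different sessions; **ceiling** correlates the same pair refit on odd versus
even trials of one condition. In the kernel-level simulator that feeds these
references, all estimate types carry equal refit noise: with noisier
odd/even refits a perfectly stable pair would show cross-context correlation
above its own ceiling, inverting the ordering the references exist to
provide. Coupling probability versus electrode distance is a logistic model
with a B-spline distance term, reported at a 500 µm reference distance.
Session-level analyses first require at least 5 coupled units and mean
pseudo-$R^2$ above 0.01, and exclude overfit units; tuning gain across
contexts is only computed for stably tuned units ($r > 0.5$). The evoked
spike-triggered average takes the receiver's rate around sender spikes minus
the mean rate in a 36 ms pre-spike baseline window (the baseline window is a
package choice); self-pairs are rejected.

# Population geometry

Rates are estimated by convolving counts with a mass-preserving 100 ms
Gaussian; each trial is segmented from target onset to movement offset and
linearly time-warped to T = 100 points (T is configurable; endpoints are
preserved exactly). For visualization-style summaries, rewarded trials are
grouped into target-location × density categories, category means are stacked
into a (T·C·D) × N matrix, and PCA (column-centered — centering is a package
choice) gives axes and per-category projections. The stability test draws,
per resample, a reference high-density trial and one high- and one
low-density comparison trial whose targets lie within 10 cm; all three are
projected on the first d axes and the Frobenius distances reference-to-same
and reference-to-other density are recorded; after 1000 resamples
$$d' = \frac{\mu_{between} - \mu_{within}}
{\sqrt{(\sigma^2_{between} + \sigma^2_{within})/2}}$$
(the pooled-variance convention; the distance uses all retained components
jointly) is computed for 1..10 retained components. Resamples without a
target match are skipped and fewer than 100 successes flag the result
low-confidence.

# Decoding

Populations are matched to 10 units by greedy nearest-rate matching against a
reference rate distribution. The lasso decoder works on instantaneous rates:
within-context, five repetitions each hold out a distinct 10% of trials, with
the penalty grid-searched by 5-fold trial-wise CV on the remaining 90% (20
log-spaced values spanning $10^{-4}..10^{2}$ times the null-score scale);
cross-context, the decoder trains on all high-density bins and is scored on
all low-density bins. $R^2$ is computed against the test-set mean and may be
negative. The nonlinear reference decoder is a 10–20–1 network, ReLU on
input and hidden layers, no biases (inputs are sd-scaled and the target
centered so the bias-free architecture is well posed), MSE loss with L2
penalty, Adam with early stopping on a validation split (500-epoch cap,
initialization N(0, 0.1)).

The noise-correlation shuffle discretizes the conditioning variable into 15
quantile bins (optionally jointly with a second variable such as linear
velocity) and permutes each neuron's counts independently within a bin,
preserving per-neuron per-bin count multisets exactly while destroying
cross-neuron dependencies conditional on the variable; it is applied
separately within each context, since moving counts between contexts would
launder context-specific tuning across them. Bins with one time point pass
through unchanged.

# The read-out regimes behind the decoding studies

`simulate_readout_population()` constructs the three regimes the decoding
analyses dissociate. The parameters were set from a signal-to-noise argument,
not tuned: in the *coupled* regime units come in pairs riding on a shared
slow co-fluctuation (sd 0.8 counts/bin, 100 ms correlation time) with
pair-difference tuning (amplitude 0.15) identical across contexts and pair
common-mode tuning (amplitude 0.25) flipping sign between contexts. On
intact data the difference read-out cancels the shared noise and dominates
(pooled common-mode SNR is well below one), so an intact-trained decoder
transfers across contexts; shuffling whitens the shared noise, the decoder
then leans on single-unit (mostly common-mode) tuning, and its cross-context
transfer is negative by construction, $\sum_i a_i^{high} a_i^{low} =
2(A_d^2 - A_c^2) < 0$, while within-context decoding is unaffected. The
*stable* regime keeps per-unit tuning identical across contexts; the
*translated* regime offsets each unit's low-density rate in proportion to
its tuning weight, displacing the population along the read-out direction.

# Reproduction studies and problem sizes

Each headline property runs as a packaged study (`study_*` functions), which
`tests/testthat/test-acceptance.R` asserts and `scripts/acceptance.R`
reports. Problem sizes were chosen as the package's own desk-scale study
conditions: tuning recovery, 15 units × 3 covariates × ~8·10⁴ 6-ms bins,
with tuning sd 0.5 log-units and baselines 5–20 Hz emulating the several-
fold rate modulations of cortical example units (with weaker tuning, ~0.35,
a fifth of unit × covariate pairs become information-limited at this
recording length — recovery is bounded by identifiability, not by the
fitter); coupling recovery, three independent 10-unit populations with 20
injected kernels each (210 null pairs); inclusion calibration, 200 null
fits of 4000 bins; d-prime, four 600-trial sessions per condition with
contexts made fully exchangeable (equal endpoint noise) for the null —
per-session d′ has sampling noise ~0.08 at this size, so the study reports
the across-session mean, mirroring session-wise reporting conventions (for
the translated alternative, separation is asserted from two retained
components up: a one-component projection is dominated by the shared
temporal mode and need not contain the translation direction);
strength/stability dissociation, three 250-trial sessions per manipulation
with balanced (half excitatory) injected graphs so that doubling coupling
stays in a dynamically stable rate regime; behavioral pipeline, 100 sessions
of 1000 trials (the scale of a recording session). The behavioral gain shows
a small (≈0.01) downward truncation effect in the noisier context because
the 0.5 m abort filter removes legitimately short responses near the
smallest targets; the study's tolerance accounts for it.

# What passing these studies does and does not show

The generator produces Poisson spiking with exactly the model's own link and
basis family, stationary tuning, and noiseless covariates. Passing recovery
therefore demonstrates the correctness of the estimation and analysis code
and its statistical calibration — not robustness to non-Poisson dispersion,
unmodeled covariates, slow nonstationarities, spike-sorting errors, or
electrode drift, all present in real recordings. Similarly, the read-out
regimes realize the hypothesized mechanisms in their cleanest form; real
populations mix them. The chance/ceiling references in the kernel-level
simulator idealize refit noise as Gaussian and equal across estimate types.

# Known limitations

Within-area analyses only (across-area filter durations are accepted as
configuration but not analyzed); no eye-movement modeling beyond a smooth
gaze proxy; no LFP spectral estimation (phases are synthesized covariates);
no pseudo-population pooling beyond simple stacking; session bundles are
plain CSV/YAML directories rather than a binary hierarchical container. The
per-class smoothness multiplier is a two-class approximation to fully
per-term selection; fully independent per-term optimization would be slower
and was not needed for calibration or recovery at these problem sizes.
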