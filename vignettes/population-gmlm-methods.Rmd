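---
title: "Modeling population spike trains with low-rank tensor GLMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling population spike trains with low-rank tensor GLMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(popGMLM)
```

This vignette is the package's own account of the model it implements, the
assumptions behind it, the tunable constants and why they have the defaults
they do, what the synthetic-data generator does and does not emulate, and
the places where the design was genuinely open and a choice had to be made.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## The model

### Single-cell point-process GLM

Spike trains are discretized into `bin_width = 0.005` s bins. For one
neuron, the count in bin $t$ is
$y(t) \sim \mathrm{Poisson}(e^{\lambda(t)}\Delta)$ with log rate

$$\lambda(t) = w + (\mathbf{h}^{spk} * \mathbf{y})(t)
  + (\mathbf{k}^{tbar} * x^{tbar})(t)
  + \sum_{s\in\mathcal{S}} (\mathbf{k}^{(s)} * x^{(s)})(t).$$

Task events are linearized as unit impulses: the sample and test stimulus
onsets and, on match trials, the touch-bar release. Each temporal kernel is
a linear combination of raised-cosine basis functions; the orthonormalized
basis controls the kernels' temporal smoothness. Four nested stimulus
parameterizations define the event set $\mathcal{S}$: *none* (sample/test
timing only, $S=2$), *category* (sample and test category kernels, $S=4$),
*cosine* (category kernels plus shared $\cos\theta,\sin\theta$ direction
weights, $S=6$), and *full* (one kernel per direction plus two
test-category kernels, $S=D+2$). In the full model the direction kernels
absorb the sample-category response and the test-category kernels encode
test-minus-sample category tuning; this is what keeps the parameterization
identifiable. Supplementary variants with independent sample/test direction
tuning ($S=8$ and $S=2D+2$) follow the same construction; for the
independent full variant the prior mirrors the shared convention with
separate circular-GP latents per role under shared hyperparameters.

Only correct trials with unambiguous (off-boundary) categories enter any
design. The modeled window runs from sample onset to 50 ms after the
touch-bar release, or 50 ms after test motion offset when no release
occurred; the second test stimulus of non-match trials is never modeled.

### Priors and evidence optimization

Stimulus-kernel coefficients get zero-mean Gaussian priors built from
latent sums: a latent shared across kernels (scale `psi_0`) induces
sample/test correlation, category latents add `psi_c` (or `psi_s`),
cosine/sine weights get `psi_d`, and the full model adds a circular
Gaussian-process term over directions with scale `psi_theta` and
arc-length parameter `tau` via the kernel
$K(\theta,\theta') = (1 + \frac{\tau+4}{\pi}d)(1-\frac{d}{\pi})^{\tau+4}$,
$d = \arccos\cos(\theta-\theta')$. Touch-bar and spike-history coefficients
are i.i.d. normal with scales `psi_tbar`, `psi_spk`; the baseline gets an
improper flat prior. Hyperparameters carry the heavy-tailed prior
$p(h)\propto(1+h/\nu)^{-(\nu+1)/2}$ with $\nu=4$, implemented exactly in
that form (the printed density is not the squared-argument half-t; we take
it at face value — it is proper on $h>0$ and maximal at zero, which is the
regularizing behavior that matters here). Scalar prior statements of the
form $N(0,\psi)$ are read as variance $\psi^2$, consistent with every other
prior in the model family.

Single-cell GLMs are fit by Newton iteration on the log-concave posterior;
hyperparameters are chosen by maximizing a Laplace approximation of the
evidence plus the hyperprior over log-transformed hyperparameters
(Nelder-Mead on 2–5 log scales, inner Newton warm-started). The Laplace
evidence is exact for a Gaussian likelihood, which is how the test suite
validates it.

### The population tensor model

The GMLM ties the stimulus kernels of all $N$ neurons into a rank-$R_s$ CP
tensor $\mathcal{K}(t,s,n)=\sum_r T_r(t)U_{s,r}V_{n,r}$: shared temporal
factors, shared stimulus weights, per-neuron loadings. The touch-bar
response is a rank-$R_l$ matrix factorization (default $R_l = 3$), and
baselines and spike-history kernels stay per-neuron, exactly as in the
single-cell GLM. Neurons contribute independent likelihood terms — the
model captures signal correlations through the shared factors and makes no
attempt at noise correlations, which is what lets non-simultaneously
recorded cells form one population.

Optional low-rank *dynamic spike history* multiplies a shared history
kernel by an event-locked temporal gain and a per-neuron loading, so the
effective self-history filter of a cell changes along the trial; the
effective kernel at any time is the constant kernel plus the gain-weighted
dynamic kernels.

### Exact trial aggregation

The package evaluates the population likelihood on groups of trials that
share a neuron, an event layout and stimulus coefficients: without
spike-history terms all trials in such a group share their log-rate trace,
so the Poisson log likelihood depends on the data only through per-group
summed counts and trial multiplicities. Within a layout, rows are further
split by kernel support (sample-only, test-only, overlap) and rate-identical
columns merged. Both reductions are exact — the log likelihood is a sum
over (bin, trial) cells — and the test suite asserts agreement with the
direct per-trial evaluation to machine precision. This is what makes
maximum-likelihood rank sweeps at hundreds of trials per neuron and long
HMC runs feasible in plain R.

## Inference

Rank selection uses maximum likelihood (multi-start L-BFGS with analytic
gradients; temporal factors initialized as random orthonormal matrices,
loadings and stimulus weights standard normal, baselines normal around the
log mean rate). Ten-fold cross-validation stratified by sample direction
scores each rank by the mean held-out log likelihood per trial per cell;
subtracting the rank-0 model and normalizing by the single-cell GLM gives
the explainable-likelihood fraction, and the smallest rank above 0.9 is
selected. Test-scale sweeps use 5 folds purely for runtime; the fold count
is a parameter everywhere (see the limitations section for how the GLM
reference behaves at desk scale).

Bayesian inference samples parameters and log-hyperparameters jointly with
HMC: leapfrog integration with $S=\min(100,\lceil 1/\epsilon\rceil)$ steps,
dual-averaging adaptation of $\epsilon$ toward 80% acceptance (constants
$\gamma=0.05$, $t_0=10$, $\kappa=0.75$) frozen over the last 4% of warmup,
and a diagonal mass matrix re-estimated twice during warmup from inverse
empirical variances (at 16% and 76% of warmup, windows proportional to the
reference 2001–4000 and 4001–19000 of 25000). Proposals with energy error
above 1000 count as divergent and are rejected.

Because any CP component can be rescaled ($U \to aU$, $T \to bT$,
$V \to V/ab$) without changing the likelihood, the sampler interleaves ten
Metropolis-Hastings rescaling steps per component between HMC steps:
lognormal scale factors ($\omega = 0.2$) walk along the flat direction and
are accepted against the chi-distribution priors of the three factor norms
conditioned on their product, with the $1/(ut)$ change-of-variables factor.
One subtlety: written as lognormal densities evaluated at the reciprocal
scales, the printed proposal-ratio factor would contribute $s^2$ per
rescaled norm, but the correct Hastings factor for a multiplicative random
walk is $s$ (the proposal density in norm space carries a $1/u$ term). The
package uses the latter; an MH-only chain then reproduces the conditional
prior of the norms against a rejection-sampling oracle, which is asserted
in the acceptance suite and would fail under the $s^2$ variant.

MAP estimates for display set each hyperparameter to its marginal posterior
median and maximize the posterior at those values. Model comparison for the
dynamic-history variants uses PSIS-LOO computed from the draws (generalized
Pareto tail-smoothing of the importance ratios, per-trial, averaged within
neuron), implemented in the package since no LOO library is assumed.

## Geometry and decoding

For cosine-tuned fits, direction tuning at time $t$ is an ellipse in the
$R_s$-dimensional stimulus subspace generated by $f_1$ (cosine) and $f_2$
(sine) after mapping through the orthonormalized, $1/\sqrt N$-scaled output
map. The preferred angle maximizes
$D_t(\theta)=\lVert E_t(\theta)-E_t(\theta+180^\circ)\rVert$; the package
uses the standard closed form $\tan 2\theta_0 = 2f_1\!\cdot\!f_2 /
(\lVert f_1\rVert^2-\lVert f_2\rVert^2)$, evaluates both candidates
$\{\theta_0, \theta_0+90^\circ\}$, folds the argmax into $[45^\circ,
225^\circ)$ (the angle is only identified modulo 180°, and this range ties
it to the category boundary), and cross-checks against a 1° grid at
runtime, warning on disagreement. A printed closed form that drops the
$f_1\!\cdot\!f_2$ cross-term cannot pass that grid check, which is why the
cross-check is mandatory rather than decorative. Degenerate (circular)
tuning is flagged and resolved to the lower candidate angle. The category
vector is the projected difference between the two sample-category weight
columns. Posterior medians and central 99% intervals of all metrics are
computed per time point across draws. Population trajectories for
visualization come from an HOSVD of the sample-direction kernel tensor
(optionally after removing the across-direction mean), projected onto the
top neuron-mode dimensions and scaled by $1/\sqrt N$.

Decoding uses pseudopopulations — neurons were not recorded together, so
each pseudotrial samples one real trial per neuron with replacement within
condition (50 per direction) — and ridge-penalized logistic decoders on
z-scored counts (training statistics only; glmnet with $\alpha=0$,
$\lambda=0.1$, matching the stated ridge penalty of 0.1; zero-variance
features are floored, leaving them centered at zero). Direction-independent
category coding is probed by training on one direction pair per category
and validating only on withheld directions, averaging two complementary
decoders; purely circular direction tuning then cannot generalize, while a
category axis can. For the six-direction task the training pairs are
{15°, 195°} and {75°, 255°} — the source description calls them
"spaced 180° apart", which pins the second pair despite a printed 225°
that is not in the direction set. Match/non-match cross-training uses
counts 0–200 ms after test onset; with a shared RNG stream the sample- and
test-category decoders are exact mirror images about chance on the
crossing condition, and the test suite asserts that identity.

## Single-neuron indices

rCTI compares ROC discriminability (|AUC−0.5|, midrank ties) between
direction pairs at matched angular separation: adjacent directions around
the circle are paired and the mean across-boundary discriminability minus
the mean within-category discriminability is reported on a ±0.5 scale.
Distance matching is essential: pooling all pairs, perfect within-category
separation necessarily produces across-category separability too, so the
−0.5 end point stated for the index would be unreachable. rDSI is the
maximum within-category pairwise discriminability minus its mean over
direction-label shuffles. The parametric tuning curve
$\lambda(\theta)=\exp[\beta_0+\beta_{cat}c_\theta+\beta_{\sin}\sin\theta+
\beta_{\cos}\cos\theta]$ ($c_\theta=\pm 0.5$) is fit by Poisson ML;
category magnitude is $|\beta_{cat}|$ and direction magnitude the
peak-to-trough difference $2\sqrt{\beta_{\sin}^2+\beta_{\cos}^2}$, both
corrected by subtracting the mean magnitude over label-shuffled refits
(coefficients are capped at ±10 under separation and flagged). Behavioral
fractions use the Beta(1,1)-binomial posterior: mean $(k+1)/(n+2)$ and a
central 99% credible interval.

## The synthetic world

The generator emulates the six-direction categorization task: 650 ms
stimulus presentations, a 1000 ms delay, directions
{15°, 75°, ..., 315°} split at the 45°–225° boundary, 5 ms bins, and — on
match trials — a touch-bar release drawn uniformly 200–500 ms after test
onset (a reaction-time law chosen once for plausibility; the source work
models recorded, not simulated, releases). Baselines are normal around
log(8) sp/s, typical of parietal cells in these tasks. Stimulus-weight
templates produce the qualitative regimes of interest: a pure category
axis, pure circular direction tuning, both mixed, or no stimulus
dependence at all.

Three generator-scale choices matter and were made once, on realism grounds:

- **Modulation depth.** Component tensor norms are set so peak log-rate
  excursions are around 0.5–1 (rates moving several-fold across
  directions; the scale knob is `amp = 4`). Strongly tuned parietal cells
  modulate at this order; with modulations an order of magnitude weaker,
  the stimulus subspace is statistically invisible at realistic trial
  counts and no method could recover it.
- **Component balance.** Each rank-1 component is normalized to a common
  tensor Frobenius norm (with the loading direction random), so a nominal
  rank-$R$ truth genuinely contains $R$ comparable components. Without
  this, a "rank-2" truth is frequently rank-1 in all but name and rank
  recovery becomes a coin flip about the generator, not the method.
- **Distinct temporal motifs.** Each component's temporal factor is 70% a
  Gaussian envelope with its own peak time and width (drawn over the
  sample-through-delay epoch) plus 30% random smooth dynamics. Purely
  random coefficient vectors integrate to ~0 over the trial, so
  spike-count decoders would see no signal however strong the tuning; one
  *shared* envelope would instead make the components temporally collinear
  and rank identification meaningless. Real population components are
  distinct motifs — transient, sustained, delay-ramping — and the
  generator mirrors that.

What a green test does establish: binning, design construction, likelihood
and gradients are exact; the sampler targets its posterior and its
adaptation lands near the nominal acceptance rate; rank selection and
tensor recovery behave correctly on data truly generated by the model at
realistic scale; the geometry and decoding layers compute what they claim
on known ground truth. What it does not establish: anything about real LIP
data — no recorded dataset ships with the package — nor robustness to
non-Poisson dispersion, drifting baselines, or correlated noise, none of
which the generator emulates.

## Numerical choices and limitations

- Bins are half-open $[t, t+\Delta)$; events map to the bin containing
  them; spikes at the window end are excluded.
- Bump peaks are snapped to the bin grid so each raw basis column attains
  exactly 1 at its peak bin; QR orthonormalization proceeds in peak order
  with signs fixed positive at each column's largest entry.
- The spike-history cosine bumps default to peaks at 10–200 ms. At 5 ms
  bins, bumps with peaks confined to 10–20 ms have sub-bin support and the
  raw basis degenerates to (at best) duplicated indicator columns, so the
  literal narrow range is not constructible; the range stays configurable.
- The touch-bar basis mirrors the first 8 stimulus functions with the
  fastest function peaking +25 ms after release; peaks land near
  [−193, +25] ms. A rigid reversal cannot also stretch the span, so the
  printed −235 ms end point is approached but not matched exactly.
- L-BFGS objectives replace non-finite values (rate overflow during line
  search) with a large penalty; log-rates are clipped at +4 during
  simulation only.
- Near-singular stimulus prior covariances (hyperparameters driven toward
  zero during warmup) evaluate to log-posterior −Inf and are rejected
  rather than jittered.
- GLM cross-validation offers both per-fold evidence optimization (the
  reference procedure; `glm_evidence = TRUE` in `rank_sweep`) and fixed
  hyperparameters (cheaper; used in the test suite).
- **Rank selection at desk scale is biased low.** The explainable-likelihood
  fraction divides by the held-out performance of independently fit
  single-cell GLMs. At a few hundred trials per neuron the GLM reference
  pays an estimation penalty of roughly 0.1 per trial held out — a third
  of the total stimulus information in the simulations — even with
  evidence-optimized shrinkage, so `frac` values run 1.5–2 rather than
  topping out near 1 and `frac(rank 1)` typically already exceeds the 0.9
  threshold: the smallest qualifying rank is then 1 regardless of the true
  rank. Tensor recovery at the true rank is unaffected. The corresponding
  acceptance assertion is kept at its stated bar and fails honestly; with
  much larger per-neuron trial counts (shrinking the GLM penalty) the
  fraction scale normalizes and threshold selection becomes meaningful.
- The sampler stores all draws unthinned in memory as doubles; at the
  reference schedule and population sizes this is hundreds of MB and the
  desk-scale schedule is the default for interactive use.
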