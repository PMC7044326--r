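---
title: "Outcome-gated history biases: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outcome-gated history biases: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`histgate` simulates and analyzes two-alternative forced choice (2AFC)
behavior in environments with serial correlations, where subjects (rats in
the motivating experiments, but nothing in the code is species-specific)
develop *trial-history biases*: tendencies to repeat or alternate their
previous choice that build up over trials and are modulated by reward.
This vignette documents the models, the estimation choices, and the
numerical decisions a user or reviewer should know about.

## The task generator

Stimulus categories $c_k \in \{-1, +1\}$ form a two-state Markov chain
with repeat probability $P_{\mathrm{rep}}$, which alternates between 0.7
(repeating blocks) and 0.2 (alternating blocks) in blocks of 200 trials.
Both categories are unconditionally equiprobable for any
$P_{\mathrm{rep}} \in (0, 1)$, so the only structure is in the
*transitions*. The stimulus strength $s_k$ is drawn independently of the
category from $\{0, 0.23, 0.48, 1\}$, and the signed stimulus evidence is
$e_k = c_k s_k$. Each trial's sound is divided into frames of one
amplitude-modulation cycle each (20 Hz, i.e. 50 ms; 8 frames by default),
and the instantaneous evidence $S_{k,f}$ of each frame is drawn i.i.d.
from a stretched beta distribution on $[-1, 1]$ with mean $e_k$ and
variance 0.06; at $e_k = \pm 1$ the distribution degenerates to a point
mass. The per-frame amplitude weights of the two tones are
$a^L = (1 + S_{k,f})/2$ and $a^R = (1 - S_{k,f})/2$, modulated by
$1 + \sin(2\pi f_{AM} t + \varphi)$ with $\varphi = 3\pi/2$ so the
envelope starts silent.

Numerical notes:

* **Stretched beta.** We map $x \in [-1,1]$ to $u = (x+1)/2$, giving a
  Beta distribution with mean $m = (e+1)/2$ and variance $v =
  \mathrm{var}/4$; its shape parameters are $\alpha = m(m(1-m)/v - 1)$
  and $\beta = (1-m)(m(1-m)/v - 1)$. If $v \ge m(1-m)$ the request is
  infeasible and the generator raises an error; with the default variance
  this cannot happen for $|e| \le 0.48$, and $|e| = 1$ takes the
  point-mass branch.
* **Envelope identity.** $a^R$ is computed as $1 - a^L$ (algebraically
  identical to $(1 - S)/2$), which makes the conservation
  $a^L + a^R = 1$ bit-exact at every sample rather than merely accurate
  to rounding.
* **AM phase.** The modulation uses the angular form
  $2\pi f_{AM} t + \varphi$, so 20 Hz yields the stated 50 ms cycle and
  the envelope is zero at $t = 0$.
* **Strength marginals.** The marginal distribution over the four
  strengths is uniform by default and configurable
  (`task_config(strength_probs = ...)`); the task definition fixes the
  support but not the weights.

## The gated-accumulator agent

The generative model (`dynamic_params()`, `simulate_agent()`) carries
three latent variables across trials:

* lateral evidence $z^L$, a leaky accumulator of past responses;
* transition evidence $z^T$, a leaky accumulator of past transitions
  (repetition $T = +1$, alternation $T = -1$);
* a gating signal $c^T \in [0, 1]$ that scales the influence of $z^T$ on
  choice.

After a trial with response $r_t$, outcome $o \in \{+,-\}$ and transition
$T_t$ (with respect to the previous response, whose outcome is $o'$):

$$z^L \leftarrow (1 - \lambda_L^{o})\, z^L + \Delta_L^{o} r_t, \qquad
  z^T \leftarrow (1 - \lambda_T^{o})\, z^T + \Delta_T^{o',o} T_t, \qquad
  c^T \leftarrow \mathrm{clip}\!\left(c^T + \Delta_C^{o},\, 0,\, 1\right).$$

The next choice is right with probability

$$p = \pi_R + (1 - \pi_R - \pi_L)\,
      \Phi\!\left(w\, x_t + \gamma^L + \gamma^T + B\right),
  \qquad \gamma^L = z^L, \quad \gamma^T = c^T z^T r_{t-1},$$

where $x_t$ is the summed frame evidence. The product with $r_{t-1}$
projects the repeat/alternate prediction into left/right choice space.
The *gating hypothesis* corresponds to $\Delta_C^- \approx -1$ (an error
extinguishes the gate) with $\Delta_C^+ \approx +1$ (a single reward
restores it), while $z^T$ itself keeps leaking at the same moderate rate
after corrects and errors. The *complete reset* alternative
(`complete_reset_params()`) instead sets $\lambda_T^- = 1$ and leaves the
gate inert.

Conventions that were genuinely open and that we fixed once:

* The $c^T$ update is an **additive increment with hard clipping** to
  $[0, 1]$. The behavior it must express is "an error can extinguish the
  gate, a reward can restore it to its maximum of 1", which a bounded
  additive rule captures with interpretable endpoints ($\Delta_C^- = -1$
  extinction, $\Delta_C^+ = +1$ full recovery). Multiplicative or
  sigmoidal schemes would express the same qualitative dynamics but lose
  that endpoint interpretation.
* The transition bias is $c^T z^T r_{t-1}$ — the gate multiplies the
  *transition* accumulator, not the lateral one.
* Leaks are parameterized so that the retained fraction is $1 - \lambda$:
  $\lambda = 1$ is a full reset.
* On the first trial of a session there is no previous response: the
  transition update is skipped, $\gamma^T$ drops out of the choice rule,
  and the latents start at $z^L = z^T = 0$, $c^T = 1$. Sessions are
  statistically independent; no state is carried across session
  boundaries.
* A lapse term is included (bounded in $[0, 0.5]$); with lapse-free
  generative data it simply fits to zero.

### Default generative parameters

The defaults of `dynamic_params()` define the synthetic study conditions
used throughout the tests. Where the motivating experiments constrain a
value qualitatively but not numerically, we chose once what is realistic
for well-trained rats and did not revisit it:

| parameter | default | rationale |
|---|---|---|
| `w_stim` | 0.25 per summed-frame unit | an effective probit sensitivity of $\approx 2$ per unit of evidence, giving overall accuracy near 0.75 on the four-strength mix |
| `delta_T_pp` | 0.3 | only transitions between two rewarded trials update $z^T$; steady-state bias $\Delta/\lambda = 1.5$ matches a repeating-bias plateau just above 1 |
| `delta_T_pm/mp/mm` | 0 | transitions involving an error are ineffective |
| `lambda_T_+/-` | 0.2 | a 3–5 trial integration window; identical after corrects and errors (the maintenance of $z^T$ is the point of the gating account) |
| `delta_C_+` / `delta_C_-` | +1 / −1 | full recovery after a reward, extinction after an error |
| `delta_L_+` / `delta_L_-` | 0.1 / −0.05 | a win-stay/lose-switch lateral bias an order of magnitude weaker than the transition bias |
| `lambda_L_+/-` | 0.5 | fast-decaying lateral evidence |
| lapses | 0 | clean psychometrics; the fitters still estimate them |

## Fitting the agent

Because the latents are deterministic given the parameters and the
observed history, the sequential likelihood is **exact** — there is no
filtering or expectation step. `fit_dynamic_model()` maximizes the log
posterior (the exact log-likelihood plus weak Gaussian priors, sd 10, on
the unbounded parameters; flat priors on the bounded ones) with
bound-constrained quasi-Newton (`L-BFGS-B`) from a neutral start plus
random restarts (10 by default). The recursion itself is compiled (C++),
which keeps a 10,000-trial fit with multiple restarts in the tens of
seconds. Non-convergence is reported with the optimizer code and the best
iterate is returned. Reduced variants (e.g. no gating:
`fixed = c(delta_C_plus = 0, delta_C_minus = 0)`) refit with those
entries held constant, and BIC on the exact likelihood compares them.

Caveats: with $\Delta_C^+$ at its bound the likelihood is flat above the
largest gate deficit actually visited, so boundary parameters recover as
boundary values; lapse estimates sit on the boundary 0 when the
generative lapse is 0 (their standard errors are then meaningless, which
is why the recovery checks target the update and leak parameters).
$\Delta_C^+$ itself is the least identified of the update parameters: it
is informed only by the post-error-rebound trials (an error followed by
a correct response, under 10% of trials) and trades off against the
post-error leak $\lambda_T^-$ along a likelihood ridge; its profile
standard deviation is roughly 0.14 at 10,000 trials, several times
larger than that of $\Delta_T^{++}$ or $\Delta_C^-$. Recovery claims
about the gate should therefore rest on $\Delta_C^-$ (the extinction),
which is sharply identified. The likelihood is also multimodal — a
no-gating mode exists even for gated data — which is why the optimizer
seeds itself with the gating and complete-reset archetypes in addition
to neutral and random starts, and polishes the winner at a tighter
tolerance.

## Psychometric curves and conditioned biases

Two probit curves summarize behavior: the proportion of rightward
responses versus evidence $e$, $\Phi(\beta e + B)$, whose shift $B$ is
the **fixed side bias**; and the proportion of repeated responses versus
the repeating evidence $\hat e_t = r_{t-1} e_t$,
$\Phi(\beta' \hat e + b)$, whose shift $b$ is the **repeating bias**
($b > 0$ = tendency to repeat). Both are fit by Bernoulli maximum
likelihood (`stats::glm`, probit link) — not least squares on binned
proportions — and uncertainty comes from a nonparametric bootstrap over
trials (1000 resamples by default). The psychometric model is
deliberately lapse-free; lapses belong to the GLM and the agent. Fits
are flagged unstable when any evidence level has fewer than 10 trials,
and separation is reported rather than silently returned.

Sequence-conditioned biases (`repeating_bias_conditioned()`) select the
trials preceded by a given history pattern and refit the repeating curve
on that subset. Patterns are token strings over
`rep+` / `alt+` / `err` / `corr`, anchored at trial $t-1$;
`rep_pattern(n)` asks for a run of exactly $n$ correct repetitions (the
run must not extend further back — `exact = FALSE` gives the at-least
reading), optionally terminated by an error. The exact-length reading is
what "bias after $n$ consecutive correct repetitions" means in the
build-up analyses; it also keeps neighboring conditions disjoint.

## The trial-history GLM

`build_design_matrix()` implements the regression account of the same
behavior: the probit argument sums the eight current-frame evidences,
after-effect terms $S^{sum}_{t-k}$, rewarded and unrewarded response
kernels $r^+_{t-k}, r^-_{t-k}$, and transition kernels
$T^{o,q}_{t-k} = r^o_{t-k-1} r^q_{t-k}$ projected by $r_{t-1}$, over lags
$k = 1..6$ with the last lag pooling trials $t-6$ to $t-10$ under one
weight. The response model adds left/right lapse rates:
$p(r_t = +1) = \pi_R + (1 - \pi_L - \pi_R)\Phi(y_t)$.

Estimation choices:

* **Penalized MLE** with analytic gradients under `L-BFGS-B`, with a
  small configurable L2 penalty ($10^{-4}$) on all weights except the
  intercept. The penalty regularizes without visibly biasing kernels at
  the trial counts used here.
* **Conditioning on the previous outcome** (`after_correct` /
  `after_error`) makes some low-lag columns exactly collinear — e.g.
  conditioned on a correct previous trial, $T^{++}_{t-1} r_{t-1}$
  coincides with $r^+_{t-2}$ — and others identically zero. A QR rank
  check detects them; the drop order keeps transition-family columns and
  reports dropped weights as `NA`, so transition kernels (the objects of
  interest) stay identified and the indeterminacy lands on the redundant
  lateral entries.
* **Standard errors** come from the observed information (numerical
  Hessian at the optimum). Boundary lapse estimates can make the Hessian
  singular; affected entries are reported as `NA` rather than
  extrapolated.
* Signed (not rectified) frame sums are used for the after-effect
  regressors.
* Model comparison (`compare_models()`) uses training BIC and, when
  held-out sessions are supplied, held-out log-likelihood; a split
  after-correct/after-error model is treated as one model with summed
  likelihood and parameter count.

## Transfer coefficients

`transfer_coefficient()` asks how predictive the transition bias at trial
$t$ is of the choice at $t+k$, conditioned on the outcomes of trials
$t..t+k-1$. We regress (probit) the repeat-coded choice at $t+k$
($r_{t+k} = r_{t+k-1}$?) on the repeat-axis bias at $t$
($\gamma^T_t r_{t-1} = c^T z^T$), with the repeat-coded stimulus evidence
at $t+k$ and the signs of the intervening transitions
($t+1 .. t+k-1$) as covariates (both configurable). Partialling out the
intervening transitions matters: without it the strong autocorrelation of
$z^T$ makes the coefficient flat in $k$; with it the coefficient isolates
the component of the bias *carried over* from trial $t$, which decays
with lag like the GLM transition kernel. The gamma series can come from
known generative parameters, a fitted agent, or the transition kernels of
a fitted GLM. Standard errors are Wald by default; a session-level
bootstrap (200 resamples) is available and is what the discrimination
analyses use. The diagnostic signature: under gating, the
(error, correct) pattern at lag 2 has a clearly positive coefficient (the
bias survives the error and returns); under complete reset it is zero.

## What the synthetic data do and do not establish

The generator reproduces the structural conditions of the motivating
experiments — block-structured Markov categories, the four-strength
stimulus set, stretched-beta frame evidence, and choices from the gated
agent at realistic magnitudes. It does **not** emulate reaction times,
intertrial-interval effects, session-to-session drift, cross-animal
heterogeneity, lapse asymmetries, or motor/side idiosyncrasies of real
rats. Passing tests therefore establish that the estimators recover the
truth *under the model class and these conditions* — parameter
recovery, not external validity on animal data. The file-format adapter
for externally deposited behavioral tables is left as a documented
extension point.

## Problem sizes and tolerances used by the test suite

Monte-Carlo checks use sizes at which the expected sampling error is
several times smaller than the asserted tolerance: 100,000 trials for
Markov repeat fractions (±0.005) and frame-evidence variance (±0.002);
50,000 trials (100 sessions) per seed, five seeds, for the GLM gating
signature; 40 sessions of 500 trials per variant with 200 bootstrap
resamples for the transfer discrimination; 20 sessions of 500 trials,
five seeds, for dynamic-model recovery (key parameters within 15%
relative or 0.1 absolute); 200,000 trials for the conditioned
repeating-bias build-up/reset curves. Exactness checks (envelope
conservation, latent recursions versus brute-force replay, likelihood
versus enumeration) use tolerances at numerical precision
($\le 10^{-10}$) on sessions of up to 50 trials.

## Known limitations

* The exact likelihood treats latents as deterministic; if one wanted
  latent noise (e.g. diffusive $z^T$), fitting would require filtering,
  which is out of scope.
* The additive-clipped $c^T$ rule is one of several bounded update
  schemes consistent with the observed extinction/recovery dynamics;
  conclusions about *whether* gating occurs are robust to this choice,
  estimates of $\Delta_C$ are rule-specific.
* After-error GLM fits use roughly a quarter of the trials; their
  kernels are correspondingly noisier, which matters below ~10,000
  trials per condition.
* The transfer coefficient is a regression definition; alternative
  definitions (e.g. correlation-based) would change its scale but not
  the gating-versus-reset contrast it is built to expose.
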