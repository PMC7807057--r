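---
title: "Joint perceptual decisions over a haptic channel: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint perceptual decisions over a haptic channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapticdyad)
```

## The decision model

Each observer in a two-interval forced-choice contrast-oddball task is a
signal-detection observer of the signed contrast difference $\Delta C$
(second minus first interval, in contrast-percent). On a trial the
observer draws $z \sim \mathcal N(\Delta C + b, \sigma)$ and reports
"second" when $z > 0$, so the psychometric function is the cumulative
Gaussian

$$P(\Delta C) = H\!\left(\frac{\Delta C + b}{\sigma}\right),$$

with bias $b$ and internal noise $\sigma$, and maximum slope
$s = 1/\sqrt{2\pi\sigma^2}$ (the observer's *sensitivity*). A positive
bias shifts reports towards "second". The signed *confidence* attached to
a choice is the normalised decision variable $c = z/\sigma$.

Under **Weighted Confidence Sharing (WCS)** the two members of a dyad pool
their confidences and decide by the sign of $c_1 + c_2$. Because
$c_1 + c_2$ is Gaussian with mean
$(\Delta C + b_1)/\sigma_1 + (\Delta C + b_2)/\sigma_2$ and standard
deviation $\sqrt 2$, the dyad's final answers again follow a cumulative
Gaussian with

$$b_{dyad} = \frac{\sigma_2 b_1 + \sigma_1 b_2}{\sigma_1 + \sigma_2},
\qquad
\sigma_{dyad} = \sqrt 2\,\frac{\sigma_1\sigma_2}{\sigma_1 + \sigma_2},
\qquad
s_{dyad} = \frac{s_1 + s_2}{\sqrt 2}.$$

Writing $r = s_{min}/s_{max}$ for the member sensitivity ratio, the
relative dyad performance is the affine *improvement line*
$s_{dyad}/s_{max} = \tfrac{\sqrt2}{2}(1 + r)$: slope and intercept both
$\sqrt2/2 \approx 0.71$, crossing 1 at the *critical ratio*
$\sqrt 2 - 1 \approx 0.4$. `critical_ratio()` and `improvement_line()`
return these exactly; dyads are classified "similar" when $r \ge 0.4$
(the boundary itself is classified similar — the strict inequalities in
the usual statement leave the boundary undefined, so we document a tie
rule rather than leave it to floating-point accident).

Three competitor rules are implemented for model comparison, with the
closed forms from the source that introduced them (each prediction is
flagged `provenance = "cited-source formula"` since the rules are named
but not restated alongside the WCS derivation): Coin Flip,
$s_{dyad} = (s_1 + s_2)/2$; Behaviour & Feedback,
$s_{dyad} = \max(s_1, s_2)$; Direct Signal Sharing,
$s_{dyad} = \sqrt{s_1^2 + s_2^2}$. They bracket the WCS prediction
($DSS \ge WCS \ge CF$), which is what makes the improvement-vs-ratio
pattern diagnostic.

A flatter-than-predicted improvement slope with an unchanged intercept is
the signature of *over-weighting* the better member:
$s_{dyad}/s_{max} = \tfrac{\sqrt2}{2} + \tfrac{\sqrt2}{2}\gamma r$ with
$\gamma = \alpha/\beta < 1$. Because the intercept is fixed by the model,
`improvement_regression()` estimates $\gamma$ by least squares with the
intercept pinned at $\sqrt2/2$,
$\hat\gamma = \sum r(y - \tfrac{\sqrt2}{2}) \big/ \tfrac{\sqrt2}{2}\sum r^2$,
alongside the ordinary unconstrained OLS fit.

## Psychometric fitting

`fit_psychometric()` estimates $(b, \sigma)$ from per-level response
proportions. The default criterion is unweighted least squares on the
proportions, matching the generic curve-fitting practice this analysis
descends from; binomial maximum likelihood is available as the
statistically preferred option and is what the parameter-recovery tests
use, because it also provides asymptotic standard errors from the
observed information (the slope SE follows by the delta method,
$\mathrm{SE}_s = (s/\sigma)\,\mathrm{SE}_\sigma$).

Numerical choices: the optimiser is L-BFGS-B on $(b, \sigma)$ with
$\sigma \in [0.1, 100]$ contrast-percent and $b \in [-50, 50]$,
initialised from a probit-transformed linear regression with a $+1/2$
continuity correction; a second start from the first optimum polishes the
solution (a tight optimum can make the final line search report a
spurious code, so convergence is taken from either run). Proportions of
exactly 0 or 1 are used as-is by least squares — no clamping — and the
likelihood handles them natively. All-identical response patterns (or a
single level) are rejected as non-identifiable rather than returned with
a boundary $\sigma$. No lapse or guess-rate parameters are fitted: the
model deliberately has exactly $(b, \sigma)$.

Dyad fits include agreement trials by default — the WCS closed forms
above are derived for the *final* answer on every trial, agreed or not —
and `bin_choices(..., disagreement_only = TRUE)` exposes the restriction
for sensitivity analyses.

Accuracy at the standard session size (8 blocks, 16 trials per signed
level): the Cramér–Rao bound for $\sigma$ at this design gives a relative
standard error of 17–28% over $\sigma \in [3, 20]$, i.e. a best-possible
median relative error of roughly 12% for any unbiased estimator. The
recovery test therefore asserts the attainable figure (median below 15%
for the binomial MLE) — single-session estimates of $\sigma$ are
intrinsically noisy at this design, which is worth remembering when
interpreting per-dyad ratios.

## What the synthetic generator emulates

`run_experiment()` produces the two tables every downstream analysis
consumes: a per-trial decision log and long-format group-phase
trajectories.

**Design.** Balanced blocks: each oddball timing (first/second interval)
× contrast level combination appears exactly twice per block, shuffled
within block. Defaults are the standard design — 8 blocks, baseline
contrast 10%, levels 11.5/13.5/17/25%, hence 16 trials per block and
$\Delta C \in \{\pm1.5, \pm3.5, \pm7, \pm15\}$.

**Decisions.** Choices, confidences and response times come from the
signal-detection model above. Response times follow
$rt = rt_{offset} + rt_{gain}/|c|$ with multiplicative lognormal jitter
(sdlog 0.2) — an inverse confidence law chosen because response time and
confidence are inversely correlated; its exact form is a package choice,
and $|c|$ is floored at 0.05 to keep RTs finite. Disagreements are
resolved by the configured group rule; under WCS the member with larger
$|c|$ always prevails, which is the exact sign algebra the leadership
analyses rely on.

**Trajectories.** One per disagreement trial, at 100 Hz (the logging rate
is a package choice; nothing downstream depends on it). The Leader starts
a minimum-jerk reach towards the winning side at
$rt_{offset} + rt_{gain}/|c|$ (earlier when confident), with force
amplitude $0.35(1 + 0.35|c|)$ N scaled by its velocity profile. The
Follower first moves and pushes towards its own choice (excursion
$\min(0.5, 0.15 + 0.12|c|)$, force ramping up over 0.5 s and sustained),
keeps resisting until `follower_yield_delay` (default 0.9 s) after its
own onset, then relaxes and is carried. The two handles are coupled
compliantly, $x_i = u_i + \lambda(u_{other} - u_i)$ with
$\lambda = \tfrac12 k/(k + 10) < 1/2$ and default stiffness
$k = 40$ N/unit; the displayed cursor is the exact mean of the two
handles, and $\lambda < 1/2$ preserves their ordering. Perfectly rigid
coupling is the $\lambda \to 1/2$ limit, in which the two handle series
coincide and the leader/follower velocity contrast degenerates — the
compliant default is what makes that analysis non-degenerate, and it is
exposed as a parameter because the device description (identical
interfaces) and the cursor description (average of trajectories) pull in
different directions. Smooth motor noise (8-sample moving average of
white noise, sd 0.01) is added per handle. A trial ends after the slower
of the two reaches completes plus a 1 s validation hold with the combined
cursor inside $|x| \ge 0.9$ of the winning side; 0.9 is the package's
validation-zone choice.

These defaults were chosen once so that the generator exhibits the
qualitative signatures the analyses are meant to detect — leaders apply
higher peak force and positive work while followers' mean work is
negative, first-crossing accuracy grows with the threshold, and the
leader's early pace is the better match to the dyad's completion pace.
The generator emulates none of the things that make real data hard:
no lapses or attention drift, no force saturation or display feedback, no
learning across blocks, no inter-trial dependencies, and its trajectory
law is one smooth family rather than the variety of real negotiation
styles. Passing tests therefore certify the *analysis chain* — that each
estimator recovers what the generative model put in — not that human
dyads behave like the generator.

## Haptic feature extraction

`first_crossing()` returns the earliest sample at which either handle
leaves $[-X_{thresh}, +X_{thresh}]$; positions are normalised so start =
0 and the response sides are $\pm1$, so a threshold of 0.05 means 5% of
the start-to-target excursion. Simultaneous exits at one sample are
broken by larger absolute displacement, then lower member index. The
threshold sweep reported by `predictor_accuracy()` is
$\{0.05, 0.08, 0.10, 0.15, 0.20, 0.25, 0.30\}$.

`mechanical_work()` is exactly the per-sample-normalised sum
$W = \frac1N \sum_k F_k (X_k - X_{k-1})$ with $N$ the number of summed
increments — all increments of the group phase, not only moving samples
(the alternative normalisation is not what the printed formula says).
`peak_force()` uses the absolute magnitude $\max_k |F_k|$, since "highest
applied force" carries no sign convention.

`velocity_ratios()` splits each trajectory at the first crossing of a
reference threshold (default 0.05, the smallest of the sweep, since the
segmentation threshold is not otherwise pinned down) and compares mean
absolute velocities: leader and follower handles before the crossing,
the combined cursor after it. Whether the member velocities should come
from the individual handle series or from the common cursor grouped by
leader identity is genuinely ambiguous, so both are exposed via
`member_series = c("individual", "common")`; the individual mode is the
default and requires compliant coupling.

## Cohort statistics

`compare_dyad_vs_best()` runs the paired one-sample t-test of
$s_{dyad} - s_{max}$ within a similarity class ($df = n - 1$, matching
the paired design); a constant-zero difference vector returns $t = 0$,
$p = 1$ rather than an error, so exactly-null cohorts behave. Unpaired
comparisons are out of scope here; any that were added would use the
Welch correction. No multiple-testing correction is applied — the
reported p-values are raw, and each test reports its own $n$ explicitly
because class sizes differ between cohorts. `run_pipeline()` wires
everything together and is deterministic from one integer seed; every
random quantity in the package is drawn from the single R session stream
that the seed initialises.

## Problem sizes used by the test suite

The suite checks parameter recovery on a $3\times3$ grid of member noise
levels ($\sigma \in \{4, 6, 9\}^2$) at 30 blocks per cell, against
3-standard-error bands from the observed information. The directional
cohort checks use 14 similar-sensitivity dyads and 5 different-sensitivity
dyads at 20 blocks per dyad: a power analysis of the simulator showed the
similar-class advantage is then reliably significant at $\alpha = 0.05$,
while 5 dyads give little power for the different-class deficit, which is
therefore asserted directionally (negative mean and t) — the same
asymmetry the small different-class sample produces in practice.
Monte-Carlo checks of choice rates use $10^5$ draws against
3-binomial-SE bands.

## Known limitations

* The generator's leadership signatures are built in by construction;
  effect *sizes* (forces in newtons, work in joules) are on the
  generator's own scale and are not calibrated to any recording.
* Single-session $\sigma$ estimates carry ~17–28% relative SE (see
  above); per-dyad classifications near the 0.4 boundary are
  correspondingly unstable.
* The trajectory model has a single yield event; real negotiations with
  repeated reversals would need a richer controller, and features such as
  frequency-domain negotiation measures are out of scope.
* No hierarchical fitting across dyads: each psychometric function is fit
  independently.
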