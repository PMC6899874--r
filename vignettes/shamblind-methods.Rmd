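---
title: "Methods: time-resolved sham-blinding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved sham-blinding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shamblind)
```

## The problem

Sham-controlled transcranial direct current stimulation (tDCS) studies rely
on the placebo protocol being perceptually indistinguishable from active
stimulation.  The usual sham delivers the same ramp-up and ramp-down as the
active protocol but holds the current for only a few tens of seconds, so
that the initial scalp sensations are present in both conditions.  Whether
this actually blinds participants is usually assessed retrospectively (an
end-of-study guess), which confounds perception with memory.  This package
implements a *time-resolved* assessment: the participant is probed every 30
seconds during the task ("Is the stimulation on?" and "How sure are you?",
0--10), and the analysis asks at which times the active and sham conditions
become distinguishable at the group level.

The default protocols are a 30 s ramp-up + 600 s plateau at 1 mA + 30 s
ramp-down (active, 660 s of current) and 30 s + 20 s + 30 s (sham, 80 s),
probed 32 times over a 960 s task; the first probe falls at 30 s, the
moment both protocols reach full intensity.

## Weighted detection scores and bootstrap bands

Each probe response is collapsed to a signed score
$s = (\pm 1)\,c$, with $+1$ for "yes (it is on)", $-1$ for "no", and
$c \in [0, 10]$ the confidence: $+10$ means certainty that the current is
on, $-10$ certainty that it is off, and $0$ complete uncertainty either
way.  Missing probes (the response window can lapse) propagate as missing
scores rather than zeros, because $0$ means "answered, maximally unsure".

For each condition and probe time the package reports the group **median**
score with a **percentile bootstrap** confidence interval: participants are
resampled with replacement `n_boot` times (default 5,000), the median is
recomputed for each resample, and the interval is read off the empirical
quantiles of those medians at $(1-\text{level})/2$ and
$1-(1-\text{level})/2$ (default level 0.95, type-7 quantiles).  The
implementation draws multinomial resample counts and reads the median off
the sorted sample with matrix arithmetic, which is distributionally
identical to naive resampling but vectorised.  Missing scores shrink that
probe's resampling pool; a probe with fewer than two usable scores is
flagged and gets no band.  Bias-corrected (BCa) intervals are deliberately
not used: the analysis totals below are defined on plain percentile bands.

Reproducibility: one seeded RNG stream per condition (streams `seed`,
`seed + 1`, ... in alphabetical condition order) with probes processed in
time order, so a fixed seed reproduces every band bit for bit.

## Distinct windows and the headline percentage

A probe time is *distinct* when the two conditions' intervals do not
intersect.  Runs of consecutive distinct probes on the 30 s grid are merged
into windows spanning the first to the last probe of the run; an isolated
distinct probe therefore contributes zero seconds.  With this convention,
distinct probes at 120--360 s, 480 & 510 s, and 660 & 690 s merge into
three windows totalling $240 + 30 + 30 = 300$ s.

The total is expressed as a percentage of the difference in total
current-on time between conditions, *ramps included*:
$660 - 80 = 580$ s by default, so 300 s corresponds to 51.7%.  Note the
denominator convention matters when quoting the percentage: a plateau-only
denominator ($600 - 20 = 580$ s here, coincidentally equal) or one that
excludes half-ramps would give different figures for other protocols; this
package always uses the ramp-inclusive difference and errors when it is
not positive.

No multiplicity correction is applied across the 32 probe comparisons; the
windows are descriptive, not a family of tests.

## Per-participant logistic crossover fits

An individual-level alternative is to fit, per participant and session, a
binomial logistic regression of the yes/no answers on probe time and read
off the time at which the fitted "yes" probability crosses 1/2
($-\beta_0/\beta_1$).  Individual response sequences are often unsuitable
for this model — participants switch between yes and no more than a
monotone curve allows — so every fit carries an explicit failure reason:

* `degenerate_responses`: all answers identical (no crossover exists);
* `nonconvergent`: the IRLS fit did not converge;
* `non_monotone`: the slope is indistinguishable from zero at `alpha`;
* `crossover_out_of_range`: the estimate falls outside the task window
  (default 0--960 s);
* `ok` otherwise.

The slope test uses the **likelihood ratio**, not the Wald statistic: a
cleanly separated step response (yes until some time, no afterwards — the
best case for this analysis) has an unbounded slope estimate and a useless
Wald standard error, while its likelihood ratio against a flat model is
decisive, and the crossover estimate $-\beta_0/\beta_1$ converges to the
midpoint of the separating gap.  Alternating responses are correctly
flagged `non_monotone` either way.

## Reaction-time pipeline

The forced-choice task yields 100 baseline trials (Block 1, pre-stimulation,
200 s at the nominal 2.0 s trial cycle) and 320 in-task trials in 32
sub-blocks of ten.  Sub-blocks 1--11 form Block 2, 12--22 Block 3 (the
second half of stimulation under the active protocol), and 23--32 Block 4
(post-stimulation); Blocks 2 and 3 together hold the 220 trials delivered
during active stimulation.

Per participant, condition and block, the median reaction time of
*correct, responded* trials is computed (no outlier trimming; trials
without a response are excluded from medians and counted as errors for
accuracy).  Baseline-corrected deltas
$\Delta\text{RT}_b = \tilde{RT}_b - \tilde{RT}_1$ are compared between
conditions with one-tailed paired $t$-tests, directional for anodal
facilitation (differences taken as sham $-$ active, alternative
mean $> 0$).  Cohen's $d_z = \bar d / s_d$, so $t = d_z\sqrt{n}$ exactly.

Baseline equivalence uses the two one-sided tests (TOST) procedure with
bounds on the $d_z$ scale: $t_\text{lower} = (d_z + b)\sqrt{n}$ and
$t_\text{upper} = (d_z - b)\sqrt{n}$ on $n - 1$ degrees of freedom, with
the TOST $p$ the larger of the two one-sided $p$-values; equivalence is
declared when $p < \alpha$.  The default bound $b = 0.4$ excludes a
moderate standardised effect.

Group accuracy is the mean of per-participant accuracies with a percentile
bootstrap interval over participants, and the exploratory sub-block time
course bootstraps the per-sub-block median RT with exactly the same band
and window machinery as the blinding analysis.

## Questionnaire statistics and power

Side-effect ratings (headache, tingling, itching, burning, pain; ordinal
1--5 per session) are compared with Wilcoxon signed-rank tests: zero
differences discarded (the classical treatment, not Pratt's), midranks for
ties, and either (a) a $z$ statistic from the normal approximation with
tie-corrected variance and no continuity correction — the form
conventionally reported for such questionnaires — or (b) the exact
two-sided $p$ by full enumeration of the $2^m$ sign assignments, feasible
for $m \le 16$ effective pairs.  The default (`method = "auto"`) uses the
exact enumeration whenever it is feasible, because the normal
approximation is coarse for small $m$: by complete enumeration its error
can reach 0.035 at $m = 5$ even without ties, and far more when the
ordinal differences are heavily tied.  No correction is applied across the
five scales; report accordingly.

The end-of-study sham guess is summarised as a proportion with an exact
one-sided binomial test against 0.5 ("above chance" is directional).

Design power for the paired $t$-test uses the noncentral $t$ distribution
with noncentrality $d\sqrt{n}$; `required_sample_size()` iterates $n$
upward until the target power is reached.  For $d = 0.45$, one-tailed,
$\alpha = 0.05$, power 0.8, this gives $n = 32$ (achieved power 0.8008;
0.789 at $n = 31$).

## The synthetic cohort generator

The generator exists so that every stage of the pipeline runs, and can be
tested, without any experimental data.  It emulates a 32-participant,
two-session, counterbalanced crossover (participants alternate
active-first/sham-first by index) with the probe and trial structure above.
It is a *minimal* perceptual model — enough to produce the qualitative
group-level time course, with no claim to mechanism.

**Detection.**  A latent salience $s(t)$ is 1 during the ramp-up, decays
exponentially during the plateau with half-life
`desensitization_halflife_s` (default 300 s: scalp desensitisation leaves
the group drifting toward uncertainty by roughly five minutes of sustained
stimulation), holds its plateau-end level through the ramp-down
(desensitisation does not reset while the current falls), and afterwards
collapses as $s_\text{end}\,(1 - (u/P)^3)$ over the persistence window
$P$ = `persistence_s` (default 30 s).  The cubic shape encodes
hold-then-collapse: the lingering sensation is still almost fully salient
at the first probe after sham current-off (10 s in, $s \approx 0.96\,
s_\text{end}$) and gone by the next (40 s in), which is what makes the
probe at 90 s still read "on" in both conditions while the 120 s probe
separates them — a linear fade cannot produce both.  The probability of
answering "yes" is $p_\text{off} + (p_\text{on} - p_\text{off})\,s(t)$
(defaults 0.95/0.05); confidence is truncated-normal on $[0, 10]$ centred
at 8 ("yes") or 7 ("no") with SD 1.5, plus a per-participant anchoring
offset (SD 1.5) reflecting that raters use the 0--10 scale differently —
without it, group bands are unrealistically tight.  A small fraction of
probes (1%) lapse unanswered.

**Reaction times.**  Log-normal with median 430 ms and within-participant
log-SD 0.18 (within-trial spread ≈ 78 ms), a participant random intercept
of log-SD 0.13 (between-participant spread of baseline medians ≈ 57 ms), a
practice trend of $-2$ ms per block position across the eight blocks of
the two sessions, accuracy 0.956 per trial and a 0.005 no-response rate.

**Anodal effect calibration.**  `anodal_dz` is defined as the *true*
standardised effect of the paired active-vs-sham contrast of Block-3
$\Delta$RT medians.  The generator converts it to a mean additive speed-up
applied to active Blocks 2--3 using an analytic standardiser:
$\sigma_D^2 = \tau_a^2 + 2\,(v_{3} + v_{1})$, where $\tau_a$ =
`anodal_sd_ms` (default 35 ms, between-participant variability of the
stimulation response, which dominates) and $v_b = \pi\sigma^2 m^2
e^{2\tau^2} / (2 n_b)$ is the asymptotic sampling variance of a log-normal
sample median over the expected number of correct trials in block $b$.
Simulation confirms the realised $d_z$ matches the request to well under
1% at the defaults, so recovery tests (e.g., 80% one-tailed power at
$d_z = 0.45$, $n = 32$) probe the analysis, not the calibration.

**Questionnaires.**  Ratings are drawn from a common ordinal distribution
(probabilities 0.45/0.30/0.15/0.07/0.03 for 1..5), with the active-session
itching rating shifted up one category (capped at 5) — itching is the
sensation most reliably elevated by sustained stimulation.  The sham guess
is correct with probability 25/32 (the blinding-failure rate the design
anticipates); guess confidence is truncated-normal on $[1, 10]$.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: expectation and priming effects,
submodality time courses (tingling vs burning), serial dependence or
idiosyncratic switching in probe answers (each probe is an independent
Bernoulli draw given $s(t)$), probe timing locked to trial onsets (the
30 s grid is taken as exact), session-order effects on detection, and any
relation between guess confidence and accuracy.

## Numerical choices and degenerate inputs

* Percentile intervals use type-7 quantiles of the bootstrap medians.
* Bands need $\ge 2$ usable scores; thinner probes are flagged, carry no
  interval, and are treated as overlapping (non-distinct) — a conservative
  choice for window totals.
* Window merging treats probes as consecutive when separated by the
  smallest grid step; totals are sums of first-to-last spans, so widening
  any interval can only shrink the total.
* Zero-variance paired differences make $t$ (and TOST) undefined and
  raise an error rather than returning 0/0.
* All-equal ratings make the signed-rank test undefined and are flagged.
* The percentage of stimulation-time difference errors when the two
  protocols deliver equal current-on time.
* A sham-guess table with no rows errors; missing probe answers are never
  imputed.

## Problem sizes used by the test suite

The statistical property tests run at sizes chosen to keep Monte-Carlo
error well inside the asserted bands: 2,000 replicate draws (bootstrap
coverage at $n = 32$, with 2,000 resamples per interval), 5,000 replicates
per bound for the TOST size check, 2,000 generated cohorts for the power
recovery check, and 20 seeded end-to-end runs for the qualitative
time-course structure.  The full suite completes in a few minutes on one
CPU.

## Known limitations

* The perceptual model is homogeneous across participants except for the
  confidence anchoring offset; it does not generate the
  individual-response heterogeneity that defeats per-participant logistic
  fits in real data (the crossover failure taxonomy is exercised with
  constructed patterns instead).
* The normal-approximation signed-rank $p$ is inaccurate below about ten
  effective pairs; use the exact method there (the default does).
* Percentile bootstrap bands for a median at $n = 32$ undercover slightly
  (~94--95% at nominal 95%); the coverage test asserts the 93--97% band.
* The analysis treats the two conditions' bands independently per probe;
  no correction is made for the 32 comparisons, matching the descriptive
  intent of the window summary.
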