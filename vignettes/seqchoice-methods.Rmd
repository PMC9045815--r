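---
title: "Models and methods behind seqchoice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seqchoice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqchoice)
options(seqchoice.verbose = FALSE)
```

## The scientific problem

When a monkey chooses between two juices offered in variable amounts, its
choices define a relative value: the quantity ratio $q_B/q_A$ at which it
is indifferent between juice A (preferred) and juice B. When the two
offers appear in sequence instead of simultaneously, three behavioral
phenomena appear: choices become less accurate (shallower choice
sigmoid), they tilt toward the second offer (order bias), and they tilt
toward the preferred juice by an amount that grows with the relative
value itself (preference bias). Orbitofrontal cortex (OFC) carries
signals for the individual offer values, the chosen juice and the chosen
value, which makes it possible to ask *at which computational stage* each
bias arises: valuation, value comparison, or later. This package
implements that entire analysis chain — behavioral model fitting,
neuronal classification, cross-task tuning comparisons, neuronal
relative-value readouts, circuit inhibition, and choice probability —
together with a synthetic-data generator that emulates sessions and
spike trains with known ground truth, so every stage is testable without
any recorded data.

## Choice models

Each session interleaves two tasks (simultaneous vs sequential offers)
with a common offer-type set. Choices are fit per task with a probit
regression on the log quantity ratio:

$$\text{choice B} \sim \Phi(X), \qquad
X = a_0 + a_1 \log(q_B/q_A) \quad (\text{task 1})$$

$$X = a_2 + a_3 \log(q_B/q_A) + a_4(\delta_{AB} - \delta_{BA})
\quad (\text{task 2})$$

i.e. two parallel sigmoids for the two presentation orders. Derived
measures: relative value $\rho = \exp(-a_0/a_1)$, sigmoid steepness
$\eta = a_1$, order bias $\varepsilon = 2\rho_{T2}\,a_4/a_3$, and
order-specific relative values $\rho_{AB} = \exp(-(a_2+a_4)/a_3)$,
$\rho_{BA} = \exp(-(a_2-a_4)/a_3)$, so that $\varepsilon \approx
\rho_{BA} - \rho_{AB}$ to first order in $a_4/a_3$. Logit links and a
value-difference regressor ($X = a_0 q_A + a_1 q_B$) are provided as
robustness variants and compared by BIC; derived relative values from
probit and logit are nearly identical in rank.

Implementation notes:

* Fits use `stats::glm` (binomial family) on per-trial data; forced
  choices (one offer null) are excluded from log-ratio fits because the
  log is undefined at zero, and retained in value-difference fits.
* Standard errors of the derived measures come from the delta method
  with numerically differentiated gradients of each transform.
* Complete or quasi-complete separation (choices perfectly ordered by
  the regressor) is detected by non-convergence or coefficients
  exceeding 50 in magnitude; such fits are flagged and carry no derived
  measures, and sessions flagged this way are excluded downstream rather
  than aborting the batch.
* $R^2$ for binary models is McFadden's pseudo-$R^2$.
* Session stability is enforced with the Tukey rule: sessions whose
  fitted steepness falls outside quartiles $\pm$ 1.5 IQR (type-7
  quantiles; a zero IQR excludes nothing) are dropped from population
  analyses. The same rule screens outliers before population
  correlations elsewhere.

The preference bias is quantified across sessions by an ANCOVA of
$\{\rho_{AB}, \rho_{BA}\}$ on $\rho_{T1}$ with the order as covariate
and parallel lines imposed: a common slope $> 1$ is the preference bias
(the task-2 inflation grows with $\rho$), a positive intercept
difference (BA above AB) is the order bias. The preference bias index
$\mathrm{PBI} = 2(\rho_{T2}-\rho_{T1})/(\rho_{T2}+\rho_{T1})$ summarizes
the inflation per session independent of the juice pair.

## Neuronal responses and classification

A *trial type* is (quantities, choice) in task 1 and (quantities, order,
choice) in task 2; a *neuronal response* is one cell's mean firing rate
per trial type in one time window. Windows are 0.5 s anchored at task
events (task 1: post-offer, late-delay, pre-juice, post-juice; task 2:
post-offer1, post-offer2, post-juice). Cells pass a task-relatedness
screen — one-way ANOVA (factor: trial type) at $p < 0.01$ in at least
one window of either task; trial types with a single trial are kept for
response means but excluded from the variance test.

Classification regresses each response on candidate decision variables
(values expressed in units of juice B via the session's behavioral
$\rho$) and accumulates the signed explained variance
$sR^2 = \mathrm{sign}(b_1) R^2$ (zero when the slope is not significant
at 0.05) across windows. Task 1 uses four variables (offer value A/B,
chosen juice, chosen value); task 2 uses eight window-specific variable
*sequences* (e.g. the offer value A sequence is offer value A|AB,
offer value A|BA, chosen value A across the three windows; the chosen
juice A sequence is AB|BA+, AB|BA−, chosen juice). A window's
contribution to a sequence is its $sR^2$ times the sequence's predicted
sign, so contradictory encoding subtracts; this makes the task-1 and
task-2 scores structurally parallel, and the joint classification simply
adds the two aligned scores of each candidate and takes the maximum
positive total (ties, which have measure zero, break by a fixed priority
order and are logged). Cells with no positive score are untuned.

Two candidates deserve a caveat: in sessions where one juice is chosen
almost always, *chosen value* and the dominant juice's *offer value*
coincide on nearly every trial type, and in task 2 the domain-restricted
offer value variables cannot be penalized for the trial types they do
not cover. Classification accuracy on labeled synthetic populations is
~97–99% overall, with the residual errors exactly in this confusable
pair — an identifiability limit of the design, not of the estimator, and
the reason experimenters pick offer ranges that split choices.

## Tuning comparisons across tasks

Tuning is the OLS line $r = b_0 + b_1 S$ through a response's trial-type
means, with $S$ the encoded variable. With $S_{max}$ the session maximum
of $S$, the mean activity is $r_{mean} = b_0 + b_1 S_{max}/2$ and the
activity range is $\Delta r = |b_1 S_{max}|$. A tuning is significant
when the slope is ($p<0.05$) and its sign matches the cell's class. The
cross-task analyses pair each offer value cell's task-1 post-offer
tuning with its task-2 post-offer1 and post-offer2 tunings (two
observations per cell, as in the scatter analyses), compare $r_{mean}$
and $\Delta r$ by paired t and Wilcoxon tests, and correlate the range
change $\Delta r_{T2} - \Delta r_{T1}$ with the session's steepness
change $\Delta\eta$. The EO/OE analysis compares each cell's response to
its encoded juice offered first (post-offer1) versus second
(post-offer2), the signature that would implicate valuation in the order
bias; under the default generator it is null by construction and the
pipeline reproduces the negative result.

Because regressions run on unweighted trial-type means (the field's
convention, which we keep), types with very few trials contribute
heavy-tailed noise to per-cell $\Delta r$; population tests on small
cell counts inherit that, which is why the package's own validation
asserts the cross-task null on effect size rather than on a single
p-value.

## Neuronal measures of relative value

Chosen value cells encode value independent of juice identity, so their
coefficients expose the internal value ratio. Task 1 (post-offer):
$r = \theta_0 + \theta_A q_A \delta_{choice,A} + \theta_B q_B
\delta_{choice,B}$ gives $\rho^{neuronal} = \theta_A/\theta_B$. Task 2:
two bilinear fits in the post-offer1/post-offer2 windows (the value on
display, split by order) give $\theta_{1A}, \theta_{1B}, \theta_{2A},
\theta_{2B}$ and four measures $\rho_{offer1} = \theta_{1A}/\theta_{1B}$,
$\rho_{offer2} = \theta_{2A}/\theta_{2B}$,
$\rho_{AB} = \theta_{1A}/\theta_{2B}$,
$\rho_{BA} = \theta_{2A}/\theta_{1B}$, valid only when all four slopes
are individually significant (ratios of noisy near-zero coefficients are
meaningless). The identity $\rho_{AB}\rho_{BA} =
\rho_{offer1}\rho_{offer2}$ holds exactly by construction and is asserted
to machine precision. $\Delta\rho^{neuronal} = \rho_{BA} - \rho_{AB}$ is
the neuronal analogue of the order bias and is correlated with
$\varepsilon$ across cells; $\rho_{BA}$ vs $\rho_{AB}$ is summarized by a
Deming regression (equal error variances on both axes — the conventional
default when no variance ratio is stated).

The scenario analysis asks whether the preference bias exists already in
the values (scenario 1) or arises downstream (scenario 2): it compares
$\rho^{neuronal}_{T2}$ (taken as $\rho_{offer2}$, configurable) with the
behavioral measures of both tasks by paired tests and by regressions
with slope-equal-1 tests. The inference rule is: the neuronal measure
must differ significantly from one behavioral measure and align with the
other; if both paired tests reach significance (ratio estimators carry a
small finite-sample bias), alignment goes to the reference with less
than half the other's gap. On synthetic populations the pipeline
separates the two scenarios with power above 0.9 at 12 sessions of 3
cells.

## Chosen juice cells: circuit inhibition and choice probability

Spike trains are smoothed, for display purposes only, with a causal
exponential kernel mimicking a postsynaptic potential (decay constant
20 ms, unit area, influence only forward in time); the quantitative
analyses below use raw counts.

*Circuit inhibition.* For each chosen juice cell, E is the juice
eliciting the higher post-juice rate (ties toward juice A, logged). In
OE trials — the other juice offered first — the firing rate in a 300 ms
window starting 250 ms before offer2 onset is regressed on the
normalized offer1 value, $r = c_0 + c_1 V(O)/\Delta V_O$, forced
choices excluded; $\Delta V_O$ is the session value range of juice O, so
cells recorded with different ranges pool. Negative $c_1$ is circuit
inhibition — the decision circuit's initial condition. Population tests
(t and Wilcoxon, after IQR screening) ask whether mean $c_1 < 0$, and
$c_1$ is correlated with $\varepsilon$ across cells.

*Choice probability.* Within each split-choice offer type of the OE
trials (types with fewer than 2 trials of either outcome excluded), an
ROC analysis compares the spike-count distributions for E-chosen vs
O-chosen trials; the AUC is computed by the rank-sum identity
$\mathrm{AUC} = U/(n_1 n_2)$ with midrank ties (each tied pair counts
0.5) — required for integer counts — and validated exhaustively against
a brute-force concordant-pair oracle. The cell's CP is the unweighted
mean AUC across qualifying offer types (a trial-weighted variant is
available), computed on a 100 ms/25 ms sliding grid and in four fixed
250 ms windows: pre-offer1 (control), late-offer2, early-wait, and
pre-juice. The late-offer2 and early-wait windows are anchored at offer2
offset, matching their names and their ordering in the trial. CP-PBI
correlations per fixed window test whether sessions with weaker early
commitment (low CP around offer2) carry a larger preference bias.

## The synthetic-data generator

`generate_choices()` inverts the task-2 probit exactly: choices are
drawn with $P(B) = \Phi(\eta[\log(q_B/q_A) - \log\rho_{task}] + a_4
(\delta_{AB}-\delta_{BA}))$ with $a_4 = \varepsilon\eta/(2\rho_{T2})$,
so the fitted $\varepsilon$ recovers the generating one in expectation.
Orders are counterbalanced within offer type, tasks pseudorandomly
interleaved, task-2 trials 1.5 times task-1 trials, forced choices
always take the nonzero offer. The preference bias is a multiplicative
task-2 shift of $\rho$ applied at the choice stage only (scenario 2, the
paper-like default); `scenario = 1` instead shifts the values that drive
task-2 neuronal activity, so the analyses can be shown to discriminate
the two.

`generate_spikes()` draws inhomogeneous Poisson spikes from
piecewise-constant rates: offer value cells are linear in their juice's
value while it is on display (task-2 slopes scaled by `task2_scale`,
default 0.75, emulating the weaker sequential-offer signals, plus a
constant offset that preserves $r_{mean}$ across tasks); chosen value
cells follow the value currently on display and then the chosen value;
chosen juice cells carry binary juice/choice modulation, the
circuit-inhibition offset $c_1 V(O)/\Delta V_O$ during the inter-offer
delay of OE trials, and a linear-in-time divergence toward the eventual
choice starting `cp_onset` after offer2 onset (default +0.05 s, just
after the circuit-inhibition window closes, so the two phenomena are
separable; a ramp reaching $\pm$`cp_sep`/2 over `cp_ramp` seconds).
Negative rates are clipped at zero and logged. An optional
negative-binomial noise toggle supports overdispersion robustness
checks.

Default study conditions (chosen once, as a typical session): $\rho$
around 2.5 (population draws uniform on [1, 4]), $\eta_{T1}$ 3–6,
$\eta_{T2}$ 1.5–4, $\varepsilon$ centered positive, preference shift
1.1, 240 task-1 trials (~600 total), baseline 6 sp/s, tuning slope
1.5 sp/s per value unit (negative-encoding cells get a baseline raised
above slope times the session value range so rates do not clip). Offer
sets in `generate_population()` are adapted per session so that the
log quantity ratios straddle that session's indifference point — exactly
what the experimenters do when picking quantity ranges — which keeps
choices split on several types at any $\rho$; a fixed default set is
also exported.

What the generator does *not* emulate: rate autocorrelation and Fano
factors above 1 (Poisson by default), range adaptation within session,
choice hysteresis, reaction times, eye movements, and any biophysics of
the decision circuit. Passing tests therefore validate the estimators
and the pipeline logic under the stated statistical structure, not the
neural dynamics of real OFC.

## Validation scales and numerical choices

The test suite validates, at desk scale: Wald-interval coverage for
$(\rho, \eta, \varepsilon)$ on 200 sessions (observed 90–97%); the
$\varepsilon \approx \rho_{BA}-\rho_{AB}$ identity below 5% relative
error whenever $|a_4/a_3| < 0.1$; ANCOVA power at 100 sessions
(preference shift 1.15, $\varepsilon$ 0.3) with nulls at the nominal
rate; joint-classification accuracy $\ge 95$% on 200 labeled cells at
reference SNR; recovery of all four task-2 relative-value measures
within 10% median relative error at $\rho = 2.5$ with ~20 trials per
trial type, plus the exact product identity; exhaustive AUC-oracle
agreement over all count multisets on $\{0,1,2\}$ up to size 6;
unbiased $c_1$ recovery at $c_1 \in \{-2,-1,0\}$ with ~200 usable
trials per cell; and scenario discrimination power $\ge 0.8$ over
replicate populations. One quantity falls honestly short of its
nominal mark: the median $|\hat\varepsilon - \varepsilon|$ at ~600
trials/session measures ~0.11–0.12. That is the Fisher-information
limit of the design ($SE(a_4)\approx 0.1$ from ~290 usable task-2
trials, inflated by $2\rho/\eta$), not an estimator defect — the
coverage results confirm the intervals are calibrated — and roughly
twice the task-2 trial count would be needed to push it below 0.1.

Numerical conventions: GLM convergence at $10^{-8}$ on the deviance
with at most 100 iterations; quantiles type 7 everywhere; degenerate
regressors (constant within domain) yield $sR^2 = 0$ with a log rather
than an error; empty or single-order inputs raise errors; every
exclusion (outlier session, unclassified cell, skipped trial type,
failed ROC) is logged to standard error with a reason.
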