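---
title: "Learning and auditing electrolyte repletion policies offline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning and auditing electrolyte repletion policies offline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

repleteRL learns when, by which route, and at what dose to replete potassium,
magnesium or phosphate in critically ill patients, from retrospective EHR data
alone. This vignette is the package's own account of the model, the
estimators, and the design choices behind them: what is assumed, what the
defaults mean, and what the synthetic experiments do and do not demonstrate.

## The decision problem

Repletion is modeled as a Markov decision process sampled at 6-hour decision
points, the cadence at which ICU staff can realistically act on a
recommendation. At each point the patient occupies a continuous state
$s \in S$ — a named numeric vector of static attributes, binned vitals and
labs, and indicators of medications given in the prior interval — and the
clinician (or policy) chooses one discrete action $a \in A$ from an
electrolyte-specific catalog: no repletion, one of three oral dose levels, one
of the IV dose-and-infusion-duration entries (six for K, four for Mg, three
for P), or any oral+IV combination. Catalog sizes are therefore 28 (K), 20
(Mg) and 16 (P).

Feedback is a four-term penalty evaluated on the transition
$(s, a, s')$:

$$ r = -\big(w_{iv}\,\phi_{iv} + w_{po}\,\phi_{po} +
        w_{high}\,\phi_{high} + w_{low}\,\phi_{low}\big) $$

where, in the default *indicator* form, $\phi_{iv}$ and $\phi_{po}$ flag an
IV or PO component in $a$, and $\phi_{high}$, $\phi_{low}$ flag the next
electrolyte level falling above or below the reference range. With
non-negative weights normalized to unit L1 norm, rewards live in $[-1, 0]$
and the weights read directly as relative priorities. A *graded* form
(penalty proportional to the distance from the nearest range endpoint) is
available behind `mdp_spec(reward_form = "graded")` for sensitivity analyses;
it is not the default because it changes the interpretation of the weight
vector and the indicator form is the simplest model consistent with a
four-condition weighted sum.

The discount factor defaults to $\gamma = 0.9$. Stays are capped at eight
days, i.e. at most 32 decision points; at $\gamma = 0.9$ the effective
horizon ($1/(1-\gamma) = 10$ intervals, 2.5 days) matches the time scale on
which a repletion decision can plausibly influence electrolyte trajectories.
Sensitivity of learned policies to $\gamma \in \{0.75, 0.9, 0.99\}$ is an
exercise for the user; nothing in the machinery assumes a particular value
below 1.

Default reference ranges are K 3.5–5.0 mEq/L, Mg 1.7–2.3 mg/dL,
P 2.5–4.5 mg/dL. They are configuration, never hard-coded: institutions
differ, and every estimator takes them from `mdp_spec()`.

## From raw tables to transition samples

The ingestion contract is three long-format tables: per-visit statics,
timestamped observations, timestamped medication administrations. Cohort
selection keeps adults (age > 18) with stays of one to eight days, at least
one value of each required variable, an admission weight, and at least one
repletion event of the target electrolyte; each excluded visit is attributed
to the first failed filter in that order, so the exclusion report is a
well-defined funnel (the attribution order is a package convention — the
funnel is otherwise ambiguous).

Visits are divided into half-open 6-hour bins $[6k, 6(k+1))$. Within a bin,
measurements outside the variable's clinical plausibility bounds are
discarded, and the mean of the survivors represents the interval. Missing
cells are filled by last-observation-carried-forward for up to 48 h,
measured from the bin in which the value was genuinely observed — not from
the last carried copy, which would allow unbounded carry chains — and by the
population mean afterwards. Population means default to train-split-only
means in the pipeline. The observed/imputed mask is preserved so that
descriptive analyses (pre/post-repletion distributions) never mistake
imputed fill for measurements.

Medication rows are assigned to the bin containing their start time: an
order placed in an interval is the action taken at that decision point.
Free-form doses are snapped onto the catalog grid — PO by nearest dose, IV
by nearest dose then nearest duration, ties always toward the lower level,
same-route rows within a bin summed before snapping.

Each consecutive bin pair yields one
$\langle s, a, r, s' \rangle$ sample; the final bin emits a terminal sample
whose regression target is its reward alone (no bootstrap). A terminal
sample's range penalty is evaluated at its own (final observed) level, a
convention needed because no later level exists.

## Fitted Q-iteration and fitted-Q evaluation

`fqi()` learns the optimal Q-function by iterated regression on the fixed
batch: iteration 1 fits $y = r$; iteration $k$ fits
$y = r + \gamma \max_{a'} Q_{k-1}(s', a')$. The regression input is the
state vector concatenated with a one-hot action encoding, so one model
serves the whole catalog; with rare actions this shares strength across the
action space, which matters for catalogs where most combination actions are
seldom logged. `fqe()` uses the same machinery with
$y = r + \gamma \hat Q_{k-1}(s', \pi(s'))$ to value a *fixed* policy;
evaluating logged behavior substitutes the recorded next action for
$\pi(s')$.

The function approximator is pluggable (`regressor_spec()`): gradient-boosted
trees (default), a randomized-tree ensemble, or exact tabular averaging. The
boosted-tree default was chosen for its single-threaded prediction speed —
every FQI sweep predicts the full catalog at every next state — with
identical contracts across back-ends. The tabular regressor predicts the
training-target mean for seen input rows and 0 for unseen ones; on a finite
MDP with full state-action coverage this makes FQI *exactly* empirical value
iteration, which the test suite exploits by comparing against an independent
dynamic-programming oracle on enumerable MDPs (20 random MDPs with
transition probabilities in eighths, sample multisets matching the
transition law exactly, agreement required to 1e-6).

Greedy action selection breaks exact ties by catalog order, which places
NONE first: on indifference the policy does not treat. Recommendations are
decoded hierarchically (treat? → route → dose/duration) from the flat
argmax, with all per-action Q-values exposed for audit; a per-step variant
(three separately learned models) would be a possible extension but the
flat-then-decode readout keeps a single value function to validate.

## Inverse RL: estimating what drove behavior

`irl_weights()` estimates the four reward weights under which observed
behavior looks optimal, by discounted feature-expectation matching. The
behavior's feature expectations $\mu_E = E[\sum_t \gamma^t \phi_t]$ are
computed directly from held-out logged trajectories. Candidate policies'
feature expectations are estimated model-free by one FQE per penalty
component, read off at initial states — rather than by simulator rollouts,
so the estimator also applies to real data whose dynamics cannot be
simulated.

The weight update is the max-margin rule: each outer iteration reports the
direction $w$ (unit ball) under which the behavior dominates every candidate
policy found so far by the largest margin, solved exactly in the 4-feature
space as the minimum-norm point of the convex hull of
$\{\mu_E - \mu_j\}$ (Frank–Wolfe with exact line search). Solving the
induced MDP under the proposal adds a new candidate, and the loop stops when
a candidate matches $\mu_E$ within tolerance or the budget is exhausted. We
use the max-margin rather than the projection variant of feature matching
because the quantity reported *is* the weight vector: the projection
residual $\mu_E - \bar\mu$ collapses to estimation noise precisely when the
algorithm succeeds, whereas the last separating direction remains a
well-defined estimate when the candidate hull reaches the behavior point.
Signs are unconstrained — historical behavior can and does resolve to small
negative cost weights — and the output is L1-normalized.

Identifiability caveats, flagged in diagnostics rather than hidden: behavior
with (near-)zero feature expectations carries no signal (`degenerate`), and
logs generated by a *deterministic* policy with no execution noise provide
no overlap, so no model-free off-policy estimator — FQE included — is
identified on them. The simulator's policy rollouts therefore accept an
`explore_prob`: a small probability per decision of an omitted dose or an
unprompted order, the two kinds of noise real clinician logs contain. The
weight-recovery experiment uses 0.2; positivity is a precondition of the
estimator, not a tuning knob of the experiment.

## The synthetic cohort: what it emulates, and what it does not

Real repletion EHRs are access-restricted, so `simulate_cohort()` generates
cohorts with the statistical structure the analysis assumes: irregularly
sampled labs and vitals with configurable missingness, a mean-reverting
electrolyte with additive dose response, a threshold-driven clinician with a
configurable over-repletion tendency, and combination orders recorded as two
medication rows sharing a start time.

The electrolyte follows
$L' = L + \rho\,(\text{setpoint} + \text{drift} - L) + e_{po}\,\text{po} +
e_{iv}\,\text{iv} + \epsilon$. Defaults (for K: setpoint 4.4, drift −0.25,
$\rho = 0.35$, $\sigma = 0.15$, PO effect 0.15 and IV effect 0.25 per dose
level; Mg and P scaled analogously to their units) were fixed by a design
requirement, not by fitting: *"replete only when deficient" must be the
optimal policy under the four-term reward.* That requires (i) admissions to
present deficient — drawn around $\text{setpoint} + 6\times\text{drift}$,
about 2.9 mEq/L for K, so sicker cohorts both run lower and arrive lower;
(ii) recovery without treatment to be slow enough that repletion genuinely
helps (several intervals below range untreated); and (iii) in-range states
to be self-stabilizing, so preemptive repletion buys almost nothing. The
last point fixes the reversion rate: with slow reversion (≈0.1/interval) a
state just above the range floor faces a material chance of dipping below
range next interval, and the optimal policy repletes *preemptively* across a
wide in-range band — defensible physiology, but it inverts the qualitative
pattern the package is meant to detect. At $\rho = 0.35$ the band collapses
to a sliver above the floor and the optimal policy repletes essentially only
when deficient.

The simulated clinician repletes with certainty below a threshold set
slightly *inside* the deficient region (1.5 noise SDs below the range low),
repletes with probability `over_replete_prob` (default 0.3) at or above it,
and picks route and dose independently of severity. This reproduces both
halves of the historical pattern: unprompted repletion at adequate levels,
and untreated mild deficiency.

Non-electrolyte covariates are independent stationary noise around
plausible ICU means. They are nuisance features by construction: their
irrelevance is something the learner must discover, not something the
generator encodes. Consequently, passing tests on this cohort demonstrate
the estimators' correctness and the qualitative behavior of learned policies
under known ground truth; they do not demonstrate transport to real
patients, where covariates confound, dynamics are nonstationary and
deficits are not unidimensional. No simulator output should be read as
reproducing any institution's statistics.

## Numerical conventions and degenerate inputs

Exact greedy ties go to NONE. Dose snapping ties go to the lower level.
Non-finite regression targets abort with the iteration index rather than
propagate. Zero historical repletions make the percent-change in repletion
frequency undefined and it is reported as such. A variable never observed in
a cohort makes its population mean undefined and imputation fails naming the
variable. All randomness flows from explicit integer seeds: cohort
generation, train/test splits, regressor fits; a pipeline run records its
seed and per-stage counts in a manifest, and rerunning a configuration
reproduces the manifest exactly.

Problem sizes used by the shipped experiments (chosen as the smallest that
give stable qualitative answers): 2,000-visit cohorts for policy-behavior
comparisons; 5,000 trajectories for validating fitted-Q evaluation against
Monte-Carlo returns; behavior-policy training cohorts of 600 visits and
five replicate seeds for weight recovery; 20 enumerable MDPs for the
dynamic-programming equivalence checks.

## Costs

`event_cost()` prices one repletion event from a single-rate configuration:
drug cost per route component; ordering and preparation once per event;
route-specific administration and IV monitoring; and an attributed number of
follow-up lab draws (panel price plus phlebotomy time). Combination events
sum their PO and IV route components but order, preparation and labs are
counted once. The shipped `default_cost_model()` contains round illustrative
USD figures; every monetary output of the package is a function of this
configuration, and none reproduces any published institutional total.

## Known limitations

- The learned policy's quality on real data is bounded by the usual offline
  caveats: confounding by indication, no ground-truth counterfactuals, and
  support limited to action-state pairs clinicians actually visited. The
  frequency comparison is state-matched (the policy is queried at logged
  states) for exactly this reason.
- The reward treats the four penalties as the complete objective; harms that
  resist quantification (infusion-site events, alarm burden) enter only
  through the configured route costs.
- Electrolytes are modeled independently; coupled dynamics (e.g. refractory
  hypokalemia under hypomagnesemia) are out of scope.
- The IRL estimate is identified only up to behaviors the candidate set can
  discriminate; its diagnostics (matching error, degeneracy flag) should be
  read before its point estimate.
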