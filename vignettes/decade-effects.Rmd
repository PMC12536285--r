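---
title: "Decade effects in serial mental addition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decade effects in serial mental addition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decadd)
```

## The problem

When people add numbers written in base-10 place-value notation, not all
single-digit additions are equally hard. Adding `a` to a running total `Au`
(decade part `A`, unit `u`) falls into one of four qualitative types:

* **post-complement** `[-]`: the augend is round (`u = 0`); the addition
  merely writes `a` into the empty unit position (e.g. 10 + 5);
* **subcomplement** `[<]`: `u > 0` and `u + a < 10`; the sum stays inside
  the decade (e.g. 15 + 4);
* **complement** `[=]`: `u + a = 10`; the sum lands exactly on the next
  decade (e.g. 15 + 5);
* **supercomplement** `[>]`: `u + a > 10`; the sum crosses the decade and
  needs a carry (e.g. 15 + 6).

In the serial-addition paradigm a participant adds a list of digits one (or
two) at a time, holding the running total in mind and typing only the final
sum on cue. Every visible digit is an addend, every running total an augend,
so each inter-keypress interval is the latency of exactly one classified
addition. The empirical finding this package operationalizes is a latency
gradient `post < comp < sub < super` that cannot be reduced to problem size
(complements involve *larger* addends than subcomplements yet are faster),
plus, with two visible addends, strategic re-ordering of the addends to
manufacture complement-then-post-complement sequences.

`decadd` implements the full quantitative apparatus around this claim: the
taxonomy (`classify_single()`, `classify_dual()`, `optimal_sequences()`),
constrained stimulus generation (`list_spec()`, `generate_list()`,
`generate_set()`), a generative simulator of sessions
(`sim_params()`, `simulate_experiment()`), conservative measurement
(`first_presentation_accuracy()`, `screen_outliers()`,
`addition_latency_table()`, `list_latency_table()`) and mixed-effects
inference (`fit_accuracy_model()`, `fit_latency_model()`,
`compare_models()`, `run_study_analysis()`).

## The paired-addend taxonomy

With two simultaneous addends, the features `u + a1`, `u + a2`, `a1 + a2`
and `u + a1 + a2` define nine types. Round augends give types 1-3 by the
pair sum against 10. Otherwise any partial sum equal to 10 gives type 6,
the *overt complements and pairs*, with subtypes by which sums hit 10:
direct complement (6a, `u + a1 = 10`), indirect complement (6b,
`u + a2 = 10`), pair (6c, `a1 + a2 = 10`) and the complement-pairs 6d/6e
where a complement and a pair coincide. Otherwise the total decides:
below 10 (type 4), exactly 10 (type 5, *covert complement* — round only via
the associative order), 11-19 (type 7), exactly 20 (type 8, covert) and
above 20 (type 9). Types group back onto the single-addend categories as
{1,2,3} → post, {4,5} → sub, {6} → comp, {7,8,9} → super.

```{r dual}
classify_dual(15, 4, 5)   # indirect complement: reverse the addends
optimal_sequences(15, 4, 5)
```

Three design choices here were genuinely open and are resolved as follows.

* **Augends above 99.** The taxonomy depends only on `u = Au mod 10`; the
  decade part never matters, so arbitrarily large running totals are
  classified through their unit digit.
* **Equal addends.** Generated stimuli never repeat adjacent digits, but
  classification of `a1 = a2` is still defined by the same cascade. A
  complement-pair subtype (6d/6e) requires two *distinct* addends, so the
  single candidate (augend unit 5 with addends 5, 5) resolves to the direct
  complement 6a.
* **Plan ranking.** `optimal_sequences()` scores the linear, commuted and
  associative evaluation orders by (i) how many facilitative steps (post or
  comp) they induce and (ii) the summed difficulty under the empirical
  ordering post < comp < sub < super, breaking ties deterministically
  linear < commuted < associative. In the associative plan the first step is
  the pair formation (a pair summing to 10 is itself a complement) and the
  second adds the pair total to the running augend; adding a round total is
  a pure decade increment and is typed like a post-complement. Under this
  model an addition belongs to category comp exactly when (its augend unit
  is non-zero and) some order contains a complement step immediately
  followed by a post step — a property the test suite checks by exhaustive
  enumeration.

## Stimulus generation

Sessions use 30 lists, 10 per list type. Single-addend lists hold 4-6
digits 1-9 with no adjacent repetitions and contain exactly zero, one or
two complement steps along the running total (the first element is the
initial augend). Paired-addend lists hold 8, 10 or 12 digits, are consumed
in pairs from an initial augend of zero, and allow *no* overt complements
or pairs, *some* (exactly one of each) or *many* (three or more in total);
covert opportunities (types 2/5/8) are not forbidden in "no" lists — the
published example lists require this reading, since the "many" example
itself contains covert complements while "some" counts exactly one overt
complement and one pair.

The sampler draws the list length from per-type weights, then
rejection-samples uniform digit sequences of that length until the sum
window and the count contract hold, so conditional on length the
distribution is uniform over valid lists and the length distribution is
exactly the calibrated one. The published set-composition tables report
mean element counts of 4.92/5.06/5.23 (sums 24.5/25.1/25.7) for the three
single-addend list types and 9.79/10.03/10.26 (sums 49.5/50.2/51.3) for the
paired ones, with the exact construction windows unpublished; the default
length weights solve those mean element counts and the default sum windows
([20,29]/[20,30]/[21,30] and [44,55]/[44,56]/[45,56]) stagger the sums in
the same direction, so that facilitation effects cannot be problem-size
artifacts of the sets. Both are ordinary `list_spec()` fields and can be
overridden. One structural constraint is worth recording: a 4-element list
cannot hold two complements with a sum above 20 (consecutive complements
are impossible, so the unique two-complement pattern there runs
10 → post → 20), hence two-complement lists draw lengths from {5,6} with
weights preserving the 5.23 mean.

`validate_list()` re-checks every constraint through the public counters
(`count_complements()`, `count_opportunities()`), a deliberately separate
code path from the sampler's fast inner loop, and is used as the oracle in
the generator's tests.

## The generative simulator

`simulate_experiment()` emulates the full procedure: each of the (default)
21 participants receives a unique random stimulus set; lists are presented
in random order; miscalculated or late lists are re-presented at the end of
the sequence with an incremented presentation index until every list has a
correct, on-time entry.

The latency of a step of type `t` with problem-size covariate `x` (the
addend, or the addend sum for paired steps) for participant `p` is

    latency = (base[t] + slope * x + b_p) * eps,

with `b_p ~ Normal(0, participant_sd^2)` drawn once per participant and
`eps` lognormal with unit mean and coefficient of variation `residual_cv`
(response times are positively skewed with right tails; a multiplicative
lognormal is the standard generative choice and keeps latencies positive).
A paired addition executes the plan chosen by `choose_plan()` — with
probability `strategy_prob` the top-ranked order, else the displayed linear
order — and its latency is the sum of the two induced step intercepts plus
`search_cost` when a non-linear plan is executed.

Defaults (all tunable through `sim_params()`):

| parameter | default | units | rationale |
|---|---|---|---|
| `base_latency` | 638 / 935 / 823 / 1298 (post/sub/comp/super) | ms | the observed mean latencies of the four types |
| `addend_slope` | 0 | ms/unit | the type intercepts above are *marginal* means, so the size effect is folded into them; a nonzero slope redistributes the same means and is available for sensitivity analyses |
| `participant_sd` | 120 | ms | typical between-adult RT spread |
| `residual_cv` | 0.25 | — | typical trial-to-trial RT variability |
| `error_hazard` | .005 / .045 / .01 / .075 | per addition | chosen so closed-form first-presentation list error rates land in the observed 5-23% band with the observed ordering |
| `late_prob` | 0.03 | — | late entries are rare |
| `strategy_prob` | 0.9 | — | indirect complements were only marginally slower than direct ones, implying near-ubiquitous re-ordering |
| `search_cost` | 50 | ms | that marginal slow-down |
| `entry_mean` | 800 | ms | result entry under a 2 s limit |

Miscalculation is modelled per addition but observed only per list (the
paradigm never reveals which step failed), so a list errs with probability
`1 - prod(1 - hazard[step])`. Late entries are generated only at the
result-entry event and are neither correct nor genuine errors. Whether a
published list latency includes the entry interval is not stated, so the
simulator records the entry time in its own column and the measurement
layer can compute either convention (`include_entry`).

What the simulator deliberately does **not** model: learning or fatigue
across trials, keystroke-level motor processes, and retrieval-versus-
counting process differences. Passing tests therefore show that the
*pipeline* recovers the structure this generative model puts in — they do
not certify the model against real adders, whose latency distributions,
error correlations and strategy mixtures are richer.

For calibration studies (`null_sim_params()`, `null_set_specs()`), all type
intercepts and hazards are equal and all list types share one length
distribution and sum window, making the three list types exchangeable by
construction: any rejection beyond the nominal rate would indicate a defect
in the inference chain.

## Measurement conventions

Accuracy is the proportion of genuine errors among a list's *first*
presentations, with late entries removed from numerator and denominator.
Latency uses only correct, on-time presentations. Outliers are values
exceeding the overall mean by more than `outlier_k = 3` standard
deviations, computed once on the full vector (not iteratively) and screened
one-sided above by default — the convention matches the published wording
"exceeding the overall mean"; two-sided screening is a config switch. On
default simulated data the screen removes well under 5% of values (the
published realized rates are 0.79-2.1%).

## Inference

All models include a participant random intercept. Accuracy uses a
logistic mixed model (`lme4::glmer`), latency a linear mixed model
(`lmerTest::lmer`, Satterthwaite degrees of freedom); pairwise contrasts
between marginal means come from `emmeans` with Tukey adjustment. Effect
sizes attach to contrasts as partial eta-squared via the standard
conversion `t^2 / (t^2 + df)`. Nested comparisons (`compare_models()`) are
maximum-likelihood likelihood-ratio tests; because the published analysis
does not name its pseudo-R-squared variant, the default reported here is
the gain in marginal R-squared (fixed-effect variance over fixed + random +
residual variance) from adding the factor, with the likelihood-based
`1 - exp(-chi^2 / n)` reported alongside. Convergence or singularity
messages are captured into the fit's `diagnostics` rather than swallowed;
a zero-variance outcome raises a structured degenerate-fit error. Exact
printed coefficients, odds ratios and pseudo-R-squared values from the
original software are *not* an anchoring target (estimator variants and
package versions shift them); directions, orderings and summary tables
are.

```{r report, eval = FALSE}
log <- simulate_experiment(21, 1, seed = 1)
run_study_analysis(log)
```

## Problem sizes and numerical choices

The package's own verification uses: exhaustive enumeration for the
taxonomy (900 single cases, 720 dual triples); 1,000 generated lists per
list type per study for the validator; 100 replications of a 21-participant
experiment for parameter recovery (each type's marginal-mean 95% interval
must cover its generating value in at least 90% of replications — this fit
uses correct-trial latencies *without* the contaminant screen, since
simulated data contain no artifacts and one-sided screening would clip the
genuine upper tail of the slowest type, biasing its mean); 200
null replications for the type-I calibration of both contrast families
(Tukey-adjusted family-wise rejection within broad binomial slack of the
nominal 5%); and a 12-participant paired-addend simulation for the
strategy diagnostic — under full strategy use, indirect complements (6b)
sit near their direct counterparts (6a), and under no strategy use near
supercomplements (type 7), which is precisely the discriminating pattern
that licenses the strategic-reversal interpretation. These sizes are the
study's own conditions where stated (21 participants, 30 lists) and
otherwise chosen to keep Monte-Carlo error far smaller than the effects
under test.

Numerical details: latencies are floored at 1 ms (relevant only under
extreme negative participant effects); `residual_cv = 0` switches the
lognormal factor off exactly, which the exact-identity tests exploit;
rejection sampling has an explicit attempt budget and fails loudly on
unsatisfiable specifications; all randomness descends from a single seed,
with per-participant sub-seeds drawn deterministically from it so sets are
independent yet reproducible.

## Known limitations

* The exact unpublished set-construction windows are re-derived
  assumptions, flagged as configurable; only their direction is anchored.
* The replication path (`decadd_replicate()`) expects the user to download
  the deposited raw data; its column schema is adapted through a mapping
  config, and the package's tests exercise that machinery on synthetic
  stand-ins only.
* Only base 10 is exercised; the taxonomy is parameterized by the decade
  structure conceptually but not exposed for other bases, and subtraction
  is out of scope.
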