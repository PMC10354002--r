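---
title: "From stated preferences to a cost-effectiveness frontier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From stated preferences to a cost-effectiveness frontier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choicefrontier)
```

## The problem

Adolescents in South Africa carry a high burden of HIV, other STIs and
unintended pregnancy, yet their uptake of clinic-based HIV and contraceptive
services is low.  Discrete choice experiments (DCEs) reveal *which* service
attributes — friendly staff, confidentiality, Wi-Fi, subsidized food,
afternoon hours, youth-only space — would draw adolescents in, but a
preference coefficient is not a policy: deciding what to implement requires
projecting coefficients into additional patients and pricing each bundle of
modifications at a real clinic.  `choicefrontier` implements that
translation as a reusable, tested pipeline: conditional-logit coefficients →
percentage-point uptake changes → additional adolescents per month → monthly
incremental cost → incremental cost-effectiveness ratios (ICERs) on an
efficiency frontier over all attribute combinations.

## The choice model and the uptake translation

A conditional logit assigns alternative $i$ in a choice task the probability

$$P_i = \frac{e^{\beta'x_i}}{\sum_j e^{\beta'x_j}},$$

where $x_i$ is the alternative's attribute vector and $\beta$ the utility
weights.  Under reference (dummy) coding the baseline service — clinic
location, morning hours, unfriendly staff, no confidentiality, no
incentives — has utility zero, and a scenario's utility is the sum of the
coefficients of the levels it switches on.

The uptake translation is a **two-alternative contrast**: the status quo's
utility is pinned so that its choice probability equals the clinic's
baseline uptake share $p_0$, and a scenario shifts the log-odds by its
utility $u$:

$$\Delta p = 100\,\big[\mathrm{logit}^{-1}(\mathrm{logit}(p_0) + u) - p_0\big]
\quad\text{(percentage points)}.$$

This is the natural reading of "change in the probability of choosing to use
services from baseline" when the original survey's full choice-set design is
not available.  Its standard error uses the delta method on the
percentage-point scale, $100\,p(1-p)\,\mathrm{se}(u)$ at the shifted
probability $p$, with $\mathrm{se}(u)$ combined from the levels' standard
errors **assuming independence** — published DCE tables rarely include the
coefficient covariance matrix.  `scenario_utility()` accepts a full `vcov`
when one exists.  Confidence intervals are symmetric with
$z = 1.959964$.

Three facts about this translation are worth stating plainly:

* it is strictly increasing in $u$, odd under the logistic symmetry
  $\Delta p(-u; p_0) = -\Delta p(u; 1-p_0)$, and superadditive for positive
  shifts while probabilities stay below 0.5 — all verified by tests against
  an independently coded closed form;
* the published per-attribute uptake deltas (e.g. 18.54 points for friendly
  staff from a 0.19 coefficient) are **not** recoverable from the rounded
  printed coefficients through this (or any) logit translation at the stated
  baseline.  The packaged uptake table therefore treats the printed deltas as
  authoritative *inputs* for everything downstream, and the logit translation
  is exercised on synthetic coefficients with known truth;
* printed combination coefficients (e.g. 0.11 for Wi-Fi + food) are not the
  sum of their components (0.05), so combined rows cannot be regenerated from
  single-attribute rows; the pipeline takes combination deltas from the
  table, and `delta_uptake()` documents the no-interaction additivity it
  assumes when used on raw coefficients.

## From uptake to people

`project_uptake()` applies $\Delta p$ multiplicatively to the clinic's
baseline adolescent count ($1531$ per month at Clinic A, $1808$ at
Clinic B, both at a 30.60% baseline share): $\mathrm{additional} =
\mathrm{round}(N_\mathrm{base}\,\Delta p / 100)$, rounding **half away from
zero** — the only rule consistent with every checkable published count
(e.g. $1531 \times 0.0271 = 41.49 \to 41$,
$1808 \times 0.23 = 415.84 \to 416$).  Negative projected changes (possible
at a lower confidence bound) clamp to zero additional adolescents by
default; `floor = 1` reproduces the published sensitivity tables' convention
of reporting one adolescent.  The unrounded count is kept alongside for
cost-per-patient arithmetic.

## The costing model

Each clinic cost line carries a monthly amount in ZAR and one allocation
rule, mirroring an incremental, health-system-perspective costing:

| rule | incremental monthly cost | used for |
|---|---|---|
| `none_incremental` | 0 | assets (no new assets needed) |
| `per_visit` | unit cost × additional adolescents | supplies, Wi-Fi supply |
| `shared_all_patients` | amount × additional / (headcount + additional) | utilities-type overheads |
| `extra_room_overhead` | room share × amount, if youth-only or afternoon | counselling-room space |
| `afternoon_staff_time` | amount × afternoon hours fraction, if afternoon | staff extension |
| `all_adolescents_billed_to_additional` | unit × (baseline + additional), if food | subsidized food |

Any line may add a `requires=` gate so that a cost tied to an attribute
contributes nothing to scenarios without it.  Conversion to USD uses the
2019 mid-year rate of 14 ZAR/USD (configurable).  Costs are assumed to scale
linearly with volumes — no saturation, no stepwise capacity jumps.

Two configuration knobs have no published value and carry package defaults
chosen once as round, clinically plausible figures: the **afternoon
staff-time fraction** (0.02 — roughly two extra hours a day staffed by a
skeleton roster, which puts an afternoon-only scenario near the published
$1000–1150/month total) and the **counselling-room overhead share**
(0.08 — one room's slice of facility overheads, consistent with the
published youth-only totals of $611–812/month).  Both live in
`cost_config()` and the run log records them for every pipeline run.

The original clinics' line-by-line workbooks were never published, so the
packaged workbook is a *synthetic reconstruction* at the scale of the
published per-category summary (it is named accordingly).  The costing
module is therefore validated by formula oracles and invariance properties
(gating, money homogeneity, per-visit linearity), not by regenerating the
published per-category cells — several of which cannot be reconciled with
the printed totals.  For frontier arithmetic the packaged strategy tables
carry the published per-strategy totals directly.

## Dominance and the frontier

`build_frontier()` runs the textbook incremental analysis over strategies
$(e_s, c_s)$ = (additional adolescents/month, total monthly cost):

1. **Strict dominance** — drop any strategy for which another (or doing
   nothing, the zero-cost zero-effect baseline) is at least as effective and
   no more costly, with one comparison strict.
2. **Extended (weak) dominance** — iteratively drop any survivor whose ICER
   over its next-cheaper neighbour is at least the ICER of its
   next-more-effective neighbour over it.  The survivors are exactly the
   vertices of the lower-left convex hull of the effect–cost points anchored
   at the origin, so frontier ICERs strictly increase.  Collinear middle
   points and exact (cost, effect) ties are resolved deterministically (ties
   keep the lexicographically first name), making labels independent of
   input order.
3. The first survivor's ICER is priced against the do-nothing baseline; no
   willingness-to-pay threshold is applied — the output *is* the frontier.

Tests compare the engine's survivor set on 1,000 random strategy sets with
an independently coded brute-force hull walk.

ICERs use whole-person (rounded) effects by default, which is how the
published Clinic A ladder is computed; `use_exact_effects = TRUE` switches
to unrounded counts, which is what the published Clinic B mid-rung value
(9.32) requires.  The two source tables are inconsistent on this point; the
default follows the convention that reproduces the larger share of printed
values, and the flag surfaces the other.

**A data inconsistency worth knowing about.**  At Clinic A the published
table keeps (Wi-Fi, youth-only) on the frontier and labels (Wi-Fi, food)
weakly dominated — yet by the printed numbers (Wi-Fi, food) buys uptake
more cheaply from the origin (\$10.15 vs \$10.62 per additional adolescent),
and its ICER over (Wi-Fi, youth-only) is \$8.01, *below* its predecessor's,
which is the opposite of what weak dominance requires.  No dominance rule
reproduces that labelling; it appears to be an error in the source's
spreadsheet (Clinic B's table is fully hull-consistent).  The engine follows
the definitions: it swaps the two strategies and reports the discrepancy
rather than silently matching the printed frontier.  The published pairwise
contrasts themselves (\$9.78, \$10.45) are exact arithmetic on the printed
columns and are reproduced by `pairwise_icer()`.

## Sensitivity analysis

`run_sensitivity()` re-runs projection, costing and frontier construction at
the lower (or upper) bound of every scenario's uptake confidence interval.
Because interval widths differ across bundles, the frontier can reshuffle:
combinations whose lower bound stays high can displace nominally better
ones.  The published lower-bound tables ship as reference fixtures only;
their cost-per-patient columns are internally misaligned, so no numeric
check pins them.

## The synthetic choice-experiment module

To test the whole pipeline without the unavailable survey data,
`generate_design()` + `simulate_choices()` create choice tasks (default 805
respondents × 8 tasks × 2 alternatives, the scale of the original survey;
tasks per respondent and alternatives per task were not published, so these
conventional defaults are configurable) with uniformly random attribute
levels, rejecting tasks whose alternatives are identical, and sample choices
from the softmax of the true utilities.  `fit_conditional_logit()` maximises
the conditional-logit likelihood by Newton–Raphson on the analytic gradient
and observed information (convergence at gradient max-norm $< 10^{-6}$;
standard errors from the inverse observed information; rank-deficient
designs and separation raise errors instead of drifting).  The fit agrees
with `survival::clogit()` to machine precision on simulated data, and
`recovery_experiment()` confirms near-zero bias and 90–99% coverage of
nominal 95% intervals over 200 replicates at survey scale.

What the generator does *not* emulate: D-efficient designs, respondent
heterogeneity (mixed logit), attribute interactions, and stated-vs-revealed
preference gaps.  Passing recovery tests show the estimator and translation
are self-consistent — not that real-world uptake will match projections.

## Numerical and validation choices

* Probabilities via max-subtracted softmax; exact translation invariance.
* Counts rounded half away from zero; currency displayed at 2 decimals with
  all internal arithmetic in double precision.
* Cost per additional adolescent uses the unrounded count and is `NA` (not
  infinite) when a costly scenario projects no additional uptake.
* A strategy with zero cost and zero effect ties with the do-nothing
  baseline and is labelled weakly dominated.
* Master seeds fan out into separate design/simulation streams so any
  replicate is reproducible in isolation.
* Validation problem sizes: 1,000 random strategy sets (≤10 strategies) for
  the hull oracle; 805 × 8 single fits and 200-replicate recovery runs for
  the estimator; these run in about two minutes on a laptop core.

## Limitations

The framework inherits the source data's limits: stated preferences may
overstate real uptake (hence the lower-bound sensitivity mode), the
challenging-to-modify attributes (friendliness, confidentiality) have the
largest projected impact but no defensible costing, combination utilities
assume no interactions, and linear cost scale-up ignores saturation.  The
published uptake deltas are used as printed because they cannot be re-derived
from the rounded coefficients.
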