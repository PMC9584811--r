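---
title: "Titration, anomaly scoring and country-level pooling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Titration, anomaly scoring and country-level pooling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intertemporal)
```

## The instrument

Temporal discounting — the devaluation of outcomes with delay — is usually
summarised by an indifference point: the delayed amount at which a person
switches from "take it now" to "wait". This package implements a short
adaptive instrument that approximates the indifference point with a
three-step titration and then probes five classic intertemporal choice
anomalies with four further binary items, so that a complete protocol takes
between 10 and 13 binary choices.

Every amount is a constant proportion of a per-country monetary **anchor**,
roughly 10% of the average monthly household income in local currency, which
makes the same design portable across currencies and income standards. A
staircase set starts at 110% of the base amount delayed by 12 months. An
impatient choice (taking the gain now, or deferring a payment) raises the
delayed offer along the ascending ladder 120% then 150%; a patient choice
lowers it along 102% then 101%. A reversal at the second item terminates the
set, so each set has exactly six terminal patterns and takes two or three
items. Three sets are run: small gains at the anchor, the identical values
as payments, and the gain set again at ten times the anchor.

The simplified indifference point is defined as the *smallest delayed amount
the participant accepted* in the small-gain set. With a 500-unit base, a
participant who rejects 550 but accepts 600 has indifference 600. (The
alternative reading, "the largest value at which the delayed option was
chosen", contradicts that very switch pattern on the ascending branch — the
participant never saw a larger accepted value — so the smallest-accepted
rule is used; it reproduces the canonical example on both branches.) A
participant who rejects even the 150% offer is assigned the 150% value with
a censoring flag, and anomaly items are still constructed, because the
protocol shows the anomaly scenarios to everyone.

From the indifference value $v$ and base $b$ (premium $p = v - b$) the four
anomaly items are:

* **present bias** (shifted interval): $b$ at 12 months vs. $v$ at 24
  months;
* **subadditivity**: $b$ now vs. $b + 2p$ at 24 months — the *additive*
  extension of the 12-month premium over the doubled horizon (with $b=500$,
  $v=600$ this is the printed 700; multiplicative compounding would give
  720 and is deliberately not used);
* **delay / speedup framing**: $b$ now vs. $v$ at 12 months, the premium
  described once as a bonus for waiting and once as a fee given up to
  receive the gain now.

Amounts are rounded half-away-from-zero to a configurable currency
denomination (default: one unit). Times are fixed at 0, 12 and 24 months.

## Scoring

Each completed staircase set maps onto an integer **category 0–5** ordered
by revealed impatience (0 = accepted the 101% offer; 5 = rejected all
offers; the loss set mirrored so that deferring payments scores high). Each
anomaly item contributes one point when the discount-consistent (immediate
gain) option is chosen. The **discounting score** is the sum: 0 means
always-delayed gains and always-immediate losses, 19 the reverse. The
decomposition (3 × 0–5 + 4 × 0–1) is reconstructed from the published score
range and the item structure and is isolated in one function so an
alternative weighting can be swapped in. Scores are standardised with the
pooled sample mean and sample ($n-1$) standard deviation.

Anomaly flags follow the published worked examples at the first-item level:

* absolute magnitude — immediate at the first small-gain item *and* delayed
  at the first large-gain item;
* gain–loss asymmetry — immediate gain *and* pay-now at the first items;
* delay–speedup — immediate under delay framing *and* delayed under speedup
  framing;
* present bias — delayed chosen at the shifted 12→24 item;
* subadditivity — delayed at the 0→24 item *and* immediate at the shifted
  12→24 item (the strict two-item conjunction).

Each flag has a mirror-image inconsistency flag (reverse magnitude, reverse
gain–loss, reverse framing, future bias, superadditivity); a flag and its
mirror are never simultaneously true. Two documented variants exist:
`rule_variant = "category"` compares whole-set categories for the magnitude
and gain–loss rules, and `present_bias_rule = "conjunction"` adds the
impatient first leg (immediate at the first small-gain item) to the
present-bias rule, which is how the canonical two-part example is phrased.

### A structural property of the shifted-item detector

The default present-bias rule is the weakest reconstruction in the scoring
module, and two consequences are worth stating plainly. First, for any
*stationary* agent (exponential or hyperbolic, no present-bias parameter),
accepting the indifference offer at 12 months implies accepting the same
relative premium over the shifted 12→24 interval, so the detector fires for
every consistent agent whose indifference is interior to the titration
grid. Second, the condition for choosing delayed at the *speedup* framing
item is algebraically identical to the shifted-item condition for such
agents, so a framing-only agent always co-fires the default present-bias
detector. Both facts are consequences of the instrument re-using the
accepted premium, not software choices; the `"conjunction"` variant
suppresses both for patient agents. The single-mechanism reference grid
(`mechanism_grid()`) therefore places the magnitude, sign and subadditivity
agents in the censored impatience range ($k > \log 1.5$), where the shifted
item is declined and full one-flag exclusivity holds under the default
rules, and documents the framing agent's exclusivity under the conjunction
variant.

## The respondent simulator

Synthetic respondents are discounted-utility agents. A prospect pair with
sooner option at $a$ months and later at $b$ months is evaluated by
composing per-interval factors $F(0,a)\,F(a,b)$ with, for an interval of
length $\Delta$ years,

$$F_{\text{exp}} = e^{-k_{\text{eff}}\Delta^{s}},\qquad
  F_{\text{hyp}} = \frac{1}{1 + k_{\text{eff}}\Delta^{s}},\qquad
  F_{\beta\delta} = \beta^{[a=0]}e^{-k_{\text{eff}}\Delta^{s}},$$

and $k_{\text{eff}} = k\,(m/\text{anchor})^{-\gamma}\rho^{[\text{loss}]}$
where $m$ is the magnitude of the prospect pair. Each mechanism maps to one
anomaly: $\gamma > 0$ (lower rates for larger magnitudes), $\rho < 1$
(losses discounted less), $\beta < 1$ (a one-off penalty for leaving the
present, applied only to intervals starting now, so it cancels in shifted
comparisons), $s < 1$ (a whole interval discounted less than its composed
halves), and a framing premium $\varphi$ (in anchor units) added to the
immediate option's utility under delay framing only. Choices are logistic
in the utility difference scaled by $T \times \text{anchor}$; $T = 0$ is
the deterministic limit with ties resolved to the immediate option.

The population generator draws the latent log rate from
$\log k = \mu + \beta_{\text{gini}} z_{\text{gini}} +
\beta_{\text{gdp}} z_{\text{gdp}} + \beta_{\text{infl}} z_{\text{infl}} +
u_c + \varepsilon_i$ with standardised country covariates, a country random
intercept and individual noise. Defaults describe the study conditions the
package targets: 61 countries × 200 respondents, median annual rate near
0.12 with individual log-SD 0.8 (spanning fully patient to censored
staircase behaviour), country SD 0.15, modest country effects
($\beta_{\text{gini}} = +0.2$, $\beta_{\text{gdp}} = -0.2$,
$\beta_{\text{infl}} = 0$), minority subpopulations carrying each anomaly
mechanism (20–35% each), and temperature 0.05. These choices produce
anomaly prevalences broadly in the 10–40% band reported for real
populations, an aggregate mean score near the published 10–11, and a
between-country share of score variance well under 20%. Response times are
lognormal (median ≈ 7 minutes, floored at 150 s so that clean records never
trip the timing rule), and demographics and finances are simple categorical
and lognormal placeholders — sufficient for exercising the quality-control
rules, not demographically realistic. One known gap from real data: under
the default one-leg rule the simulated present-bias prevalence is far
higher than published prevalences, for the structural reason above; the
conjunction variant brings it into a realistic range. Passing tests on
these agents show the machinery is correct under the generative model, not
that the model captures real response behaviour (no inattention, no
item-order effects, no cultural response styles).

Labelled quality-control violations are injected at configurable rates
(defaults 1–5%): failed attention checks, sub-120 s response times,
completion ≤ 90%, ages above 100, incomes above $10^8$, and nonsense
free-text flags.

## Quality control

Exclusions mirror a pre-registered two-stage pipeline. Stage one: attention
failure (choosing to *pay* rather than receive), nonsense free text
(external flag — the package does not attempt text analysis), age above
100, response time below $\max(120\,\text{s}, \text{median} - 3 \times
\text{MAD})$, and completion ≤ 90%. Stage two, applied only to financial
analyses and reported separately: money values above $10^8$, incomes more
than 100 MADs and assets more than 1000 MADs above the country median, and
zero income while employed full time. The MAD is used raw (no 1.4826
normal-consistency constant), the timing median is pooled across countries,
and the medians for the timing and outlier rules are computed on records
surviving the first three rules so that nonsense records cannot contaminate
them; all three conventions are exposed as arguments. Records failing
several rules are counted under each rule but removed once, so per-rule
counts may sum to more than the number removed; the report keeps the full
record-by-rule matrix and its overlap cross-counts.

## Aggregation

Country means are pooled with the classical DerSimonian–Laird
random-effects model: $\hat\tau^2 = \max\{0, (Q - df)/C\}$ from the
fixed-effect weights, pooling weights $1/(v_i + \hat\tau^2)$ with
$v_i = s_i^2/n_i$, $I^2 = \max\{0, (Q - df)/Q\}$, normal-quantile
confidence intervals, and a 95% prediction interval using a $t$ quantile
with $k - 2$ degrees of freedom (reported as undefined for $k = 2$ rather
than extrapolated). Anomaly proportions are pooled on the logit scale —
which stabilises variances — with a 0.5 continuity correction at the
boundaries, then back-transformed. Meta-regression uses weighted least
squares with the method-of-moments residual $\tau^2$
(the $Q_E$-based estimator under fixed-effect weights) and re-fitted
random-effects weights. The between/within-country variance partition uses
one-way ANOVA method-of-moments components with the unbalanced-design
correction $n_0 = (N - \sum n_i^2/N)/(k-1)$, truncating a negative
between-component at zero. REML/likelihood-based alternatives are
deliberately out of scope; the moments estimators are the classical
defaults and are cross-checked in the test suite against an independent
implementation (`metafor`).

## Worked demonstration

```{r demo}
anchors <- demo_country_table()
cfg <- population_config(n_per_country = 150, seed = 20)
pop <- sample_population(cfg, anchors)
sim <- simulate_study(pop, anchors, cfg)
qc <- apply_exclusions(sim$responses)
glance(qc)

scored <- score_responses(qc$retained, anchors)
summary <- summarize_countries(scored, anchors)
meta <- random_effects_meta(summary$mean_score, summary$var_mean,
                            labels = summary$country_id)
meta
variance_partition(scored$discounting_score, scored$country_id)
```

```{r forest, fig.width = 6, fig.height = 3}
autoplot(meta)
```

## Problem sizes, tolerances and degenerate inputs

The validation suite enumerates all $6^3 \times 2^4 = 3456$ complete paths
exhaustively (seconds), and calibrates the pipeline on 61 synthetic
countries × 200 agents with 100 replicates for moderator-sign recovery and
a single seeded draw for the intraclass-share check — sizes chosen to make
the Monte Carlo error of those checks small relative to their acceptance
margins while keeping a full run in minutes on one core. Numerical
conventions worth knowing: monetary rounding is half-away-from-zero;
zero-variance score vectors refuse to standardise rather than return NaN;
`proportion_meta()` drops zero-size countries with a warning; a constant
moderator is an error, not a silent drop; and deterministic agents resolve
utility ties toward the immediate option (ties occur exactly on the
measure-zero boundary of the parameter grid, which the documented grid
avoids).

## Limitations

The anomaly criteria are reconstructions from published worked examples;
the exact pre-registered codings (including any weighting of the two
framing items) may differ in detail. The score decomposition is likewise a
faithful-but-reconstructed reading of the 0–19 range. The simulator is a
tool for validating the pipeline, not a behavioural model of any
population; in particular its demographic fields are placeholders and its
country covariates are synthetic. Real-data features such as partial
completion midway through a staircase are out of scope: the scorer requires
complete paths and the completion filter is expected to run first.
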