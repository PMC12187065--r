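---
title: "A Markov cohort model of one-time echocardiographic screening for aortic stenosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of one-time echocardiographic screening for aortic stenosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asscreen)
```

## The decision problem

Degenerative aortic stenosis (AS) is the most common valvular disease of
the elderly. It progresses silently for years — severity is graded by
aortic valve area (AVA): mild above 1.5 cm², moderate 1.0–1.5 cm², severe
below 1.0 cm² — and once severe disease becomes symptomatic, untreated
mortality is high while transcatheter aortic valve replacement (TAVR) is
effective. Because most prevalent disease in the community is undiagnosed,
a one-time screening transthoracic echocardiogram (TTE) in a geriatric
cohort could shorten the delay between symptom onset and treatment. The
question this package answers is economic: does one-time TTE screening at
70 or 80 years of age buy enough quality-adjusted life years (QALYs), at
what extra cost, to be worthwhile for a publicly funded payer at a
willingness-to-pay of \$50 000 per QALY?

`asscreen` implements a monthly-cycle Markov cohort model comparing a
screened and an unscreened arm over a lifetime horizon, with a
probabilistic sensitivity analysis (PSA) summarized as the incremental
cost-effectiveness ratio (ICER), net monetary benefit (NMB) and
cost-effectiveness acceptability curve (CEAC).

## Health states and transitions

The state space (`state_names()`) has 25 compartments:

* the screened/general population (disease-free);
* undiagnosed AS by severity — mild, moderate, severe asymptomatic,
  severe symptomatic;
* diagnosed AS in the same four grades (diagnosed patients are under
  echocardiographic surveillance and are referred for TAVR when severe
  symptomatic disease is recognised);
* a one-cycle TAVR procedure state;
* post-TAVR without stroke;
* twelve tunnelled post-TAVR-stroke months followed by a chronic
  post-stroke state — the tunnel forces first-year stroke costs,
  disutility and excess mortality to apply for exactly twelve cycles;
* death (absorbing).

Within a monthly cycle, death competes first; conditional on survival,
severity progression is resolved before detection, so a patient cannot
progress *and* be diagnosed in the same month (a one-cycle matrix cannot
represent two sequential moves). Undiagnosed severe disease can be
detected without hospitalization (probability 0.0037/month), through an
index hospitalization (0.0046/month, carrying a one-time admission cost),
and — once symptomatic — through symptom recognition with a mean delay of
nine months (probability 1/9 per month, the midpoint of a six-to-twelve
month consensus estimate of the symptom-to-diagnosis interval).
Diagnosed severe symptomatic patients undergo TAVR in the following
cycle. The procedure resolves by a fixed split: death 0.026, disabling
stroke 0.022 (entering the tunnel), and the remainder to post-TAVR —
pacemaker implantation (0.116), vascular complications (0.093) and major
bleeding (0.076) are transient, so they add expected one-time costs but
do not occupy states.

Two treatment scenarios are modelled. Under the primary
*symptomatic-trigger* policy, TAVR is performed only at recognised
symptomatic severe disease. Under *early intervention*, diagnosed severe
asymptomatic patients also proceed to TAVR in the next cycle; occupants
of the procedure state then carry base utility rather than symptomatic
utility, because the procedure is elective in asymptomatic patients.

## Parameters

`default_parameters(age)` assembles the base case; every value is
overridable through `modify_parameters()` or a YAML configuration.
Key defaults:

* **Screening yield.** At 70: screen-positive rate 0.013, of which 98.1%
  mild and the remainder moderate. At 80: 0.228, split 0.300 / 0.429 /
  0.271 across mild / moderate / severe (from 37, 57 and 33 cases among
  556 screened). Baseline severe disease starts asymptomatic; the
  prevalence of already-symptomatic undiagnosed severe disease at
  screening is taken as zero.
* **Natural history.** Monthly incidence of mild AS from the general
  population 0.0122; AVA declines by 0.07 cm²/year (SE 0.0128), which
  converts to a monthly band-crossing probability of
  `ava_band_transition(0.07, 0.5)` ≈ 0.0116 for both the mild-to-moderate
  and moderate-to-severe steps (each severity band is 0.5 cm² wide; the
  mild band is assumed equal to the moderate one since entry AVA is not
  observed); symptom onset in severe disease 0.0153/month; severe
  symptomatic mortality 0.0305/month.
* **Mortality.** A life table supplies age-specific annual death
  probabilities, converted to monthly hazards. Disease-state mortality is
  the general-population hazard scaled by a relative risk *on the hazard
  scale* — scaling probabilities directly could exceed 1 at extreme ages
  with the post-stroke first-year relative risk of 4.46 (4.46 in tunnel
  months, 1.99 chronically). The relative risks for mild, moderate and
  severe asymptomatic disease default to 1 because the source estimates
  behind the published calibration were not reported numerically;
  inventing effect sizes would be worse than under-modelling them, and
  the fields are exposed for review. Post-TAVR mortality returns to the
  general-population rate.
* **Costs (CAD, undated).** Screening TTE \$215.15 once; surveillance
  \$4.48 / \$11.95 / \$41.35 per month for diagnosed mild / moderate /
  severe (the TTE fee amortized over 48-, 18- and 9-month follow-up
  intervals, plus assessment); index hospitalization \$7940; TAVR
  \$64 466 plus expected complication costs and a \$105.25 follow-up,
  i.e. `expected_tavr_cost()` ≈ \$67 331; post-stroke \$6196.08/month in
  year one (including the index stroke admission) and \$522.08/month
  thereafter.
* **Utilities.** 0.83/year for all asymptomatic states, 0.57 for severe
  symptomatic disease (and the procedure month under the symptomatic
  trigger), 0.64 in the first post-stroke year, 0.69 after.
* **Economics.** 1-month cycles, lifetime horizon (to age 110), 1.5%
  annual discount for costs and outcomes, willingness-to-pay \$50 000 per
  QALY.

## Accrual and one-time cost timing

Each cycle accrues occupancy × monthly state cost and occupancy × annual
utility / 12, discounted at $(1+0.015)^{-t/12}$ with $t$ in months from
screening. One-time costs are charged in the cycle in which the
triggering transition completes, at that cycle's discount factor: the
screening TTE to the whole screened cohort (screen-negatives included) at
cycle 0, the index hospitalization on the hospital-detection route, and
the expected TAVR bundle on entry to the procedure state. No half-cycle
correction is applied by default: with monthly cycles the correction is
small (under 1% of lifetime QALYs in the base case) and the reference
results appear to have been computed without one; `run_cohort(...,
half_cycle = TRUE)` enables standard first/last half-cycle weights.
Residual cohort mass at age 110 transitions to death.

## The synthetic life table

The analysis requires a general-population life table, which is external
data. `synthesize_lifetable()` generates one from a Gompertz–Makeham
hazard $h(a) = c + \alpha e^{\beta a}$ with defaults $c = 2\times10^{-4}$,
$\alpha = 2.5\times10^{-5}$, $\beta = 0.095$ over ages 65–110, closed
with $q_{110} = 1$. These values give monotone geriatric mortality close
to recent Canadian rates (about 2% at 70, 4.9% at 80, 12% at 90), which
is the statistical structure the model assumes: the generator emulates a
real life table's shape, not any specific published table. A copy
generated with the defaults ships as
`inst/extdata/synthetic_lifetable.tsv` (the filename marks it as
synthetic); `load_lifetable()` reads user-supplied tables in the same
two-column format.

Because the true life table, the severity-specific mortality relative
risks and most parameter standard errors behind the reference analysis
are not available, absolute QALY levels and ICERs computed here carry
life-table uncertainty. What passing tests demonstrate is internal
correctness (mass conservation, oracle agreement, accrual identities) and
reproduction of the *qualitative* economics — which age and policy are
cost-effective at \$50 000/QALY — not agreement with any individual
country-year mortality experience.

## Probabilistic sensitivity analysis

`run_psa()` draws one parameter set per replication (shared by both arms,
i.e. common random parameters), runs the paired cohorts, and records
per-arm discounted totals; 5000 replications is the default. Sampling
families follow the published input tables: beta for probabilities, gamma
for costs and the AVA rate, lognormal for utilities and relative risks,
fixed for the fee-schedule items. Beta and gamma are parameterized by
method of moments from (mean, SE); lognormal matches mean and SE on the
natural scale. Only the AVA progression rate has a published SE (0.0128);
all other SEs default to 20% of the mean — a uniform coefficient of
variation that keeps the PSA honest about unquantified uncertainty and is
configurable per parameter. The severity split is sampled as a Dirichlet
with concentration equal to the published split scaled by the
screen-positive count of the source cohort (127 at age 80, ~33 at age
70); the "gamma" distribution label printed against this probability
vector in the source tables is treated as a typographical artefact, and a
Dirichlet from counts is also feasible where a 20%-CV beta would not be
(a mean of 0.981 cannot carry a 0.196 SE). Utilities are truncated to
[0, 1] by rejection; a whole parameter set violating a joint invariant
(e.g. TAVR outcome probabilities summing past 1) is redrawn, at most 100
times. Each replication runs under its own seed derived once from the
master seed, so results are bit-reproducible and independent of
evaluation order.

Summaries use the ratio-of-means ICER (mean incremental cost over mean
incremental QALY), the standard for PSA reporting, never the mean of
per-replication ratios; `ceac()` reports the fraction of replications
with positive incremental NMB across a willingness-to-pay grid.

## Calibration tools

Two of the published calibrations are reproducible from their inputs and
are built in directly: severity progression from the AVA decline
(`ava_band_transition()`), and mortality scaling by relative risk
(`mortality_with_rr()`). The third — AS incidence targeted to aortic
sclerosis prevalence — depends on prevalence trajectories that were not
reported, so the default configuration pins the incidence at its
published value (0.0122/month) and `calibrate_incidence()` is provided as
a reproduction tool: a bisection root-find (bracket [0, 0.1], tolerance
1e-8) matching the modelled prevalence of incident AS at a target age,
measured on a disease-free cohort from the screening age. The round-trip
property — prevalence simulated at 0.0122 is recovered as ≈ 0.0122 — is
part of the test suite.

## Validation

An individual-level microsimulation (`run_microsim()`) pushes sampled
patients through the same transition matrices and one-time-cost rules and
must agree with the cohort engine's discounted totals within Monte-Carlo
error; the test suite checks both arms at 10⁵ individuals against a
3-standard-error band. Structural properties tested across the full age
range and all four strategy pairs: every transition row sums to 1 within
1e-12, cohort mass is conserved within 1e-9 over 480 cycles, death
occupancy is monotone and reaches 1 at the horizon, and a null world with
no AS leaves the arms differing by exactly the \$215.15 screening fee and
zero QALYs.

## Worked example

```{r, eval = FALSE}
lt <- synthesize_lifetable()
params <- default_parameters(80)
pair <- strategy_pair(80, "symptomatic_trigger", params)

# deterministic base case
evaluate_pair(pair, params, lt)

# probabilistic analysis (about 3 minutes at 5000 replications)
psa <- run_psa(pair, params, lt, n_reps = 5000, seed = 1)
summary(psa)
ceac(psa, wtp_grid = seq(0, 1e5, by = 5000))
```

With the bundled synthetic life table, screening at 80 under the
symptomatic trigger yields an ICER near \$21 000/QALY (cost-effective at
\$50 000), while screening at 70 and both early-intervention policies
exceed \$50 000/QALY — the same policy conclusion in all four analyses as
the reference results, with absolute ICERs differing through the
life-table and relative-risk inputs discussed above. Problem sizes used
throughout the package's own analyses: 360–480 monthly cycles per arm,
5000 PSA replications, 10⁵ microsimulated individuals.

## Known limitations

* Surgical valve replacement, repeat/valve-in-valve TAVR, sex
  stratification, frailty-based screening exclusions, alternative
  screening modalities and incidental non-AS findings are out of scope.
* Mortality relative risks for pre-symptomatic disease default to 1;
  if undiagnosed moderate/severe AS carries excess mortality, the model
  understates the benefit of early detection.
* The cohort advances in age deterministically; everyone shares one age.
* Costs are unitless currency (CAD implied) with no inflation indexing.
* The utility of the procedure month and the first post-TAVR month is an
  interpretive choice (severe-symptomatic utility under the symptomatic
  trigger, base utility for elective early intervention), as it is not
  observable from the inputs.
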