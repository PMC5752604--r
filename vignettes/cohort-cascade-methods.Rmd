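---
title: "Methods: a deterministic care-cascade cohort model for maternal and neonatal mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a deterministic care-cascade cohort model for maternal and neonatal mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnhimpact)
```

## The model

`mnhimpact` propagates an annual cohort of pregnancies through a
decision-tree model of cause-specific mortality. Mortality causes are broken
into *sub-conditions* (specific etiologies: atonic uterus within maternal
hemorrhage, sepsis within maternal infection, and so on), because
interventions act on etiologies, not on aggregate causes — suturing treats a
laceration, not a retained placenta. Each sub-condition carries:

* an **un-prevented incidence** $I$: the fraction of pregnancies that would
  develop it if no preventive intervention existed;
* an **untreated case fatality rate** $q_u$ and a residual **treated CFR**
  $q_t \le q_u$;
* for maternal sub-conditions, fetal death rates
  $f_t \le f_u$ and incremental incidence links to neonatal sub-conditions
  (e.g. obstructed labor → birth asphyxia).

The cohort is stratified over three care settings — home, clinic, hospital —
by a delivery-place distribution. Each sub-condition then passes through the
cascade, per setting, in a fixed order:

$$\text{cohort} \to \text{prevention} \to \text{diagnosis} \to
  \text{transfer} \to \text{treatment} \to \text{mortality}.$$

Every intervention is scored by three constructs: **penetration** $p$
(availability in the setting), **utilization** $u$ (appropriate use given
availability) and **efficacy** $e$ (success under ideal conditions).
Penetration and utilization are per-setting; efficacy is a single
setting-independent value, because it is defined as benefit under ideal,
controlled conditions. Receipt is $c = p\,u$ (availability and use assumed
independent) and per-intervention success is $s = c\,e$.

The engine is an expected-value machine: masses of pregnancies, not
individuals, move through the tree, and nothing is rounded until report
rendering. Identical inputs give bit-identical outputs, and every result
embeds content hashes of its inputs.

### Stage composition: layers and lines

Several interventions can be available for one sub-condition and stage.

* **Layers** are mutually independent: combined success is
  $1 - \prod_i (1 - s_i)$, which is permutation-invariant by construction.
* **Lines** form an ordered cascade: line 1 is received with probability
  $c_1$; line $k$ is offered only to those who *received and failed* line
  $k-1$, so the administered fractions are $a_1 = c_1$,
  $a_k = a_{k-1}(1 - e_{k-1})\,c_k$ and the cascade succeeds with probability
  $\sum_k a_k e_k$. People who never received line $k-1$ drop out — this
  makes lines numerically distinct from layers and genuinely
  order-dependent.

When layers and line groups coexist at one stage, each line group first
collapses to its cascade success and then enters the layer product as one
more independent term. The source material does not state a joint formula
for this case; independent combination is this package's design choice,
forced in part by the requirement that layer order be irrelevant.

Usage constraints are enforced per sub-condition pathway: a single-use
intervention (a cesarean delivery) may appear only once, while the same
agent may legitimately recur with different timing tags (oxytocin as
third-stage prophylaxis and again as hemorrhage treatment).

### The cascade semantics

* **Prevention** moves would-be cases to the condition-negative pool:
  positive mass is $m I (1 - s_{\mathrm{prev}})$. Prevented individuals
  carry zero mortality risk from the sub-condition.
* **Diagnosis** gates everything downstream: undiagnosed cases can receive
  neither treatment nor transfer and die at $q_u$. Diagnostic efficacy is
  interpreted as sensitivity; false positives are not granted treatment
  benefit, and since the model tracks no treatment harms or costs,
  specificity is not modelled.
* **Transfer** happens once, immediately after diagnosis and before
  treatment, and only *up* the ladder home < clinic < hospital. Movers face
  the destination's treatment penetration/utilization but retain their
  origin's prevention history. Chained transfers are disallowed (the
  source describes a single referral step).
* **Treatment** splits diagnosed mass by the composed stage success.
  Successful treatment maps a case to $q_t$ (default 0) rather than deleting
  it — efficacy is success of *treatment*, not survival, so residual
  mortality is a parameter.

### Fetal and neonatal benefit of maternal treatment

A maternal treatment can additionally benefit the fetus
(`fetal_efficacy`) or the neonate (`neonatal_efficacy`): conditional on an
intervention succeeding for the mother, it also delivers its fetal
(neonatal) benefit with that probability, independently per succeeding
intervention. This yields closed forms: for layers
$P(\text{no benefit}) = \prod_i (1 - s_i b_i)$ and for a line group
$1 - \sum_k a_k e_k b_k$, with
$P(\text{success, no benefit}) = P(\text{no benefit}) - P(\text{failure})$.
The treated-with-benefit mass has fetal death rate 0 (link rate 0); the
treated-without-benefit mass uses $f_t$ (the treated link rate); everything
else uses $f_u$ (the untreated link rate). The limiting behaviour is the
intended one: benefit efficacy 1 removes the treated stratum's entire
contribution, benefit efficacy 0 leaves it at the treated rate.

Neonatal sub-conditions receive their own base incidence plus the
maternal-induced incidence, then run through the same cascade with their own
interventions; the dependency is strictly one-way (neonatal outcomes never
feed back into maternal or fetal deaths, enforced at validation).

Link-induced neonatal cases are attributed to the **original delivery
setting**, not the maternal transfer destination. Early in development they
followed the mother's final setting, but that lets a maternal *diagnosis*
alone (with useless treatment) change neonatal outcomes by relocating the
neonate into different neonatal coverage, silently breaking the exact
equivalence "no diagnosis ≡ no treatment" that the model is supposed to
satisfy. Modelling referral as affecting maternal treatment access only is
the conservative choice and restores the exact gate.

## Scenarios, calibration, comparison

A *model definition* (structure: sub-conditions, interventions, transfers)
and a *scenario* (numbers: births, setting mix, all rates and coverages) are
separate, versioned JSON files (`inst/extdata/model-schema.md`). A scenario
is resolved against a model at load; after resolution it is self-contained
and hash-linked to that model, and cross-model comparisons are refused.

* `preset_no_intervention()` zeroes every penetration and utilization; the
  model then collapses to the closed form
  $\text{deaths} = B \, I \, q_u$ per sub-condition, which is how incidences
  are calibrated against *historical* (pre-intervention era) mortality:
  `calibrate_incidence(target, cfr)` inverts it as $I = \text{target}/q_u$,
  rejecting targets above the CFR as infeasible.
* `lives_saved(reference, comparison)` differences expected deaths per
  population type and sub-condition.
* `sensitivity_bounds()` evaluates the scenario's low and high parameter
  variants by two further full deterministic runs — no interval arithmetic;
  under monotone variants the two runs bracket the central estimate
  exactly.
* The recommended validation pattern is the four-scenario ladder:
  no-intervention (historical calibration), current care, high-income
  coverage, and per-intervention change scenarios. With pointwise-ordered
  coverage these produce ordered death totals, which the test suite asserts.

## The microsimulation oracle

`microsim()` is a seeded individual-level Monte Carlo re-implementation of
the same rules — per-individual Bernoulli draws for setting, onset, receipt,
success, benefit, diagnosis, transfer and death, with line cascades walked
event by event. It shares none of the analytic engine's composition
formulas and exists purely for verification (`oracle_compare()` reports
per-(sub-condition, population) z-scores under the binomial standard
error). The production model itself is deterministic by design.

The acceptance suite compares 50 random configurations at $n = 10^5$ with a
4-standard-error flag threshold. Because that is ~1750 simultaneous
comparisons, a single-stage 4-SE rule has a roughly 10% chance of one false
alarm per suite run; the suite therefore uses a two-stage design in which a
stage-1 flag must reproduce at $n = 10^6$ under an independently derived
seed. A genuine engine bias reproduces with a larger $|z|$; a sampling tail
does not. (The one stage-1 flag observed during development was verified to
be exactly such a tail: $z = 4.04$ at $n=10^5$, $z = -1.13$ and $0.17$ on
two independent $n=10^6$ replicates.) Seeds are fixed in the tests and were
not selected against outcomes. The oracle uses one RNG stream per run with a
fixed evaluation order, which fulfils the determinism contract (same seed
and configuration → identical stream) without per-individual substreams.

## The synthetic world

The shipped default model encodes the standard condition inventory for this
domain — maternal obstructed labor, infection (sepsis, syphilis, malaria),
hemorrhage (placental abruption, placenta previa, ruptured uterus,
lacerations, atonic uterus, retained placenta), hypertensive disorders and
fetal distress; neonatal infection, birth asphyxia and preterm birth, with
IUGR/RDS/IVH/NEC kept as zeroed structural leaves. **Every number in it is a
synthetic placeholder**: the published source prints no parameter tables
(its values live in an unpublished data version), so the shipped values were
chosen once to be plausible in scale for a low-resource setting (incidences
0.5–10%, untreated CFRs 0.2–30%, hospital-skewed availability,
cesarean-class surgery hospital-only and single-use) and are not revisited.
A green test therefore establishes the *engine's* correctness — mass
conservation, gating, monotonicity, oracle agreement — not the realism of
any particular death count.

`generate_random_params()` draws whole scenario parameterizations from fixed
uniform ranges (incidence 0.01–0.15, untreated CFR 0.02–0.30, treated CFR at
most 30% of untreated, coverage 0–0.9 penetration and 0.2–1 utilization,
efficacy 0.3–0.95, outgoing transfer mass at most 0.8). Penetration and
utilization are sorted so availability never decreases up the care ladder;
this "facilities are at least as equipped as homes" assumption is what makes
*increasing an upward transfer probability* provably never harmful, and it
is the regime the tests certify. With arbitrary unordered coverage a
transfer could move patients to worse care and that monotonicity would be
false — by design, not by bug.

What the generator does **not** emulate: correlation between coverages of
related interventions, comorbidity (each sub-condition is evaluated
independently; one cesarean may be double-counted across two co-occurring
sub-conditions), within-pregnancy time dynamics, morbidity outcomes, and
stochastic variation in population flows.

## Numerical choices

* Probabilities are decimals in $[0,1]$ everywhere; files never contain
  percentages.
* Mass conservation is asserted internally after every split at $10^{-9}$
  relative tolerance, and the audit trail (`strata_trace`) lets tests
  recompute it independently.
* The diagnosis gate ("zero diagnostic success ≡ zero treatment success")
  holds exactly in real arithmetic; tests assert it at $10^{-12}$ relative
  tolerance because the two zeroings traverse different summation orders.
* Calibration round-trips are exact ($10^{-12}$ relative) because the
  no-intervention model is a product of two numbers.
* Degenerate inputs: empty intervention sets compose to stage success 0;
  `births = 0` propagates zero masses; transfer rule sets summing above 1
  are configuration errors, not renormalised.
* An optional scalar `adjustment` on `run_scenario()` scales reported totals
  only (default 1), exposing the "adjusted for causes outside the model"
  step sometimes needed when matching all-cause envelopes; per-sub-condition
  entries are never adjusted.

## Known limitations

* No comorbidity, cost, dose, supply-chain or DALY accounting.
* Untreated CFRs are setting-independent (the source does not state
  otherwise; if care quality differences matter beyond intervention access,
  they must be expressed through coverage).
* Transfers are single-step and upward only.
* The shipped parameter values are placeholders; any substantive use
  requires a calibrated scenario file.
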