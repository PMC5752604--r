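# File formats (schema_version 1.0)

Both file kinds are JSON with a top-level `schema_version` field; unknown
versions are rejected at load. All probabilities are decimals in `[0, 1]`,
never percentages. The three care settings are always `home`, `clinic`,
`hospital`, in that (strictly increasing capability) order.

## Model definition (`load_model()` / `write_model()`)

```jsonc
{
  "schema_version": "1.0",
  "sub_conditions": [
    {
      "id": "atonic_uterus",                // unique
      "condition_id": "maternal_hemorrhage",// parent cause grouping
      "population": "maternal",             // "maternal" | "neonatal"
      "unprevented_incidence": 0.08,        // per pregnancy, no prevention
      "untreated_cfr": 0.05,                // death | condition, no success
      "treated_cfr": 0.003,                 // death | successful treatment
      "fetal_death_rate_untreated": 0.0,    // maternal sub-conditions only
      "fetal_death_rate_treated": 0.0,      // must be <= untreated rate
      "neonatal_links": {"birth_asphyxia": 0.3},          // optional
      "neonatal_links_treated": {"birth_asphyxia": 0.3}   // <= untreated link
    }
  ],
  "interventions": [
    {
      "id": "oxytocin",
      "kind": "treatment",                  // preventive|diagnostic|treatment
      "targets": ["atonic_uterus"],
      "efficacy": 0.7,                      // one value, setting-independent
      "penetration": {"home": 0, "clinic": 0.5, "hospital": 0.8},
      "utilization": {"home": 0, "clinic": 0.8, "hospital": 0.8},
      "fetal_efficacy": 0,                  // treatment's fetal benefit
      "neonatal_efficacy": 0,               // treatment's neonatal benefit
      "composition": {"mode": "line", "order": 1}, // or {"mode": "layer"}
      "single_use": false,                  // at most once per pathway
      "timing_tags": ["postpartum_treatment"] // legitimises id re-use
    }
  ],
  "transfers": [
    { "from": "home", "to": "hospital",     // strictly up the ladder
      "probability": 0.15,                  // given positive diagnosis
      "subconditions": ["atonic_uterus"] }  // per (sub, from): sum <= 1
  ]
}
```

Constraints enforced at load: every referenced id resolves; `treated_cfr <=
untreated_cfr` and the fetal analogue; neonatal sub-conditions carry no fetal
rates or links; `(id, kind)` pairs are unique but the same `id` may recur
across kinds with distinct `timing_tags`; line orders within one
(sub-condition, kind) group are unique and contiguous from 1; single-use
interventions appear at most once per sub-condition pathway unless timing
tags differ; transfers move strictly upward and outgoing probabilities per
(sub-condition, origin) sum to at most 1.

## Scenario parameters (`load_scenario()` / `write_scenario()`)

A scenario file stores *overrides*; everything not mentioned defaults to the
model definition it is resolved against. `write_scenario()` emits the fully
resolved tables, so written files round-trip field-for-field.

```jsonc
{
  "schema_version": "1.0",
  "scenario_id": "current_care_synthetic",
  "births": 100000,
  "setting_distribution": {"home": 0.5, "clinic": 0.3, "hospital": 0.2}, // sums to 1
  "coverage": [                             // optional overrides
    { "intervention": "mgso4/treatment",    // uid "id/kind" (or bare id)
      "setting": "clinic",                  // or "all"
      "penetration": 1, "utilization": 1 }
  ],
  "efficacy": {"mgso4/treatment": 0.6},     // optional, per intervention
  "rates": [                                // optional, per sub-condition
    { "subcondition": "sepsis", "unprevented_incidence": 0.05,
      "untreated_cfr": 0.15, "treated_cfr": 0.01 }
  ],
  "transfers": [                            // optional patches/additions
    { "from": "home", "to": "hospital",
      "subcondition": "preeclampsia_eclampsia", "probability": 0.8 }
  ],
  "bounds": {                               // optional low/high variants
    "low":  { "rates": [ /* same format */ ] },
    "high": { "rates": [ /* same format */ ], "coverage": [ /* ... */ ] }
  }
}
```

The shipped example files under `extdata/scenarios/` use this format; all
their numbers are synthetic placeholders.
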