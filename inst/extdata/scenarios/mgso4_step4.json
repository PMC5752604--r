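{
  "schema_version": "1.0",
  "scenario_id": "mgso4_step4_plus_transfer",
  "births": 100000,
  "setting_distribution": {
    "home": 0.5,
    "clinic": 0.3,
    "hospital": 0.2
  },
  "coverage": [
    {
      "intervention": "mgso4/treatment",
      "setting": "clinic",
      "penetration": 1,
      "utilization": 1
    },
    {
      "intervention": "mgso4/treatment",
      "setting": "hospital",
      "penetration": 1,
      "utilization": 1
    },
    {
      "intervention": "bp_proteinuria_screen/diagnostic",
      "setting": "all",
      "penetration": 1,
      "utilization": 1
    },
    {
      "intervention": "cesarean_or_induction/treatment",
      "setting": "clinic",
      "penetration": 1,
      "utilization": 1
    },
    {
      "intervention": "cesarean_or_induction/treatment",
      "setting": "hospital",
      "penetration": 1,
      "utilization": 1
    }
  ],
  "transfers": [
    {
      "from": "home",
      "to": "clinic",
      "subcondition": "preeclampsia_eclampsia",
      "probability": 0.1
    },
    {
      "from": "home",
      "to": "hospital",
      "subcondition": "preeclampsia_eclampsia",
      "probability": 0.8
    },
    {
      "from": "clinic",
      "to": "hospital",
      "subcondition": "preeclampsia_eclampsia",
      "probability": 0.8
    }
  ]
}
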