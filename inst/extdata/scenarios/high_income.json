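{
  "schema_version": "1.0",
  "scenario_id": "high_income_synthetic",
  "births": 100000,
  "setting_distribution": {
    "home": 0.5,
    "clinic": 0.3,
    "hospital": 0.2
  },
  "coverage": [
    {
      "intervention": "oxytocin/preventive",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "uterine_massage/preventive",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "clean_delivery_kit/preventive",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "itn_bednet/preventive",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "chlorhexidine_cord_care/preventive",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "partograph/diagnostic",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "fever_screen/diagnostic",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "syphilis_rdt/diagnostic",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "malaria_rdt/diagnostic",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "blood_loss_assessment/diagnostic",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "bp_proteinuria_screen/diagnostic",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "fetal_heart_monitoring/diagnostic",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "newborn_danger_signs/diagnostic",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "cesarean_delivery/treatment",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "antibiotics_oral/treatment",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "antibiotics_iv/treatment",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "penicillin/treatment",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "act_antimalarial/treatment",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "emergency_cesarean_hemorrhage/treatment",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "suturing/treatment",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "oxytocin/treatment",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "misoprostol/treatment",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "balloon_tamponade/treatment",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "manual_removal_placenta/treatment",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "mgso4/treatment",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "cesarean_or_induction/treatment",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "antibiotics_neonatal/treatment",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "bag_mask_resuscitation/treatment",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "advanced_resuscitation/treatment",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "kangaroo_care/treatment",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    },
    {
      "intervention": "antenatal_corticosteroids/treatment",
      "setting": "all",
      "penetration": 0.95,
      "utilization": 0.95
    }
  ]
}
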