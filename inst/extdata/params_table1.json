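{
  "ttr_sdw": 0.64,
  "frac_below_of_out_of_range": 0.54,
  "gtw_ttr_uplift": 0.073,
  "p_bleed_annual_inrange": 0.014,
  "rr_bleed_out_of_range": 4.7,
  "rr_bleed_dab": 0.93,
  "bleed_split_warfarin": {
    "intracranial": 0.42,
    "extracranial": 0.58
  },
  "bleed_split_dab_raw": {
    "intracranial": 0.126,
    "extracranial": 0.904
  },
  "p_te_annual_inrange": 0.024,
  "rr_te_subtherapeutic": 3.5,
  "rr_te_other_out_of_range": 0.9,
  "rr_te_dab": {
    "stroke_se": 0.66,
    "mi": 1.38,
    "pe": 1.61,
    "dvt": 1
  },
  "te_split_warfarin": {
    "stroke": 0.525,
    "mi": 0.125,
    "pe": 0.3,
    "dvt": 0.05
  },
  "ich_outcomes": {
    "no_deficit": 0.08,
    "mild": 0.16,
    "severe": 0.34,
    "death_first_month": 0.42
  },
  "p_death_extracranial": 0.02,
  "stroke_outcomes": {
    "death_m1": 0.083,
    "death_m2": 0.056,
    "death_m3": 0.056,
    "severe": 0.402,
    "mild": 0.425,
    "none": 0.091
  },
  "p_death_pe": 0.12,
  "p_death_dvt": 0.06,
  "p_death_mi": 0.07,
  "stop_after_gi_bleed_days": 30,
  "cost_dab_daily": 3.2,
  "cost_warfarin_daily": 0.074,
  "cost_lmwh_course": 27.9,
  "cost_inr_month_sdw_y1": 8.06,
  "cost_inr_month_gtw_y1": 5,
  "cost_inr_month_later": 4.03,
  "cost_genotyping": 615,
  "event_costs": {
    "stroke_none": 845,
    "stroke_mild": 23772,
    "stroke_severe": 42620,
    "ich_none": 1067,
    "ich_mild": 21218,
    "ich_severe": 36451,
    "subdural": 31942,
    "extracranial_bleed": 8146,
    "dvt": 2576,
    "pe": 8799,
    "mi": 7177
  },
  "post_event_monthly": {
    "severe": 6259,
    "mild": 1855
  },
  "utilities": {
    "no_event_warfarin": 0.95,
    "no_event_dab": 0.95,
    "ich_none": 0.95,
    "ich_mild": 0.75,
    "ich_severe": 0.51,
    "extracranial": 0.8,
    "stroke_none": 0.95,
    "stroke_mild": 0.75,
    "stroke_severe": 0.39,
    "mi": 0.84,
    "pe": 0.76,
    "dvt": 0.84
  },
  "globals": {
    "horizon_days": 1825,
    "discount_annual": 0.03,
    "cohort_size": 10000,
    "n_replicates": 1000,
    "psa_cohort_size": 5000,
    "psa_iterations": 1000,
    "wtp_threshold": 50000,
    "age_mean": 64,
    "age_sd": 8
  },
  "flags": {
    "literal_rr_labels": false,
    "literal_ich_utilities": false,
    "additive_ttr_uplift": false,
    "background_mortality": false
  }
}
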