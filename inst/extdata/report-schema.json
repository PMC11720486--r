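{
  "title": "awarekit analysis report",
  "type": "object",
  "required": {
    "provenance": {"type": "object",
                   "required": ["seed", "n_participants", "blocks"]},
    "stages": {"type": "object"}
  },
  "stage_conventions": {
    "priming_*": ["mean_effect_ms", "bf10", "n"],
    "dprime_obj_*": ["mean_dprime", "bf10", "n"],
    "regression_*": ["intercept_mean_ms", "intercept_ci95", "slope_mean",
                     "bf10_intercept", "rhat_max"],
    "grt_*": ["selected_constraints", "aic", "pct_accounted",
              "ideal_criterion", "d_cond_at_criterion"],
    "common_dprime": ["anova_bf_incl", "anova_model_bf10", "correlations"],
    "failed stage": ["error"]
  }
}
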