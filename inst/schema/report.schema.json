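{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "tumgrowth pipeline report",
  "type": "object",
  "required": ["scenario", "seed", "package_version", "r_version"],
  "properties": {
    "scenario": {
      "type": "string",
      "enum": ["simulate-then-fit", "fit-only", "hill", "survival"]
    },
    "seed": { "type": "integer" },
    "package_version": { "type": "string" },
    "r_version": { "type": "string" },
    "fit": {
      "type": "object",
      "required": ["estimates"],
      "properties": {
        "estimates": {
          "type": "object",
          "required": ["k_growth_mean", "omega_k", "v_max_mean",
                       "omega_vmax", "eff_mean", "omega_eff", "gamma",
                       "sigma_prop", "sigma_add"],
          "additionalProperties": { "type": "number" }
        },
        "covariate_effects": { "type": "object" },
        "accept": { "type": "object" }
      }
    },
    "treatment_slowing_factor": { "type": ["number", "null"] },
    "lrt": {
      "type": "object",
      "required": ["statistic", "df", "p_value"],
      "properties": {
        "statistic": { "type": "number", "minimum": 0 },
        "df": { "type": "integer", "minimum": 1 },
        "p_value": { "type": "number", "minimum": 0, "maximum": 1 }
      }
    },
    "hill": {
      "type": "object",
      "required": ["ec50", "hill_n", "top"],
      "additionalProperties": { "type": "number" }
    },
    "survival": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["group", "reference", "statistic", "p_value"]
      }
    }
  }
}
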