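{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "dappmap run configuration",
  "description": "Structural schema of the run configuration consumed by dappmap_run(); enforced by validate_run_config().",
  "type": "object",
  "additionalProperties": false,
  "properties": {
    "ses_type": {"enum": ["rural", "peri_urban"]},
    "climate_level": {"enum": [0, 1, 2]},
    "seed": {"type": "integer"},
    "schedule": {
      "type": "object",
      "properties": {
        "start": {"type": "integer"},
        "horizon": {"type": "integer", "minimum": 1},
        "step": {"type": "integer", "minimum": 1}
      },
      "required": ["start", "horizon", "step"]
    },
    "grid_n": {"type": "integer", "minimum": 2},
    "security_aggregate": {"enum": ["mean", "min"]},
    "optimality_aggregate": {"enum": ["mean", "terminal"]},
    "check_every_step": {"type": "boolean"},
    "top_fraction": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
    "max_pathways": {"type": "number"},
    "contrast": {"enum": ["RH_vs_PH", "PH_vs_RH", "TH_vs_SH", "SH_vs_TH"]},
    "perturbation_size": {"type": "number", "minimum": 0},
    "pathway": {"type": "array", "items": {"type": ["string", "integer"]}},
    "output_dir": {"type": "string"}
  }
}
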