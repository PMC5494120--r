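{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "admorph evaluation report",
  "type": "object",
  "required": ["classifier", "scheme", "repeats", "seed", "n_subjects",
               "n_features", "classes", "pca", "per_fold", "aggregate"],
  "properties": {
    "classifier": {"type": "string"},
    "scheme": {"enum": ["split7030", "kfold10", "loo"]},
    "repeats": {"type": "integer", "minimum": 1},
    "seed": {"type": "integer"},
    "n_subjects": {"type": "integer", "minimum": 2},
    "n_features": {"type": "integer", "minimum": 0},
    "classes": {"type": "array", "items": {"type": "string"},
                "minItems": 2},
    "pca": {
      "type": "object",
      "required": ["enabled", "standardize"],
      "properties": {
        "enabled": {"type": "boolean"},
        "k": {"type": ["integer", "array", "null"]},
        "standardize": {"type": "boolean"}
      }
    },
    "per_fold": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["acc", "sen", "spe", "confusion"],
        "properties": {
          "acc": {"type": "number", "minimum": 0, "maximum": 100},
          "sen": {"type": ["number", "null"]},
          "spe": {"type": ["number", "null"]},
          "confusion": {"type": "array",
                        "items": {"type": "array",
                                  "items": {"type": "integer"}}}
        }
      }
    },
    "aggregate": {
      "type": "object",
      "required": ["mean_acc", "mean_sen", "mean_spe", "sd_acc"],
      "properties": {
        "mean_acc": {"type": "number"},
        "mean_sen": {"type": ["number", "null"]},
        "mean_spe": {"type": ["number", "null"]},
        "sd_acc": {"type": "number"}
      }
    },
    "permutation": {
      "type": "object",
      "required": ["observed_acc", "null_acc", "n_perm", "p_value"],
      "properties": {
        "observed_acc": {"type": "number"},
        "null_acc": {"type": "array", "items": {"type": "number"}},
        "n_perm": {"type": "integer", "minimum": 1},
        "p_value": {"type": "number", "exclusiveMinimum": 0, "maximum": 1}
      }
    }
  },
  "additionalProperties": false
}
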