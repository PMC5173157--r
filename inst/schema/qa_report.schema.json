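{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Delineation QA report",
  "type": "object",
  "required": ["overlapping_analysis", "time_analysis", "decision"],
  "properties": {
    "overlapping_analysis": {
      "type": "object",
      "required": ["group_a", "group_b"],
      "properties": {
        "group_a": {"$ref": "#/definitions/overlap_summary"},
        "group_b": {"$ref": "#/definitions/overlap_summary"}
      }
    },
    "time_analysis": {
      "type": "object",
      "required": ["group_a", "group_b", "saving_ratio_of_means_pct",
                   "saving_per_patient_mean_pct", "paired_t"],
      "properties": {
        "group_a": {"$ref": "#/definitions/time_summary"},
        "group_b": {"$ref": "#/definitions/time_summary"},
        "saving_ratio_of_means_pct": {"type": "number"},
        "saving_per_patient_mean_pct": {"type": "number"},
        "saving_estimator_used": {"type": "string"},
        "paired_t": {
          "type": "object",
          "required": ["mean_diff_min", "t_statistic", "p_value"],
          "properties": {
            "mean_diff_min": {"type": "number"},
            "t_statistic": {"type": "number"},
            "df": {"type": "number"},
            "p_value": {"type": "number"},
            "ci95": {"type": "array"}
          }
        }
      }
    },
    "decision": {
      "type": "object",
      "required": ["observed", "thresholds", "met", "n_met",
                   "mandatory_met", "accepted"],
      "properties": {
        "observed": {
          "type": "object",
          "required": ["mdsc", "mshd_mean_mm", "tt_saving_pct"],
          "properties": {
            "mdsc": {"type": "number"},
            "mshd_mean_mm": {"type": "number"},
            "tt_saving_pct": {"type": "number"}
          }
        },
        "thresholds": {
          "type": "object",
          "required": ["dsc_min", "mshd_max_mm", "tt_saving_min_pct"],
          "properties": {
            "dsc_min": {"type": "number"},
            "mshd_max_mm": {"type": "number"},
            "tt_saving_min_pct": {"type": "number"}
          }
        },
        "met": {
          "type": "object",
          "required": ["mdsc", "mshd", "tt_saving"],
          "properties": {
            "mdsc": {"type": "boolean"},
            "mshd": {"type": "boolean"},
            "tt_saving": {"type": "boolean"}
          }
        },
        "n_met": {"type": "integer"},
        "mandatory_met": {"type": "boolean"},
        "accepted": {"type": "boolean"}
      }
    },
    "sensitivity": {
      "type": "object",
      "required": ["removed_ids", "summary"],
      "properties": {
        "removed_ids": {"type": "array"},
        "summary": {"$ref": "#/definitions/overlap_summary"}
      }
    },
    "subgroup": {"type": "object"},
    "flags": {"type": "object"},
    "parameters": {"type": "object"}
  },
  "definitions": {
    "overlap_summary": {
      "type": "object",
      "required": ["mdsc", "dsc_sd", "mshd_mean_mm", "mshd_sd_mm", "n_patients"],
      "properties": {
        "mdsc": {"type": "number"},
        "dsc_sd": {"type": "number"},
        "mshd_mean_mm": {"type": "number"},
        "mshd_sd_mm": {"type": "number"},
        "n_patients": {"type": "integer"}
      }
    },
    "time_summary": {
      "type": "object",
      "required": ["n", "t1", "t2", "tt"],
      "properties": {
        "n": {"type": "integer"},
        "t1": {"$ref": "#/definitions/mean_sd"},
        "t2": {"$ref": "#/definitions/mean_sd"},
        "tt": {"$ref": "#/definitions/mean_sd"}
      }
    },
    "mean_sd": {
      "type": "object",
      "required": ["mean", "sd"],
      "properties": {
        "mean": {"type": "number"},
        "sd": {"type": "number"}
      }
    }
  }
}
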