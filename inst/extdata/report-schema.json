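{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "prisafe workflow report",
  "type": "object",
  "required": ["header", "summary", "outcomes", "testing_plan"],
  "properties": {
    "header": {
      "type": "object",
      "required": ["tool", "version", "config"],
      "properties": {
        "tool": {"type": "string"},
        "version": {"type": "string"},
        "seed": {"type": ["integer", "null"]},
        "config": {"type": "object"}
      }
    },
    "summary": {
      "type": "object",
      "required": ["n", "by_category", "by_disposition"],
      "properties": {
        "n": {"type": "integer", "minimum": 0},
        "by_category": {
          "type": "object",
          "additionalProperties": {"type": "integer", "minimum": 0}
        },
        "by_disposition": {
          "type": "object",
          "additionalProperties": {"type": "integer", "minimum": 0}
        }
      }
    },
    "outcomes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["pri_id", "category", "stage", "disposition"],
        "properties": {
          "pri_id": {"type": "string"},
          "category": {"enum": ["A", "B1", "B2", "C"]},
          "stage": {"enum": ["step1", "step2a", "step2b"]},
          "disposition": {
            "enum": ["no_safety_risk", "testing_required", "action_required"]
          },
          "pri_dose": {"type": ["number", "null"]},
          "limit": {"type": ["number", "null"]},
          "limit_type": {"type": ["string", "null"]},
          "margin": {"type": ["number", "null"]},
          "isf": {"type": ["number", "null"]},
          "rationale": {"type": "string"}
        }
      }
    },
    "testing_plan": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["pri_id", "test_point"],
        "properties": {
          "pri_id": {"type": "string"},
          "test_point": {
            "enum": ["proA_pool", "cex_pool", "viral_filtration_pool"]
          },
          "assay_lod": {"type": ["number", "null"]}
        }
      }
    },
    "unmatched_measurements": {
      "type": "array", "items": {"type": "string"}
    }
  }
}
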