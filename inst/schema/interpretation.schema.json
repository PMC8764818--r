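{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "InterpretationDocument",
  "description": "Statement / evidence-line / provenance triad for a finalized variant pathogenicity assertion.",
  "type": "object",
  "required": ["schema_version", "statement", "evidence_lines", "provenance"],
  "additionalProperties": false,
  "properties": {
    "schema_version": {"type": "string"},
    "statement": {
      "type": "object",
      "required": ["subject", "predicate", "object", "condition",
                   "mode_of_inheritance"],
      "additionalProperties": false,
      "properties": {
        "subject": {"type": "string"},
        "predicate": {"const": "has_pathogenicity"},
        "object": {"enum": ["Pathogenic", "Likely pathogenic",
                            "Uncertain significance", "Likely benign", "Benign"]},
        "condition": {"type": "string", "pattern": "^MONDO:[0-9]{7}$"},
        "mode_of_inheritance": {"type": "string", "pattern": "^HP:[0-9]{7}$"}
      }
    },
    "evidence_lines": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["criterion", "strength", "explanation", "evidence_refs"],
        "additionalProperties": false,
        "properties": {
          "criterion": {"type": "string"},
          "strength": {"enum": ["StandAlone", "VeryStrong", "Strong",
                                "Moderate", "Supporting"]},
          "explanation": {"type": "string"},
          "evidence_refs": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "provenance": {
      "type": "object",
      "required": ["agent", "agent_kind", "captured_at", "status",
                   "computed_classification", "conflict_flag"],
      "additionalProperties": false,
      "properties": {
        "agent": {"type": "string"},
        "agent_kind": {"enum": ["individual", "affiliation"]},
        "captured_at": {"type": "string"},
        "status": {"enum": ["Approved", "Published"]},
        "computed_classification": {"enum": ["Pathogenic", "Likely pathogenic",
                                             "Uncertain significance",
                                             "Likely benign", "Benign"]},
        "conflict_flag": {"type": "boolean"}
      }
    }
  }
}
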