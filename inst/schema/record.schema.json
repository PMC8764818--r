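{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ClassificationRecord",
  "type": "object",
  "required": ["record_id", "variant", "disease", "moi", "owner", "evaluations",
               "evidence", "status", "computed_classification", "conflict_flag",
               "created", "modified"],
  "properties": {
    "record_id": {"type": "string"},
    "variant": {
      "type": "object",
      "properties": {
        "caid": {"type": "string", "pattern": "^CA[0-9]+$"},
        "clinvar_id": {"type": "string", "pattern": "^[0-9]+$"},
        "hgvs_names": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["reference", "hgvs", "is_mane_select"],
            "properties": {
              "reference": {"type": "string"},
              "hgvs": {"type": "string"},
              "protein_hgvs": {"type": "string"},
              "is_mane_select": {"type": "boolean"}
            }
          }
        },
        "gene_symbol": {"type": "string"}
      },
      "anyOf": [{"required": ["caid"]}, {"required": ["clinvar_id"]}]
    },
    "disease": {
      "type": "object",
      "required": ["mondo_id"],
      "properties": {
        "mondo_id": {"type": "string", "pattern": "^MONDO:[0-9]{7}$"},
        "label": {"type": "string"}
      }
    },
    "moi": {
      "type": "object",
      "required": ["hpo_id"],
      "properties": {
        "hpo_id": {"type": "string", "pattern": "^HP:[0-9]{7}$"},
        "label": {"type": "string"}
      }
    },
    "owner": {
      "type": "object",
      "required": ["owner_id", "kind", "is_vcep"],
      "properties": {
        "owner_id": {"type": "string"},
        "kind": {"enum": ["individual", "affiliation"]},
        "is_vcep": {"type": "boolean"},
        "members": {"type": "array", "items": {"type": "string"}}
      }
    },
    "evaluations": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["code", "status", "effective_strength"],
        "properties": {
          "code": {"type": "string"},
          "status": {"enum": ["NotEvaluated", "Met", "NotMet"]},
          "effective_strength": {"enum": ["StandAlone", "VeryStrong", "Strong",
                                          "Moderate", "Supporting"]},
          "explanation": {"type": "string"}
        }
      }
    },
    "evidence": {"type": "array", "items": {"type": "string"}},
    "status": {"enum": ["InProgress", "Provisional", "Approved",
                        "NewProvisional", "Published"]},
    "published": {"type": "boolean"},
    "scv": {"type": "string", "pattern": "^SCV"},
    "computed_classification": {"enum": ["Pathogenic", "Likely pathogenic",
                                         "Uncertain significance",
                                         "Likely benign", "Benign"]},
    "conflict_flag": {"type": "boolean"},
    "override_classification": {"enum": ["Pathogenic", "Likely pathogenic",
                                         "Uncertain significance",
                                         "Likely benign", "Benign"]},
    "override_rationale": {"type": "string"},
    "created": {"type": "string"},
    "modified": {"type": "string"}
  }
}
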