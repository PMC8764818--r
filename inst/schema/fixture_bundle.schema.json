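{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "FixtureBundle",
  "description": "Local JSON stand-in for the external variant evidence sources, keyed by CAid.",
  "type": "object",
  "required": ["variants"],
  "properties": {
    "generator": {
      "type": "object",
      "properties": {
        "seed": {"type": "integer"},
        "n_variants": {"type": "integer"}
      }
    },
    "variants": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "anyOf": [{"required": ["caid"]}, {"required": ["clinvar_id"]}],
        "properties": {
          "caid": {"type": "string", "pattern": "^CA[0-9]+$"},
          "clinvar_id": {"type": "string", "pattern": "^[0-9]+$"},
          "gene_symbol": {"type": "string"},
          "transcripts": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["id", "hgvs_c"],
              "properties": {
                "id": {"type": "string"},
                "hgvs_c": {"type": "string"},
                "hgvs_p": {"type": "string"},
                "is_mane_select": {"type": "boolean"},
                "consequence": {"type": "string"}
              }
            }
          },
          "genomic_hgvs": {"type": "string"},
          "clinvar_summary": {
            "type": "object",
            "properties": {
              "overall_interpretation": {"type": "string"},
              "n_submissions": {"type": "integer"}
            }
          },
          "allele_frequencies": {
            "type": "object",
            "additionalProperties": {"type": "number", "minimum": 0, "maximum": 1}
          },
          "insilico_scores": {
            "type": "object",
            "additionalProperties": {"type": "number"}
          },
          "conservation_scores": {
            "type": "object",
            "additionalProperties": {"type": "number"}
          },
          "gene_info": {"type": "object"},
          "scenario": {"enum": ["pathogenic_rich", "benign_rich",
                                "conflicting", "empty"]}
        }
      }
    }
  }
}
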