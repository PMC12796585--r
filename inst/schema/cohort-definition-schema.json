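{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "ehrconsult/cohort-definition/v1",
  "title": "Cohort definition",
  "type": "object",
  "required": ["name", "criteria"],
  "properties": {
    "name": { "type": "string", "minLength": 1 },
    "criteria": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["domain", "code_prefix"],
        "properties": {
          "domain": {
            "enum": ["diagnosis", "procedure", "medication", "observation"]
          },
          "code_system": { "type": ["string", "null"] },
          "code_prefix": {
            "oneOf": [
              { "type": "string", "minLength": 1 },
              { "type": "array", "items": { "type": "string", "minLength": 1 }, "minItems": 1 }
            ]
          },
          "mode": { "enum": ["include", "exclude"], "default": "include" },
          "temporal": {
            "enum": ["ever", "on_or_after_index", "before_index"],
            "default": "ever"
          },
          "role": { "enum": ["plain", "index_candidate"], "default": "plain" }
        }
      }
    }
  },
  "description": "At least one include criterion with role index_candidate is required; the earliest event matching any index_candidate criterion becomes the member's index date."
}
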