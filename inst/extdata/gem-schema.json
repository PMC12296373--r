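{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "phylocomm GEM JSON dialect",
  "description": "One-to-one serialisation of the package's GEM type. Exchange convention: single-metabolite reactions with coefficient -1; negative flux = uptake.",
  "type": "object",
  "required": ["id", "metabolites", "reactions", "objective_id"],
  "properties": {
    "id": { "type": "string", "minLength": 1 },
    "metabolites": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "compartment"],
        "properties": {
          "id": { "type": "string", "minLength": 1 },
          "name": { "type": "string" },
          "compartment": { "type": "string", "minLength": 1 }
        }
      }
    },
    "reactions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "stoichiometry"],
        "properties": {
          "id": { "type": "string", "minLength": 1 },
          "stoichiometry": {
            "type": "object",
            "minProperties": 1,
            "additionalProperties": { "type": "number" }
          },
          "lower_bound": { "type": "number", "default": -1000 },
          "upper_bound": { "type": "number", "default": 1000 },
          "is_exchange": { "type": "boolean" },
          "is_biomass": { "type": "boolean", "default": false }
        }
      }
    },
    "objective_id": { "type": "string", "minLength": 1 }
  }
}
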