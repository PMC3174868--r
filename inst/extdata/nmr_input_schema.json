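{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "nmrcase NMR input document",
  "type": "object",
  "additionalProperties": false,
  "required": ["formula", "atoms"],
  "properties": {
    "formula": {
      "type": "string",
      "description": "Molecular formula in Hill notation, e.g. C2H6O"
    },
    "atoms": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "additionalProperties": false,
        "required": ["id", "element", "n_h"],
        "properties": {
          "id": { "type": "string" },
          "element": { "enum": ["C", "N"] },
          "n_h": { "type": ["integer", "null"], "minimum": 0, "maximum": 4 },
          "shift_ppm": { "type": "number", "minimum": 0 },
          "hybridization": { "enum": ["sp3", "sp2", "sp", "open"] }
        }
      }
    },
    "correlations": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "cosy": { "$ref": "#/definitions/pairs" },
        "hmbc": { "$ref": "#/definitions/pairs" },
        "n15hmbc": { "$ref": "#/definitions/pairs" },
        "adequate11": { "$ref": "#/definitions/pairs" }
      }
    },
    "options": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "open_types": { "type": "boolean" },
        "min_ring_size": { "type": "integer", "minimum": 3 },
        "max_results": { "type": "integer", "minimum": 1 },
        "forbid_hetero_hetero": { "type": "boolean" },
        "allow_4bond": { "type": "boolean" }
      }
    }
  },
  "definitions": {
    "pairs": {
      "type": "array",
      "items": {
        "type": "array",
        "items": { "type": "string" },
        "minItems": 2,
        "maxItems": 2
      }
    }
  }
}
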