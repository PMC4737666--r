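{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "intrinsic-connectome-embedding",
  "description": "Viewer-ready export of a 3-D connectome embedding: one record per node with its embedded coordinates and metadata, plus an edge list over all nonzero coupling weights (0-based node indices).",
  "type": "object",
  "required": ["format", "version", "method", "n", "nodes", "edges"],
  "properties": {
    "format": { "const": "intrinsic-connectome-embedding" },
    "version": { "type": "integer" },
    "method": { "enum": ["MDS", "Isomap"] },
    "n": { "type": "integer", "minimum": 1 },
    "nodes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["label", "xyz", "rich_club"],
        "properties": {
          "label": { "type": "string" },
          "lobe": { "type": ["string", "null"] },
          "xyz": {
            "type": "array",
            "items": { "type": "number" },
            "minItems": 3,
            "maxItems": 3
          },
          "rich_club": { "type": "boolean" }
        }
      }
    },
    "edges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["i", "j", "weight"],
        "properties": {
          "i": { "type": "integer", "minimum": 0 },
          "j": { "type": "integer", "minimum": 0 },
          "weight": { "type": "number", "exclusiveMinimum": 0 }
        }
      }
    }
  }
}
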