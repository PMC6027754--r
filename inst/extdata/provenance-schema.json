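{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "provdag-provenance-v1",
  "title": "provdag provenance document, version 1",
  "type": "object",
  "required": ["format", "version", "nodes", "edges", "templates", "groups", "analyses"],
  "properties": {
    "format": { "const": "provdag-provenance" },
    "version": { "const": 1 },
    "nodes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "kind", "label", "attributes"],
        "properties": {
          "id": { "type": "string" },
          "kind": { "enum": ["TOOL", "FILE", "RAW"] },
          "label": { "type": "string" },
          "group_id": { "type": "string" },
          "attributes": { "type": "object", "additionalProperties": { "type": "string" } }
        }
      }
    },
    "edges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["source", "target"],
        "properties": {
          "source": { "type": "string" },
          "target": { "type": "string" }
        }
      }
    },
    "templates": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "name", "tool_names", "inputs_per_group", "outputs_per_group"],
        "properties": {
          "id": { "type": "string" },
          "name": { "type": "string" },
          "tool_names": { "type": "array", "items": { "type": "string" }, "minItems": 1 },
          "inputs_per_group": { "type": "integer", "minimum": 1 },
          "outputs_per_group": { "type": "integer", "minimum": 1 }
        }
      }
    },
    "groups": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "analysis_id", "member_node_ids", "input_file_ids"],
        "properties": {
          "id": { "type": "string" },
          "analysis_id": { "type": "string" },
          "member_node_ids": { "type": "array", "items": { "type": "string" } },
          "input_file_ids": { "type": "array", "items": { "type": "string" } }
        }
      }
    },
    "analyses": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "template_id", "execution_time", "group_ids"],
        "properties": {
          "id": { "type": "string" },
          "template_id": { "type": "string" },
          "execution_time": { "type": "integer" },
          "group_ids": { "type": "array", "items": { "type": "string" }, "minItems": 1 },
          "user": { "type": "string" }
        }
      }
    }
  },
  "description": "Semantic invariants beyond this structural schema (edge alternation, acyclicity, hierarchy partition) are enforced by validate_graph()."
}
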