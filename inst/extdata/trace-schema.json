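{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "handmetrics motion-trace dialect, schema_version 1.0",
  "description": "JSON-lines file: line 1 is the header object, every further line one frame object. Positions are mm, quaternions scalar-first (w,x,y,z). Bone frames sit at bone begin points; the tip frame is the distal bone's end point with the distal orientation.",
  "definitions": {
    "vec3": {"type": "array", "items": {"type": "number"}, "minItems": 3, "maxItems": 3},
    "quat": {"type": "array", "items": {"type": "number"}, "minItems": 4, "maxItems": 4},
    "bone": {
      "type": "object",
      "required": ["bone", "begin_mm", "end_mm", "quaternion"],
      "properties": {
        "bone": {"enum": ["metacarpal", "proximal", "intermediate", "distal"]},
        "begin_mm": {"$ref": "#/definitions/vec3"},
        "end_mm": {"$ref": "#/definitions/vec3"},
        "quaternion": {"$ref": "#/definitions/quat"}
      }
    },
    "header": {
      "type": "object",
      "required": ["schema_version", "units", "capture_rate", "device_label"],
      "properties": {
        "schema_version": {"const": "1.0"},
        "units": {
          "type": "object",
          "properties": {"position": {"const": "mm"}, "angle": {"const": "deg"}}
        },
        "capture_rate": {"type": "number", "exclusiveMinimum": 0},
        "device_label": {"type": "string"}
      }
    },
    "frame": {
      "type": "object",
      "required": ["timestamp_us", "side"],
      "properties": {
        "timestamp_us": {"type": "number", "minimum": 0},
        "side": {"enum": ["left", "right"]},
        "wrist": {
          "type": "object",
          "required": ["position_mm", "quaternion"],
          "properties": {
            "position_mm": {"$ref": "#/definitions/vec3"},
            "quaternion": {"$ref": "#/definitions/quat"}
          }
        },
        "fingers": {
          "type": "object",
          "additionalProperties": false,
          "patternProperties": {
            "^(thumb|index|middle|ring|pinky)$": {
              "type": "object",
              "required": ["bones"],
              "properties": {
                "bones": {"type": "array", "items": {"$ref": "#/definitions/bone"}}
              }
            }
          }
        }
      }
    }
  }
}
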