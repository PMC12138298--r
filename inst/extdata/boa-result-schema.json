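{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "https://boa.example.org/schema/boa-result.json",
  "title": "BOA analysis result",
  "description": "Canonical JSON document for one AI body-and-organ analysis of one CT study. Coded fields carry labels resolved against the shipped value sets; a thin adapter layer can map vendor dialects onto this schema.",
  "type": "object",
  "required": ["patient_id", "study_uid", "series", "model"],
  "properties": {
    "patient_id": { "type": "string", "minLength": 1 },
    "study_uid": { "$ref": "#/$defs/dicom_uid" },
    "started": { "type": "string", "format": "date-time" },
    "series": {
      "type": "array", "minItems": 1,
      "items": {
        "type": "object",
        "required": ["series_uid"],
        "properties": {
          "series_uid": { "$ref": "#/$defs/dicom_uid" },
          "modality": { "type": "string", "default": "CT" },
          "number_of_instances": { "type": "integer", "minimum": 1 },
          "body_site": { "type": "string" }
        }
      }
    },
    "regions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["body_site", "measurement_mode", "tissues"],
        "properties": {
          "body_site": { "type": "string", "description": "display from BCABodySiteVS" },
          "measurement_mode": { "type": "string", "description": "display from BCAMeasurementsVS" },
          "slice_range": {
            "type": "object",
            "required": ["low", "high"],
            "properties": {
              "low": { "type": "integer", "minimum": 1 },
              "high": { "type": "integer", "minimum": 1 }
            }
          },
          "tissues": {
            "type": "array", "minItems": 1,
            "items": {
              "type": "object",
              "required": ["tissue", "volume_ml"],
              "properties": {
                "tissue": { "type": "string", "description": "display from BCATissueVS" },
                "volume_ml": { "type": "number", "minimum": 0 },
                "mean_density_hu": { "type": "number", "minimum": -1024, "maximum": 3071 }
              }
            }
          }
        }
      }
    },
    "organs": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["structure", "volume_ml"],
        "properties": {
          "structure": { "type": "string", "description": "display from BodyStructureLandmarkVS" },
          "volume_ml": { "type": "number", "minimum": 0 }
        }
      }
    },
    "model": {
      "type": "object",
      "required": ["name", "version"],
      "properties": {
        "name": { "type": "string", "minLength": 1 },
        "version": { "type": "string", "minLength": 1 },
        "parameters": { "type": "object", "additionalProperties": { "type": "string" } }
      }
    },
    "attachments": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["content_type"],
        "properties": {
          "content_type": {
            "enum": [
              "application/pdf",
              "application/json",
              "application/vnd.openxmlformats-officedocument.spreadsheetml.sheet"
            ]
          },
          "data": { "type": "string", "contentEncoding": "base64" },
          "url": { "type": "string", "format": "uri" }
        },
        "oneOf": [ { "required": ["data"] }, { "required": ["url"] } ]
      }
    }
  },
  "$defs": {
    "dicom_uid": {
      "type": "string",
      "maxLength": 64,
      "pattern": "^(0|[1-9][0-9]*)(\\.(0|[1-9][0-9]*))*$"
    }
  }
}
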