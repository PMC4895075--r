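{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Cloudwave Signal Format document",
  "description": "Self-descriptive JSON container for channel-oriented electrophysiological signal segments. Consumers must ignore (and preserve) attributes not listed here; the format is forward-compatible by construction.",
  "type": "object",
  "required": ["format_version", "study", "channels", "segment_count", "segments"],
  "properties": {
    "format_version": { "type": "string" },
    "study": {
      "type": "object",
      "description": "Study-specific metadata copied from the source recording header.",
      "properties": {
        "recording_id": { "type": "string" },
        "patient_id": { "type": "string" },
        "start_date": { "type": "string", "description": "dd.mm.yy as stored in the EDF header" },
        "start_time": { "type": "string", "description": "hh.mm.ss as stored in the EDF header" },
        "record_duration": { "type": "number", "description": "seconds per source data record" },
        "n_signals": { "type": "integer" },
        "n_data_records": { "type": "integer" },
        "source_file": { "type": "string" }
      }
    },
    "channels": {
      "type": "array",
      "description": "Channel-specific metadata, one entry per signal; labels are unique within a document.",
      "items": {
        "type": "object",
        "required": ["label", "physical_dimension", "physical_min", "physical_max",
                     "digital_min", "digital_max", "samples_per_record", "sampling_rate"],
        "properties": {
          "label": { "type": "string" },
          "transducer": { "type": "string" },
          "physical_dimension": { "type": "string" },
          "physical_min": { "type": "number" },
          "physical_max": { "type": "number" },
          "digital_min": { "type": "integer" },
          "digital_max": { "type": "integer" },
          "prefiltering": { "type": "string" },
          "samples_per_record": { "type": "integer" },
          "sampling_rate": { "type": "number", "description": "Hz" }
        }
      }
    },
    "segment_count": { "type": "integer", "minimum": 0 },
    "segments": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["sequence_number", "start_time", "end_time", "partial",
                     "annotations", "data"],
        "properties": {
          "sequence_number": { "type": "integer", "minimum": 0,
            "description": "0-based epoch index within the source recording" },
          "start_time": { "type": "number", "description": "seconds from recording start" },
          "end_time": { "type": "number" },
          "absolute_start": { "type": "string",
            "description": "ISO-8601 local timestamp derived from the recording start" },
          "partial": { "type": "boolean",
            "description": "true when the segment is a trailing remainder shorter than the epoch duration" },
          "annotations": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["onset", "duration", "text"],
              "properties": {
                "onset": { "type": "number", "minimum": 0 },
                "duration": { "type": "number", "minimum": 0 },
                "text": { "type": "string" },
                "ontology_term": { "type": "string" }
              }
            }
          },
          "data": {
            "type": "object",
            "description": "Per-channel physical-valued sample arrays keyed by channel label; for non-partial segments each array holds sampling_rate x (end_time - start_time) values.",
            "additionalProperties": { "type": "array", "items": { "type": "number" } }
          }
        }
      }
    }
  }
}
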