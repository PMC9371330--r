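{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "mycodyn pipeline run report",
  "type": "object",
  "required": ["package", "version", "r_version", "seed", "stages"],
  "properties": {
    "package": {"type": "string"},
    "version": {"type": "string"},
    "r_version": {"type": "string"},
    "seed": {"type": "number"},
    "stages": {"type": "object"}
  }
}
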