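[
  {
    "source_id": "owner1",
    "entries": [
      {
        "property": "cty",
        "dtype": "string",
        "unit": "undefined",
        "value": "GZ"
      },
      {
        "property": "qa",
        "dtype": "string",
        "unit": "undefined",
        "value": "E"
      },
      {
        "property": "cc",
        "dtype": "undefined",
        "unit": "undefined"
      }
    ]
  },
  {
    "source_id": "owner2",
    "entries": [
      {
        "property": "cty",
        "dtype": "string",
        "unit": "undefined",
        "value": "GZ"
      },
      {
        "property": "qa",
        "dtype": "undefined",
        "unit": "undefined"
      },
      {
        "property": "cc",
        "dtype": "integer",
        "unit": "%",
        "value": "0"
      }
    ]
  }
]
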