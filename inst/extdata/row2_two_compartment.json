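{
  "molecules": 6,
  "compartments": [
    {
      "id": "n1",
      "composition": "111110"
    },
    {
      "id": "n2",
      "composition": "111101"
    }
  ],
  "edges": [
    {
      "source": "n1",
      "target": "n2",
      "composition": "111100"
    },
    {
      "source": "n2",
      "target": "n1",
      "composition": "110100"
    },
    {
      "source": "n2",
      "target": "n1",
      "composition": "111000"
    }
  ],
  "pairing": [
    [0, 0, 0, 0, 0, 0],
    [0, 0, 0, 0, 1, 0],
    [0, 0, 0, 1, 0, 0],
    [0, 0, 0, 0, 0, 0],
    [0, 0, 1, 0, 0, 0],
    [0, 0, 0, 0, 0, 0]
  ],
  "regime": {
    "compartment": "none",
    "vesicle": "boolean"
  },
  "regulation": {
    "vesicle": {
      "111100": "101000",
      "110100": "010100",
      "111000": "010000"
    }
  }
}
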