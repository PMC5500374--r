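{
  "molecules": 4,
  "compartments": [
    {
      "id": "n1",
      "composition": "1110"
    },
    {
      "id": "n2",
      "composition": "1101"
    },
    {
      "id": "n3",
      "composition": "1111"
    }
  ],
  "edges": [
    {
      "source": "n1",
      "target": "n3",
      "composition": "1010"
    },
    {
      "source": "n1",
      "target": "n3",
      "composition": "1110"
    },
    {
      "source": "n2",
      "target": "n1",
      "composition": "1100"
    },
    {
      "source": "n2",
      "target": "n3",
      "composition": "0001"
    },
    {
      "source": "n3",
      "target": "n1",
      "composition": "0110"
    },
    {
      "source": "n3",
      "target": "n2",
      "composition": "1101"
    }
  ],
  "pairing": [
    [0, 0, 0, 1],
    [0, 0, 1, 0],
    [1, 0, 0, 0],
    [1, 1, 0, 0]
  ],
  "regime": {
    "compartment": "boolean",
    "vesicle": "boolean"
  },
  "regulation": {
    "compartment": {
      "1110": "0010",
      "1101": "0001",
      "1111": "0100"
    },
    "vesicle": {
      "1010": "0010",
      "1110": "0010",
      "1100": "0100",
      "0001": "0001",
      "0110": "0100",
      "1101": "1000"
    }
  }
}
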