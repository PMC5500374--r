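{
  "molecules": 6,
  "compartments": [
    {
      "id": "n1",
      "composition": "111110"
    },
    {
      "id": "n2",
      "composition": "111111"
    }
  ],
  "edges": [
    {
      "source": "n1",
      "target": "n2",
      "composition": "100110"
    },
    {
      "source": "n1",
      "target": "n2",
      "composition": "011000"
    },
    {
      "source": "n2",
      "target": "n1",
      "composition": "011110"
    },
    {
      "source": "n2",
      "target": "n1",
      "composition": "100000"
    }
  ],
  "pairing": [
    [0, 0, 0, 0, 0, 0],
    [0, 0, 0, 1, 0, 0],
    [0, 0, 0, 0, 1, 0],
    [0, 0, 0, 0, 0, 0],
    [0, 0, 1, 0, 0, 0],
    [0, 1, 0, 0, 0, 0]
  ],
  "regime": {
    "compartment": "boolean",
    "vesicle": "snare_inhibition"
  },
  "regulation": {
    "compartment": {
      "111110": "100110",
      "111111": "010101"
    }
  }
}
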