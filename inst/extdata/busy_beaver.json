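{
  "states": ["A", "B", "C", "HALT"],
  "alphabet": ["0", "1"],
  "blank": "0",
  "initial": "A",
  "rules": [
    {
      "state": "A",
      "read": "0",
      "write": "1",
      "move": "R",
      "next": "B"
    },
    {
      "state": "A",
      "read": "1",
      "write": "1",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "B",
      "read": "0",
      "write": "0",
      "move": "R",
      "next": "C"
    },
    {
      "state": "B",
      "read": "1",
      "write": "1",
      "move": "R",
      "next": "B"
    },
    {
      "state": "C",
      "read": "0",
      "write": "1",
      "move": "L",
      "next": "C"
    },
    {
      "state": "C",
      "read": "1",
      "write": "1",
      "move": "L",
      "next": "A"
    }
  ]
}
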