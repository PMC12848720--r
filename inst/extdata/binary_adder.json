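{
  "states": ["Z1", "Z2", "Z3", "GR", "DEC", "W1", "R1", "R2", "R3", "INC", "RET", "L1", "L2", "FIN", "HALT"],
  "alphabet": ["0", "1", "x", "y"],
  "blank": "0",
  "initial": "Z1",
  "rules": [
    {
      "state": "Z1",
      "read": "0",
      "write": "0",
      "move": "R",
      "next": "Z2"
    },
    {
      "state": "Z1",
      "read": "1",
      "write": "1",
      "move": "R",
      "next": "GR"
    },
    {
      "state": "Z2",
      "read": "0",
      "write": "0",
      "move": "R",
      "next": "Z3"
    },
    {
      "state": "Z2",
      "read": "1",
      "write": "1",
      "move": "R",
      "next": "GR"
    },
    {
      "state": "Z3",
      "read": "0",
      "write": "0",
      "move": "R",
      "next": "FIN"
    },
    {
      "state": "Z3",
      "read": "1",
      "write": "0",
      "move": "R",
      "next": "W1"
    },
    {
      "state": "GR",
      "read": "0",
      "write": "0",
      "move": "R",
      "next": "GR"
    },
    {
      "state": "GR",
      "read": "1",
      "write": "1",
      "move": "R",
      "next": "GR"
    },
    {
      "state": "GR",
      "read": "x",
      "write": "x",
      "move": "L",
      "next": "DEC"
    },
    {
      "state": "DEC",
      "read": "0",
      "write": "1",
      "move": "L",
      "next": "DEC"
    },
    {
      "state": "DEC",
      "read": "1",
      "write": "0",
      "move": "R",
      "next": "W1"
    },
    {
      "state": "W1",
      "read": "0",
      "write": "0",
      "move": "R",
      "next": "W1"
    },
    {
      "state": "W1",
      "read": "1",
      "write": "1",
      "move": "R",
      "next": "W1"
    },
    {
      "state": "W1",
      "read": "x",
      "write": "x",
      "move": "R",
      "next": "R1"
    },
    {
      "state": "R1",
      "read": "0",
      "write": "0",
      "move": "R",
      "next": "R2"
    },
    {
      "state": "R1",
      "read": "1",
      "write": "1",
      "move": "R",
      "next": "R2"
    },
    {
      "state": "R2",
      "read": "0",
      "write": "0",
      "move": "R",
      "next": "R3"
    },
    {
      "state": "R2",
      "read": "1",
      "write": "1",
      "move": "R",
      "next": "R3"
    },
    {
      "state": "R3",
      "read": "0",
      "write": "0",
      "move": "R",
      "next": "INC"
    },
    {
      "state": "R3",
      "read": "1",
      "write": "1",
      "move": "R",
      "next": "INC"
    },
    {
      "state": "INC",
      "read": "0",
      "write": "1",
      "move": "L",
      "next": "RET"
    },
    {
      "state": "INC",
      "read": "1",
      "write": "0",
      "move": "L",
      "next": "INC"
    },
    {
      "state": "RET",
      "read": "0",
      "write": "0",
      "move": "L",
      "next": "RET"
    },
    {
      "state": "RET",
      "read": "1",
      "write": "1",
      "move": "L",
      "next": "RET"
    },
    {
      "state": "RET",
      "read": "x",
      "write": "x",
      "move": "L",
      "next": "L1"
    },
    {
      "state": "L1",
      "read": "0",
      "write": "0",
      "move": "L",
      "next": "L2"
    },
    {
      "state": "L1",
      "read": "1",
      "write": "1",
      "move": "L",
      "next": "L2"
    },
    {
      "state": "L2",
      "read": "0",
      "write": "0",
      "move": "L",
      "next": "Z1"
    },
    {
      "state": "L2",
      "read": "1",
      "write": "1",
      "move": "L",
      "next": "Z1"
    },
    {
      "state": "FIN",
      "read": "x",
      "write": "0",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "Z1",
      "read": "x",
      "write": "x",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "Z1",
      "read": "y",
      "write": "y",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "Z2",
      "read": "x",
      "write": "x",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "Z2",
      "read": "y",
      "write": "y",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "Z3",
      "read": "x",
      "write": "x",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "Z3",
      "read": "y",
      "write": "y",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "GR",
      "read": "y",
      "write": "y",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "DEC",
      "read": "x",
      "write": "x",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "DEC",
      "read": "y",
      "write": "y",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "W1",
      "read": "y",
      "write": "y",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "R1",
      "read": "x",
      "write": "x",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "R1",
      "read": "y",
      "write": "y",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "R2",
      "read": "x",
      "write": "x",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "R2",
      "read": "y",
      "write": "y",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "R3",
      "read": "x",
      "write": "x",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "R3",
      "read": "y",
      "write": "y",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "INC",
      "read": "x",
      "write": "x",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "INC",
      "read": "y",
      "write": "y",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "RET",
      "read": "y",
      "write": "y",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "L1",
      "read": "x",
      "write": "x",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "L1",
      "read": "y",
      "write": "y",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "L2",
      "read": "x",
      "write": "x",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "L2",
      "read": "y",
      "write": "y",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "FIN",
      "read": "0",
      "write": "0",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "FIN",
      "read": "1",
      "write": "1",
      "move": "R",
      "next": "HALT"
    },
    {
      "state": "FIN",
      "read": "y",
      "write": "y",
      "move": "R",
      "next": "HALT"
    }
  ]
}
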