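[
  {
    "smarts": "[*:1][CX3:2]!@[NX3:3][*:4]",
    "K": [0, 2.0, 0, 0, 0, 0],
    "s": [1, -1, 1, 1, 1, 1],
    "tag": "amide-like C-N 2-fold (minima 0/180)"
  },
  {
    "smarts": "[c:1][c:2]!@[c:3][c:4]",
    "K": [0, 1.0, 0, 0, 0, 0],
    "s": [1, 1, 1, 1, 1, 1],
    "tag": "biaryl 2-fold (minima 90/270)"
  },
  {
    "smarts": "[CX4:1][CX4:2]@[CX4:3][CX4:4]",
    "K": [0, 0, 1.0, 0, 0, 0],
    "s": [1, 1, 1, 1, 1, 1],
    "tag": "in-ring aliphatic C-C 3-fold"
  },
  {
    "smarts": "[CX4:1][CX4:2]!@[CX4:3][CX4:4]",
    "K": [0, 0, 1.0, 0, 0, 0],
    "s": [1, 1, 1, 1, 1, 1],
    "tag": "acyclic alkane C-C 3-fold"
  }
]
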