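{
  "nodes": [
    {
      "name": "ATF6",
      "kind": "input",
      "levels": 3,
      "init": [0, 1, 2],
      "basal": 0,
      "rule": "additive",
      "compartment": "ER"
    },
    {
      "name": "PERK",
      "kind": "input",
      "levels": 3,
      "init": [0, 1, 2],
      "basal": 0,
      "rule": "additive",
      "compartment": "ER"
    },
    {
      "name": "IRE1",
      "kind": "input",
      "levels": 3,
      "init": [0, 1, 2],
      "basal": 0,
      "rule": "additive",
      "compartment": "ER"
    },
    {
      "name": "S1_2P",
      "kind": "input",
      "levels": 3,
      "init": [0, 1, 2],
      "basal": 0,
      "rule": "additive",
      "compartment": "Golgi"
    },
    {
      "name": "TRAF2",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "ASK1",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "JNK",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "IKK",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "IkB",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "NFkB",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 1,
      "rule": "additive"
    },
    {
      "name": "A20",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "CyclinD",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "BACE1",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "Abeta",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "eIF2a",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "ATF4",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "CHOP",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "GADD34",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "P53",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "ATF6f",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "joint_min"
    },
    {
      "name": "XBP1",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "cMYC",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "Bcl2",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "Survival",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "joint_min"
    },
    {
      "name": "BAX",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "Cytoc",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "Caspase9",
      "kind": "internal",
      "levels": 3,
      "init": [0, 1],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "Cancer",
      "kind": "output",
      "levels": 2,
      "init": [0],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "Apoptosis",
      "kind": "output",
      "levels": 2,
      "init": [0],
      "basal": 0,
      "rule": "additive"
    },
    {
      "name": "Alzheimer",
      "kind": "output",
      "levels": 2,
      "init": [0],
      "basal": 0,
      "rule": "additive"
    }
  ],
  "edges": [
    {
      "from": "IRE1",
      "to": "TRAF2",
      "sign": "+"
    },
    {
      "from": "TRAF2",
      "to": "ASK1",
      "sign": "+"
    },
    {
      "from": "ASK1",
      "to": "JNK",
      "sign": "+"
    },
    {
      "from": "TRAF2",
      "to": "IKK",
      "sign": "+"
    },
    {
      "from": "A20",
      "to": "IKK",
      "sign": "-"
    },
    {
      "from": "IKK",
      "to": "IkB",
      "sign": "-"
    },
    {
      "from": "IKK",
      "to": "NFkB",
      "sign": "+"
    },
    {
      "from": "IkB",
      "to": "NFkB",
      "sign": "-"
    },
    {
      "from": "NFkB",
      "to": "IkB",
      "sign": "+"
    },
    {
      "from": "NFkB",
      "to": "A20",
      "sign": "+"
    },
    {
      "from": "NFkB",
      "to": "CyclinD",
      "sign": "+"
    },
    {
      "from": "NFkB",
      "to": "BACE1",
      "sign": "+"
    },
    {
      "from": "JNK",
      "to": "BACE1",
      "sign": "+"
    },
    {
      "from": "BACE1",
      "to": "Abeta",
      "sign": "+"
    },
    {
      "from": "PERK",
      "to": "eIF2a",
      "sign": "+"
    },
    {
      "from": "eIF2a",
      "to": "ATF4",
      "sign": "+"
    },
    {
      "from": "ATF4",
      "to": "CHOP",
      "sign": "+"
    },
    {
      "from": "CHOP",
      "to": "GADD34",
      "sign": "+"
    },
    {
      "from": "GADD34",
      "to": "P53",
      "sign": "+"
    },
    {
      "from": "ATF6",
      "to": "ATF6f",
      "sign": "+"
    },
    {
      "from": "S1_2P",
      "to": "ATF6f",
      "sign": "+"
    },
    {
      "from": "ATF6f",
      "to": "XBP1",
      "sign": "+"
    },
    {
      "from": "XBP1",
      "to": "cMYC",
      "sign": "+"
    },
    {
      "from": "XBP1",
      "to": "Bcl2",
      "sign": "+"
    },
    {
      "from": "cMYC",
      "to": "Survival",
      "sign": "+"
    },
    {
      "from": "Bcl2",
      "to": "Survival",
      "sign": "+"
    },
    {
      "from": "JNK",
      "to": "BAX",
      "sign": "+"
    },
    {
      "from": "BAX",
      "to": "Cytoc",
      "sign": "+"
    },
    {
      "from": "Cytoc",
      "to": "Caspase9",
      "sign": "+"
    },
    {
      "from": "Survival",
      "to": "Cancer",
      "sign": "+"
    },
    {
      "from": "CyclinD",
      "to": "Cancer",
      "sign": "+"
    },
    {
      "from": "P53",
      "to": "Apoptosis",
      "sign": "+"
    },
    {
      "from": "Caspase9",
      "to": "Apoptosis",
      "sign": "+"
    },
    {
      "from": "Survival",
      "to": "Apoptosis",
      "sign": "-"
    },
    {
      "from": "Abeta",
      "to": "Alzheimer",
      "sign": "+"
    },
    {
      "from": "eIF2a",
      "to": "BACE1",
      "sign": "+"
    },
    {
      "from": "GADD34",
      "to": "eIF2a",
      "sign": "-"
    },
    {
      "from": "IkB",
      "to": "P53",
      "sign": "-"
    },
    {
      "from": "NFkB",
      "to": "CHOP",
      "sign": "-"
    },
    {
      "from": "JNK",
      "to": "Bcl2",
      "sign": "-"
    },
    {
      "from": "CHOP",
      "to": "Bcl2",
      "sign": "-"
    },
    {
      "from": "Bcl2",
      "to": "BAX",
      "sign": "-"
    },
    {
      "from": "Survival",
      "to": "Caspase9",
      "sign": "-"
    }
  ]
}
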