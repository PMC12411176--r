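{
  "compounds": [
    {
      "id": "A",
      "mw": 150,
      "external": false
    },
    {
      "id": "B",
      "mw": 100,
      "external": false
    },
    {
      "id": "C",
      "mw": 100,
      "external": false
    },
    {
      "id": "D",
      "mw": 200,
      "external": false
    }
  ],
  "reactions": [
    {
      "id": "r0",
      "stoich": {
        "A": 1
      },
      "lb": 0,
      "ub": 1000,
      "internal": false,
      "mass_loss": false,
      "biomass": false
    },
    {
      "id": "r1",
      "stoich": {
        "A": -2,
        "B": 1,
        "C": 2
      },
      "lb": -1000,
      "ub": 1000,
      "internal": true,
      "mass_loss": false,
      "biomass": false
    },
    {
      "id": "r2",
      "stoich": {
        "B": -2,
        "D": 1
      },
      "lb": -1000,
      "ub": 1000,
      "internal": true,
      "mass_loss": false,
      "biomass": false
    },
    {
      "id": "r3",
      "stoich": {
        "B": 1,
        "C": -1
      },
      "lb": -1000,
      "ub": 1000,
      "internal": true,
      "mass_loss": false,
      "biomass": false
    },
    {
      "id": "r4",
      "stoich": {
        "C": -2,
        "D": 1
      },
      "lb": -1000,
      "ub": 1000,
      "internal": true,
      "mass_loss": false,
      "biomass": false
    },
    {
      "id": "r5",
      "stoich": {
        "D": -1
      },
      "lb": 0,
      "ub": 1000,
      "internal": false,
      "mass_loss": false,
      "biomass": false
    },
    {
      "id": "r6",
      "stoich": {
        "A": -2,
        "D": 1
      },
      "lb": 0,
      "ub": 1000,
      "internal": false,
      "mass_loss": true,
      "biomass": false
    },
    {
      "id": "rbio",
      "stoich": {
        "A": -2.33333333333333,
        "B": -1.5,
        "C": -3,
        "D": -1
      },
      "lb": 0,
      "ub": 1000,
      "internal": false,
      "mass_loss": false,
      "biomass": true
    }
  ],
  "biomass": {
    "fractions": {
      "A": 0.35,
      "B": 0.15,
      "C": 0.3,
      "D": 0.2
    }
  }
}
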