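{
  "druglike": {
    "mw_window": [
      340,
      470
    ],
    "scaffolds": {
      "c1ccccc1": 2.0,
      "c1ccncc1": 2.0,
      "c1cncnc1": 1.5,
      "c1cscn1": 1.0,
      "c1ccc2ncccc2c1": 1.5,
      "c1ccc2[nH]ccc2c1": 1.0,
      "c1ccc2[nH]cnc2c1": 1.0,
      "c1ccc(-c2ccccc2)cc1": 1.0,
      "c1ccc(-c2ccncc2)cc1": 1.0,
      "C1CCN(c2ccccc2)CC1": 1.0,
      "c1ccc(N2CCNCC2)cc1": 1.0,
      "c1ccc(N2CCOCC2)cc1": 1.0
    },
    "substituents": {
      "C": 2.0,
      "CC": 1.0,
      "F": 1.5,
      "Cl": 1.5,
      "OC": 2.0,
      "N": 1.0,
      "N(C)C": 1.5,
      "NC(C)=O": 1.5,
      "C(=O)NC": 1.5,
      "S(C)(=O)=O": 1.0,
      "C#N": 1.0,
      "C(F)(F)F": 1.0,
      "Cc1ccccc1": 1.0,
      "c1ccccc1": 1.0,
      "N1CCOCC1": 1.0,
      "CCl": 0.06,
      "C=O": 0.04,
      "OCC": 1.0
    }
  },
  "reagentlike": {
    "mw_window": [
      200,
      340
    ],
    "scaffolds": {
      "CCCC": 0.6,
      "CC(C)C": 0.6,
      "CCOCC": 0.8,
      "C1CCCCC1": 1.0,
      "c1ccccc1": 0.8,
      "CCC(=O)OC": 1.5,
      "CCC(=O)O": 1.2,
      "CC=O": 1.2,
      "CCC#N": 0.8,
      "CCBr": 0.8,
      "CC(=O)Cl": 0.8,
      "CCN": 0.8,
      "CCO": 1.0,
      "CC(C)=O": 1.2
    },
    "substituents": {
      "C": 1.2,
      "CC": 1.2,
      "CCC": 0.6,
      "O": 1.2,
      "OC": 1.0,
      "Cl": 1.5,
      "Br": 1.2,
      "C=O": 1.2,
      "C(=O)Cl": 0.6,
      "C(=O)OC": 1.3,
      "N": 0.6,
      "C#N": 0.7
    }
  },
  "naturallike": {
    "mw_window": [
      300,
      440
    ],
    "scaffolds": {
      "C1CCC2C(C1)CCC3C2CCC4CCCC34": 4.0,
      "C1C2CC3CC1CC(C2)C3": 2.0,
      "CC1(C)C2CCC1(C)CC2": 1.5,
      "OCC1OC(O)C(O)C(O)C1O": 2.5,
      "C1CCC2CCCCC2C1": 1.5,
      "C1CC2CCC1C2": 1.0,
      "C1CC2CCC1CC2": 1.0,
      "C1CCC2CCCC2C1": 1.0,
      "C1CC2CCC1O2": 1.0,
      "C1CCOCC1": 0.4,
      "C1CCCCC1": 0.4
    },
    "substituents": {
      "O": 6.0,
      "C": 2.0,
      "OC": 0.6,
      "OC(C)=O": 0.4,
      "CO": 0.5,
      "CC": 0.4,
      "C(C)C": 0.2,
      "C=C": 0.2,
      "C1CCCCC1": 0.8,
      "C1CCOCC1": 0.5
    }
  }
}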