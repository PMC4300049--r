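{
  "name": "unified-DNA-NN-v1",
  "comment": "Unified nearest-neighbor thermodynamics for DNA duplexes (Watson-Crick stacks, dH kcal/mol, dS cal/(mol K)); loop penalties as dG at 37 C (kcal/mol), treated as purely entropic. Stacks keyed by the 5'->3' dinucleotide on one strand of the step.",
  "stacks": {
    "AA": {"dH": -7.9, "dS": -22.2},
    "AT": {"dH": -7.2, "dS": -20.4},
    "AC": {"dH": -8.4, "dS": -22.4},
    "AG": {"dH": -7.8, "dS": -21.0},
    "TA": {"dH": -7.2, "dS": -21.3},
    "TT": {"dH": -7.9, "dS": -22.2},
    "TC": {"dH": -8.2, "dS": -22.2},
    "TG": {"dH": -8.5, "dS": -22.7},
    "CA": {"dH": -8.5, "dS": -22.7},
    "CT": {"dH": -7.8, "dS": -21.0},
    "CC": {"dH": -8.0, "dS": -19.9},
    "CG": {"dH": -10.6, "dS": -27.2},
    "GA": {"dH": -8.2, "dS": -22.2},
    "GT": {"dH": -8.4, "dS": -22.4},
    "GC": {"dH": -9.8, "dS": -24.4},
    "GG": {"dH": -8.0, "dS": -19.9}
  },
  "initiation": {"dH": 0.2, "dS": -5.7},
  "terminal_AT": {"dH": 2.2, "dS": 6.9},
  "symmetry_dS": -1.4,
  "hairpin_g37": {
    "3": 3.5, "4": 3.5, "5": 3.3, "6": 4.0, "7": 4.4, "8": 4.6, "9": 4.7,
    "10": 4.9, "12": 5.2, "14": 5.4, "16": 5.6, "18": 5.8, "20": 5.9,
    "25": 6.3, "30": 6.6
  },
  "bulge_g37": {
    "1": 4.0, "2": 2.9, "3": 3.1, "4": 3.2, "5": 3.3, "6": 3.5, "7": 3.7,
    "8": 3.9, "9": 4.1, "10": 4.3, "12": 4.5, "14": 4.8, "16": 5.0,
    "18": 5.2, "20": 5.3, "25": 5.6, "30": 5.9
  },
  "internal_g37": {
    "2": 3.2, "3": 3.2, "4": 3.6, "5": 4.0, "6": 4.4, "7": 4.6, "8": 4.8,
    "9": 4.9, "10": 4.9, "12": 5.2, "14": 5.4, "16": 5.6, "18": 5.8,
    "20": 5.9, "25": 6.3, "30": 6.6
  },
  "multiloop": {"a": 3.4, "b": 0.4, "c": 0.1},
  "loop_cap": 30,
  "loop_extrapolation_coefficient": 1.75
}
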