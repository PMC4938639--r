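{
  "comment": "Generator inputs for make_pheno(): control-strain means, multiplicative mutant effects, and noise CVs. Effects encode the published mucin-null vs control contrasts; means are realistic laboratory values chosen for the simulator.",
  "means": {
    "ccrt": 1500,
    "abdomen_area": 2.2,
    "tibia_t1": 0.62,
    "tibia_t2": 0.55,
    "tibia_t3": 0.68,
    "wing_area": 2.0,
    "lifespan": 33.9,
    "starvation": 36,
    "dw": {"0d": 2.4, "4d": 3.3, "5d": 3.4, "5d_ACCR": 3.1},
    "lipid_fraction": {"0d": 0.25, "4d": 0.12, "5d": 0.12, "5d_ACCR": 0.10}
  },
  "effects": {
    "ccrt": 0.88,
    "abdomen_area": 1.063,
    "tibia_t1": 0.987,
    "tibia_t2": 0.983,
    "tibia_t3": 0.979,
    "wing_area": 0.967,
    "lifespan": 1.059,
    "starvation": 1.15,
    "dw": {"0d": 0.898, "4d": 1.083, "5d": 1.0, "5d_ACCR": 0.99}
  },
  "cvs": {
    "ccrt": 0.25,
    "abdomen_area": 0.08,
    "tibia": 0.04,
    "wing_area": 0.06,
    "lifespan": 0.41,
    "starvation": 0.30,
    "dw": 0.08,
    "lipid_fraction": 0.15
  }
}
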