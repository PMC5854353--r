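{
 "id": "myzaphis_apterae",
 "name": "Key to apterous viviparous females of the genus Myzaphis",
 "morph": "aptera",
 "root": "1",
 "couplets": {
  "1": {
   "a": {
    "predicates": [
     {
      "character": "FRONTAL_TUBERCLE",
      "op": "eq",
      "states": [
       "absent"
      ]
     }
    ],
    "goto": "2"
   },
   "b": {
    "predicates": [
     {
      "character": "FRONTAL_TUBERCLE",
      "op": "eq",
      "states": [
       "rounded",
       "quadrate",
       "rectangular"
      ]
     }
    ],
    "goto": "3"
   }
  },
  "2": {
   "a": {
    "predicates": [
     {
      "character": "DORSUM_PIGMENT",
      "op": "eq",
      "states": [
       "dark"
      ]
     },
     {
      "character": "SIPH_FORM",
      "op": "eq",
      "states": [
       "clavate"
      ]
     },
     {
      "character": "ANT_V_ANT_III",
      "op": "in",
      "lo": 0.57,
      "hi": 0.68
     },
     {
      "character": "HLS_BD_III",
      "op": "in",
      "lo": 1.25,
      "hi": 1.35
     }
    ],
    "taxon": "juchnevitschae"
   },
   "b": {
    "predicates": [
     {
      "character": "DORSUM_PIGMENT",
      "op": "eq",
      "states": [
       "pale"
      ]
     },
     {
      "character": "SIPH_FORM",
      "op": "eq",
      "states": [
       "cylindrical"
      ]
     },
     {
      "character": "ANT_V_ANT_III",
      "op": "in",
      "lo": 0.38,
      "hi": 0.45
     },
     {
      "character": "HLS_BD_III",
      "op": "in",
      "lo": 0.43,
      "hi": 0.54
     }
    ],
    "taxon": "tuatayae"
   }
  },
  "3": {
   "a": {
    "predicates": [
     {
      "character": "SETA_ABD",
      "op": "in",
      "lo": 0.055,
      "hi": 0.09
     },
     {
      "character": "DORSAL_SETA_FORM",
      "op": "eq",
      "states": [
       "long-pointed"
      ]
     }
    ],
    "taxon": "tianshanica"
   },
   "b": {
    "predicates": [
     {
      "character": "SETA_ABD",
      "op": "in",
      "lo": 0.001,
      "hi": 0.025
     },
     {
      "character": "DORSAL_SETA_FORM",
      "op": "eq",
      "states": [
       "short-blunt"
      ]
     }
    ],
    "goto": "4"
   }
  },
  "4": {
   "a": {
    "predicates": [
     {
      "character": "FRONTAL_TUBERCLE",
      "op": "eq",
      "states": [
       "rounded"
      ]
     }
    ],
    "goto": "5"
   },
   "b": {
    "predicates": [
     {
      "character": "FRONTAL_TUBERCLE",
      "op": "eq",
      "states": [
       "quadrate",
       "rectangular"
      ]
     }
    ],
    "goto": "6"
   }
  },
  "5": {
   "a": {
    "predicates": [
     {
      "character": "DORSUM_PIGMENT",
      "op": "eq",
      "states": [
       "pale"
      ]
     },
     {
      "character": "PLEURAL_STRIPES",
      "op": "eq",
      "states": [
       "absent"
      ]
     }
    ],
    "taxon": "rezwanii"
   },
   "b": {
    "predicates": [
     {
      "character": "DORSUM_PIGMENT",
      "op": "eq",
      "states": [
       "dark"
      ]
     },
     {
      "character": "PLEURAL_STRIPES",
      "op": "eq",
      "states": [
       "broad"
      ]
     }
    ],
    "taxon": "bucktoni"
   }
  },
  "6": {
   "a": {
    "predicates": [
     {
      "character": "FRONTAL_TUBERCLE",
      "op": "eq",
      "states": [
       "quadrate"
      ]
     },
     {
      "character": "HLS_BD_III",
      "op": "in",
      "lo": 0.3,
      "hi": 0.6
     },
     {
      "character": "SETAE_GENITAL",
      "op": "in",
      "lo": 4,
      "hi": 7
     }
    ],
    "taxon": "rosarum"
   },
   "b": {
    "predicates": [
     {
      "character": "FRONTAL_TUBERCLE",
      "op": "eq",
      "states": [
       "rectangular"
      ]
     },
     {
      "character": "HLS_BD_III",
      "op": "in",
      "lo": 0.8,
      "hi": 1.1
     },
     {
      "character": "SETAE_GENITAL",
      "op": "ge",
      "lo": 8
     }
    ],
    "goto": "7"
   }
  },
  "7": {
   "a": {
    "predicates": [
     {
      "character": "URS_ANT_III",
      "op": "in",
      "lo": 0.32,
      "hi": 0.51
     },
     {
      "character": "HT_II_ANT_III",
      "op": "in",
      "lo": 0.42,
      "hi": 0.67
     },
     {
      "character": "PLEURAL_STRIPES",
      "op": "eq",
      "states": [
       "absent"
      ]
     }
    ],
    "taxon": "turanica"
   },
   "b": {
    "predicates": [
     {
      "character": "URS_ANT_III",
      "op": "in",
      "lo": 0.7,
      "hi": 0.87
     },
     {
      "character": "HT_II_ANT_III",
      "op": "in",
      "lo": 0.85,
      "hi": 1.0
     },
     {
      "character": "PLEURAL_STRIPES",
      "op": "eq",
      "states": [
       "narrow"
      ]
     }
    ],
    "taxon": "oezdemirae"
   }
  }
 }
}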