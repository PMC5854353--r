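{
 "id": "macrosiphini_genera_222",
 "name": "Key to aphid genera of the tribe Macrosiphini with 2-2-2 first tarsal chaetotaxy (apterous viviparous females)",
 "morph": "aptera",
 "root": "1",
 "couplets": {
  "1": {
   "a": {
    "predicates": [
     {
      "character": "RHIN_ANT_III",
      "op": "ge",
      "lo": 1
     }
    ],
    "taxon": "Hydaphias"
   },
   "b": {
    "predicates": [
     {
      "character": "RHIN_ANT_III",
      "op": "in",
      "lo": 0,
      "hi": 0
     }
    ],
    "goto": "2"
   }
  },
  "2": {
   "a": {
    "predicates": [
     {
      "character": "SIPH_FORM",
      "op": "eq",
      "states": [
       "pore"
      ]
     },
     {
      "character": "URS_FORM",
      "op": "eq",
      "states": [
       "stiletto"
      ]
     }
    ],
    "taxon": "Cryptosiphum"
   },
   "b": {
    "predicates": [
     {
      "character": "SIPH_FORM",
      "op": "eq",
      "states": [
       "cylindrical",
       "clavate",
       "truncate-squamous"
      ]
     },
     {
      "character": "URS_FORM",
      "op": "eq",
      "states": [
       "normal"
      ]
     }
    ],
    "goto": "3"
   }
  },
  "3": {
   "a": {
    "predicates": [
     {
      "character": "ANT_TUBERCLE_INNER",
      "op": "eq",
      "states": [
       "spiculose"
      ]
     }
    ],
    "taxon": "Myzus"
   },
   "b": {
    "predicates": [
     {
      "character": "ANT_TUBERCLE_INNER",
      "op": "eq",
      "states": [
       "smooth"
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
      "character": "CAUDA_FORM",
      "op": "eq",
      "states": [
       "semicircular"
      ]
     },
     {
      "character": "SIPH_INCISION",
      "op": "eq",
      "states": [
       "present"
      ]
     }
    ],
    "taxon": "Brachycaudus"
   },
   "b": {
    "predicates": [
     {
      "character": "CAUDA_FORM",
      "op": "eq",
      "states": [
       "triangular",
       "finger",
       "tongue"
      ]
     },
     {
      "character": "SIPH_INCISION",
      "op": "eq",
      "states": [
       "absent"
      ]
     }
    ],
    "goto": "5"
   }
  },
  "5": {
   "a": {
    "predicates": [
     {
      "character": "ANT_TUBERCLE_DEV",
      "op": "eq",
      "states": [
       "well-developed"
      ]
     }
    ],
    "taxon": "Micromyzella"
   },
   "b": {
    "predicates": [
     {
      "character": "ANT_TUBERCLE_DEV",
      "op": "eq",
      "states": [
       "low"
      ]
     }
    ],
    "goto": "6"
   }
  },
  "6": {
   "a": {
    "predicates": [
     {
      "character": "SIPH_FORM",
      "op": "eq",
      "states": [
       "truncate-squamous"
      ]
     }
    ],
    "taxon": "Staegeriella"
   },
   "b": {
    "predicates": [
     {
      "character": "SIPH_FORM",
      "op": "eq",
      "states": [
       "cylindrical",
       "clavate"
      ]
     }
    ],
    "goto": "7"
   }
  },
  "7": {
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
      "character": "DORSUM_SCULPTURE",
      "op": "eq",
      "states": [
       "smooth"
      ]
     },
     {
      "character": "SIPH_FORM",
      "op": "eq",
      "states": [
       "cylindrical"
      ]
     }
    ],
    "taxon": "Pseudacaudella"
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
      "character": "DORSUM_SCULPTURE",
      "op": "eq",
      "states": [
       "reticulated",
       "wrinkled"
      ]
     },
     {
      "character": "SIPH_FORM",
      "op": "eq",
      "states": [
       "clavate"
      ]
     }
    ],
    "goto": "8"
   }
  },
  "8": {
   "a": {
    "predicates": [
     {
      "character": "DORSUM_SCULPTURE",
      "op": "eq",
      "states": [
       "reticulated"
      ]
     }
    ],
    "taxon": "Hyadaphis"
   },
   "b": {
    "predicates": [
     {
      "character": "DORSUM_SCULPTURE",
      "op": "eq",
      "states": [
       "wrinkled"
      ]
     }
    ],
    "taxon": "Richardsaphis"
   }
  }
 }
}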