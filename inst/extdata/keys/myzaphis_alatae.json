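{
 "id": "myzaphis_alatae",
 "name": "Key to known alate viviparous females of the genus Myzaphis",
 "morph": "alata",
 "root": "1",
 "couplets": {
  "1": {
   "a": {
    "predicates": [
     {
      "character": "PT_BASE",
      "op": "in",
      "lo": 0.6,
      "hi": 0.75
     },
     {
      "character": "URS_ANT_III",
      "op": "in",
      "lo": 0.33,
      "hi": 0.34
     },
     {
      "character": "HT_II_ANT_III",
      "op": "in",
      "lo": 0.46,
      "hi": 0.5
     }
    ],
    "taxon": "juchnevitschae"
   },
   "b": {
    "predicates": [
     {
      "character": "PT_BASE",
      "op": "in",
      "lo": 0.95,
      "hi": 1.76
     },
     {
      "character": "URS_ANT_III",
      "op": "in",
      "lo": 0.19,
      "hi": 0.31
     },
     {
      "character": "HT_II_ANT_III",
      "op": "in",
      "lo": 0.26,
      "hi": 0.45
     }
    ],
    "goto": "2"
   }
  },
  "2": {
   "a": {
    "predicates": [
     {
      "character": "ANT_V_ANT_III",
      "op": "in",
      "lo": 0.61,
      "hi": 0.63
     },
     {
      "character": "HT_II_ANT_VI",
      "op": "in",
      "lo": 0.3,
      "hi": 0.32
     }
    ],
    "taxon": "tianshanica"
   },
   "b": {
    "predicates": [
     {
      "character": "ANT_V_ANT_III",
      "op": "in",
      "lo": 0.28,
      "hi": 0.51
     },
     {
      "character": "HT_II_ANT_VI",
      "op": "in",
      "lo": 0.36,
      "hi": 0.72
     }
    ],
    "goto": "3"
   }
  },
  "3": {
   "a": {
    "predicates": [
     {
      "character": "HW_ANT",
      "op": "in",
      "lo": 0.25,
      "hi": 0.3
     },
     {
      "character": "URS_ANT_VI",
      "op": "in",
      "lo": 0.25,
      "hi": 0.3
     },
     {
      "character": "HT_II_ANT_VI",
      "op": "in",
      "lo": 0.36,
      "hi": 0.39
     },
     {
      "character": "RHIN_ANT_III",
      "op": "in",
      "lo": 15,
      "hi": 24
     }
    ],
    "taxon": "rosarum"
   },
   "b": {
    "predicates": [
     {
      "character": "HW_ANT",
      "op": "in",
      "lo": 0.31,
      "hi": 0.44
     },
     {
      "character": "URS_ANT_VI",
      "op": "in",
      "lo": 0.34,
      "hi": 0.47
     },
     {
      "character": "HT_II_ANT_VI",
      "op": "in",
      "lo": 0.44,
      "hi": 0.72
     },
     {
      "character": "RHIN_ANT_III",
      "op": "in",
      "lo": 6,
      "hi": 16
     }
    ],
    "goto": "4"
   }
  },
  "4": {
   "a": {
    "predicates": [
     {
      "character": "SIPH_CAUDA",
      "op": "in",
      "lo": 2.0,
      "hi": 2.27
     },
     {
      "character": "HW_ANT",
      "op": "in",
      "lo": 0.43,
      "hi": 0.44
     },
     {
      "character": "ANT_IV_ANT_III",
      "op": "in",
      "lo": 0.26,
      "hi": 0.31
     },
     {
      "character": "PT_BASE",
      "op": "in",
      "lo": 0.95,
      "hi": 1.0
     }
    ],
    "taxon": "rezwanii"
   },
   "b": {
    "predicates": [
     {
      "character": "SIPH_CAUDA",
      "op": "in",
      "lo": 1.21,
      "hi": 1.68
     },
     {
      "character": "HW_ANT",
      "op": "in",
      "lo": 0.31,
      "hi": 0.4
     },
     {
      "character": "ANT_IV_ANT_III",
      "op": "in",
      "lo": 0.33,
      "hi": 0.46
     },
     {
      "character": "PT_BASE",
      "op": "in",
      "lo": 1.05,
      "hi": 1.5
     }
    ],
    "goto": "5"
   }
  },
  "5": {
   "a": {
    "predicates": [
     {
      "character": "ANT_IV_ANT_III",
      "op": "in",
      "lo": 1.0,
      "hi": 1.45
     }
    ],
    "taxon": "bucktoni"
   },
   "b": {
    "predicates": [
     {
      "character": "ANT_IV_ANT_III",
      "op": "in",
      "lo": 0.31,
      "hi": 0.41
     }
    ],
    "taxon": "turanica"
   }
  }
 }
}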