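{
 "id": "myzaphis_oviparae",
 "name": "Key to known oviparous females of the genus Myzaphis",
 "morph": "ovipara",
 "root": "1",
 "couplets": {
  "1": {
   "a": {
    "predicates": [
     {
      "character": "ANT_SEGMENTS",
      "op": "eq",
      "states": [
       "5"
      ]
     }
    ],
    "goto": "2"
   },
   "b": {
    "predicates": [
     {
      "character": "ANT_SEGMENTS",
      "op": "eq",
      "states": [
       "6"
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
      "character": "PT_BASE",
      "op": "in",
      "lo": 0.66,
      "hi": 1.0
     },
     {
      "character": "URS_HT_II",
      "op": "in",
      "lo": 1.0,
      "hi": 1.15
     },
     {
      "character": "URS_ANT_V",
      "op": "in",
      "lo": 0.6,
      "hi": 0.83
     }
    ],
    "taxon": "rezwanii"
   },
   "b": {
    "predicates": [
     {
      "character": "PT_BASE",
      "op": "in",
      "lo": 1.2,
      "hi": 1.37
     },
     {
      "character": "URS_HT_II",
      "op": "in",
      "lo": 0.7,
      "hi": 0.75
     },
     {
      "character": "URS_ANT_VI",
      "op": "in",
      "lo": 0.35,
      "hi": 0.36
     }
    ],
    "taxon": "turanica"
   }
  },
  "3": {
   "a": {
    "predicates": [
     {
      "character": "ANT_V_ANT_III",
      "op": "in",
      "lo": 0.33,
      "hi": 0.4
     },
     {
      "character": "ANT_IV_ANT_III",
      "op": "in",
      "lo": 0.33,
      "hi": 0.4
     }
    ],
    "taxon": "bucktoni"
   },
   "b": {
    "predicates": [
     {
      "character": "ANT_V_ANT_III",
      "op": "in",
      "lo": 0.48,
      "hi": 0.62
     },
     {
      "character": "ANT_IV_ANT_III",
      "op": "in",
      "lo": 0.43,
      "hi": 0.57
     }
    ],
    "goto": "4"
   }
  },
  "4": {
   "a": {
    "predicates": [
     {
      "character": "PSEUDO_TIBIA_III",
      "op": "in",
      "lo": 20,
      "hi": 52
     },
     {
      "character": "ANT_V_ANT_III",
      "op": "in",
      "lo": 0.54,
      "hi": 0.62
     }
    ],
    "taxon": "rosarum"
   },
   "b": {
    "predicates": [
     {
      "character": "PSEUDO_TIBIA_III",
      "op": "in",
      "lo": 61,
      "hi": 80
     },
     {
      "character": "ANT_V_ANT_III",
      "op": "in",
      "lo": 0.48,
      "hi": 0.5
     }
    ],
    "taxon": "oezdemirae"
   }
  }
 }
}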