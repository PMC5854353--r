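{
 "id": "myzaphis_males",
 "name": "Key to known males of the genus Myzaphis",
 "morph": "male",
 "root": "1",
 "couplets": {
  "1": {
   "a": {
    "predicates": [
     {
      "character": "WINGS",
      "op": "eq",
      "states": [
       "present"
      ]
     },
     {
      "character": "ANT_IV_ANT_III",
      "op": "in",
      "lo": 0.51,
      "hi": 0.59
     }
    ],
    "taxon": "oezdemirae"
   },
   "b": {
    "predicates": [
     {
      "character": "WINGS",
      "op": "eq",
      "states": [
       "absent"
      ]
     },
     {
      "character": "ANT_IV_ANT_III",
      "op": "in",
      "lo": 0.32,
      "hi": 0.48
     }
    ],
    "goto": "2"
   }
  },
  "2": {
   "a": {
    "predicates": [
     {
      "character": "ANT_SEGMENTS",
      "op": "eq",
      "states": [
       "5"
      ]
     },
     {
      "character": "PT_BASE",
      "op": "in",
      "lo": 0.58,
      "hi": 1.37
     }
    ],
    "goto": "3"
   },
   "b": {
    "predicates": [
     {
      "character": "ANT_SEGMENTS",
      "op": "eq",
      "states": [
       "6"
      ]
     },
     {
      "character": "PT_BASE",
      "op": "in",
      "lo": 1.42,
      "hi": 2.05
     }
    ],
    "goto": "4"
   }
  },
  "3": {
   "a": {
    "predicates": [
     {
      "character": "PT_BASE",
      "op": "in",
      "lo": 0.58,
      "hi": 0.81
     },
     {
      "character": "ANT_V_ANT_III",
      "op": "in",
      "lo": 0.62,
      "hi": 0.63
     },
     {
      "character": "URS_ANT_V",
      "op": "in",
      "lo": 0.65,
      "hi": 0.7
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
      "character": "ANT_V_ANT_III",
      "op": "in",
      "lo": 0.78,
      "hi": 0.86
     },
     {
      "character": "URS_ANT_V",
      "op": "in",
      "lo": 0.26,
      "hi": 0.31
     }
    ],
    "taxon": "turanica"
   }
  },
  "4": {
   "a": {
    "predicates": [
     {
      "character": "RHIN_ANT_III",
      "op": "in",
      "lo": 17,
      "hi": 30
     },
     {
      "character": "RHIN_ANT_IV",
      "op": "in",
      "lo": 2,
      "hi": 6
     },
     {
      "character": "ANT_BL",
      "op": "in",
      "lo": 0.7,
      "hi": 0.85
     }
    ],
    "taxon": "rosarum"
   },
   "b": {
    "predicates": [
     {
      "character": "RHIN_ANT_III",
      "op": "in",
      "lo": 5,
      "hi": 15
     },
     {
      "character": "RHIN_ANT_IV",
      "op": "in",
      "lo": 0,
      "hi": 1
     },
     {
      "character": "ANT_BL",
      "op": "in",
      "lo": 0.61,
      "hi": 0.64
     }
    ],
    "taxon": "bucktoni"
   }
  }
 }
}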