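{
 "id": "myzaphis_fundatrices",
 "name": "Key to known fundatrices of the genus Myzaphis",
 "morph": "fundatrix",
 "root": "1",
 "couplets": {
  "1": {
   "a": {
    "predicates": [
     {
      "character": "SETA_ABD",
      "op": "in",
      "lo": 0.02,
      "hi": 0.075
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
      "lo": 0.005,
      "hi": 0.02
     },
     {
      "character": "DORSAL_SETA_FORM",
      "op": "eq",
      "states": [
       "short-blunt"
      ]
     }
    ],
    "goto": "2"
   }
  },
  "2": {
   "a": {
    "predicates": [
     {
      "character": "SIPH_CAUDA",
      "op": "about",
      "value": 2.69
     },
     {
      "character": "PT_BASE",
      "op": "about",
      "value": 0.66
     },
     {
      "character": "URS_ANT_V",
      "op": "about",
      "value": 0.68
     }
    ],
    "taxon": "rezwanii"
   },
   "b": {
    "predicates": [
     {
      "character": "SIPH_CAUDA",
      "op": "le",
      "hi": 1.96
     },
     {
      "character": "PT_BASE",
      "op": "ge",
      "lo": 0.88
     },
     {
      "character": "URS_ANT_V",
      "op": "le",
      "hi": 0.57
     }
    ],
    "goto": "3"
   }
  },
  "3": {
   "a": {
    "predicates": [
     {
      "character": "LS_III_BD_III",
      "op": "in",
      "lo": 0.25,
      "hi": 0.4
     },
     {
      "character": "SIPH_CAUDA",
      "op": "in",
      "lo": 1.65,
      "hi": 1.96
     },
     {
      "character": "URS_ANT_V",
      "op": "in",
      "lo": 0.44,
      "hi": 0.53
     }
    ],
    "goto": "4"
   },
   "b": {
    "predicates": [
     {
      "character": "LS_III_BD_III",
      "op": "in",
      "lo": 0.57,
      "hi": 0.66
     },
     {
      "character": "SIPH_CAUDA",
      "op": "in",
      "lo": 1.43,
      "hi": 1.51
     },
     {
      "character": "URS_ANT_V",
      "op": "in",
      "lo": 0.54,
      "hi": 0.57
     }
    ],
    "taxon": "bucktoni"
   }
  },
  "4": {
   "a": {
    "predicates": [
     {
      "character": "FRONTAL_TUBERCLE",
      "op": "eq",
      "states": [
       "rounded",
       "quadrate",
       "rectangular"
      ]
     },
     {
      "character": "SIPH_PIGMENT",
      "op": "eq",
      "states": [
       "dark"
      ]
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
       "absent"
      ]
     },
     {
      "character": "SIPH_PIGMENT",
      "op": "eq",
      "states": [
       "pale"
      ]
     }
    ],
    "taxon": "tuatayae"
   }
  }
 }
}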