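[
 {
  "key": "myzaphis_alatae",
  "couplet": "5",
  "lead": "a",
  "character": "ANT_IV_ANT_III",
  "replace": {
   "character": "ANT_IV_ANT_III",
   "op": "in",
   "lo": 0.4,
   "hi": 0.46
  },
  "justification": "Printed 1.00-1.45 contradicts couplet 4b (ANT IV/ANT III 0.33-0.46) and leaves the terminal unreachable; the species' own printed alate ratio is 0.40-0.46."
 },
 {
  "key": "myzaphis_oviparae",
  "couplet": "2",
  "lead": "b",
  "character": "URS_ANT_VI",
  "replace": {
   "character": "URS_ANT_V",
   "op": "in",
   "lo": 0.35,
   "hi": 0.36
  },
  "justification": "This lead keys a 5-segmented form whose last antennal segment is ANT V; the ratio is printed against ANT VI."
 }
]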