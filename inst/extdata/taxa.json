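{
 "species": [
  {
   "taxon": "bucktoni",
   "genus": "Myzaphis",
   "epithet": "bucktoni",
   "authority": "Jacob, 1946",
   "status": "valid"
  },
  {
   "taxon": "juchnevitschae",
   "genus": "Myzaphis",
   "epithet": "juchnevitschae",
   "authority": "Kadyrbekov, 1993",
   "status": "valid"
  },
  {
   "taxon": "komatsubarae",
   "genus": "Myzaphis",
   "epithet": "komatsubarae",
   "authority": "Shinji, 1922",
   "status": "nomen_dubium"
  },
  {
   "taxon": "oezdemirae",
   "genus": "Myzaphis",
   "epithet": "oezdemirae",
   "authority": "Kanturski & Barjadze, 2018",
   "status": "valid"
  },
  {
   "taxon": "rezwanii",
   "genus": "Myzaphis",
   "epithet": "rezwanii",
   "authority": "Kanturski & Barjadze, 2018",
   "status": "valid"
  },
  {
   "taxon": "rosarum",
   "genus": "Myzaphis",
   "epithet": "rosarum",
   "authority": "(Kaltenbach, 1843)",
   "status": "valid",
   "type_species": true
  },
  {
   "taxon": "tianshanica",
   "genus": "Myzaphis",
   "epithet": "tianshanica",
   "authority": "Kadyrbekov, 1993",
   "status": "valid"
  },
  {
   "taxon": "tuatayae",
   "genus": "Myzaphis",
   "epithet": "tuatayae",
   "authority": "Kanturski & Barjadze, 2018",
   "status": "valid"
  },
  {
   "taxon": "turanica",
   "genus": "Myzaphis",
   "epithet": "turanica",
   "authority": "Nevsky, 1929",
   "status": "valid"
  },
  {
   "taxon": "avariolosa",
   "genus": "Ericaphis",
   "epithet": "avariolosa",
   "authority": "(David, Rajasingh & Narayanan, 1970)",
   "status": "valid",
   "original_genus": "Myzaphis"
  },
  {
   "taxon": "canadensis",
   "genus": "Richardsaphis",
   "epithet": "canadensis",
   "authority": "(Richards, 1963)",
   "status": "valid",
   "original_genus": "Myzaphis",
   "type_species": true
  }
 ],
 "genera": [
  "Myzaphis",
  "Ericaphis",
  "Richardsaphis",
  "Hydaphias",
  "Cryptosiphum",
  "Myzus",
  "Brachycaudus",
  "Micromyzella",
  "Staegeriella",
  "Pseudacaudella",
  "Hyadaphis"
 ],
 "genus_traits": {
  "Myzaphis": [
   {
    "character_id": "SETAE_HT_I",
    "lo": 5,
    "hi": 5,
    "provenance": "genus diagnosis"
   },
   {
    "character_id": "SETAE_CAUDA",
    "lo": 6,
    "hi": 7,
    "provenance": "genus diagnosis"
   },
   {
    "character_id": "RHIN_ANT_III",
    "lo": 0,
    "hi": 0,
    "morphs": [
     "aptera",
     "fundatrix"
    ],
    "provenance": "genus diagnosis"
   }
  ],
  "Richardsaphis": [
   {
    "character_id": "SETAE_HT_I",
    "lo": 2,
    "hi": 2,
    "provenance": "genus diagnosis"
   },
   {
    "character_id": "RHIN_ANT_III",
    "lo": 0,
    "hi": 0,
    "morphs": [
     "aptera",
     "fundatrix"
    ],
    "provenance": "genus diagnosis"
   }
  ],
  "Ericaphis": [
   {
    "character_id": "SETAE_HT_I",
    "lo": 5,
    "hi": 5,
    "provenance": "species description"
   },
   {
    "character_id": "RHIN_ANT_III",
    "lo": 0,
    "hi": 0,
    "morphs": [
     "aptera",
     "fundatrix"
    ],
    "provenance": "species description"
   }
  ]
 },
 "taxon_traits": {
  "avariolosa": [
   {
    "character_id": "SETAE_CAUDA",
    "lo": 4,
    "hi": 4,
    "provenance": "species description"
   }
  ]
 },
 "material_counts": {
  "fundatrix": 36,
  "aptera": 316,
  "alata": 47,
  "ovipara": 50,
  "male": 25,
  "total_printed": 474,
  "slides": 154
 }
}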