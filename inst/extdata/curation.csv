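taxon,morph,character_id,action,lo,hi,justification
tuatayae,aptera,ANT_IV,replace,0.08,0.10,printed 0.08-1.10: segment maximum exceeds whole antenna (0.66-0.81); read 1.10 as 0.10
bucktoni,aptera,GPW,replace,0.13,0.20,printed 0.3-0.20 inverted; congeners span 0.13-0.25; read 0.3 as 0.13
tianshanica,aptera,ANT,drop,,,printed 0.16-0.18 equals ANT III alone and is below ANT VI (0.19-0.22); no defensible correction
rezwanii,alata,RHIN_ANT_III,replace,8,11,printed 8-110; the alate key gives 6-16 for this group; read 110 as 11
rezwanii,male,SETA_THORAX,replace,0.007,0.010,printed 0.07-0.010 inverted; congener thoracic setae 0.004-0.020; read 0.07 as 0.007
turanica,aptera,SETA_ABD,replace,0.010,0.027,printed 0.010-0.271; a 0.271 mm abdominal seta would exceed the cauda; congeners at most 0.031
tuatayae,aptera,HEAD_SETA,replace,0.005,0.014,printed 0.005-0.14; HLS/BD III 0.43-0.54 implies head setae at most about 0.02 mm
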