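taxon,CH,AT,FR,DE,IT,excluded
Baetidae,1,1,1,1,1,0
Gammaridae,1,1,1,0,1,0
Tabanidae,1,1,1,1,1,0
Leuctridae,0,1,1,1,1,0
Culicoides fascipennis,0,1,1,1,1,1
Molannidae,0,1,1,1,0,0
Notonectidae,1,0,0,0,0,0
Potamanthidae,0,1,0,1,1,0
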