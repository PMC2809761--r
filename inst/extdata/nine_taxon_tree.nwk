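((((((D_erecta:7,D_yakuba:7)erecta_yakuba:3,D_melanogaster:10)mel_subgroup:15,D_ananassae:25)mel_group:8,D_pseudoobscura:33)obscura_split:3,D_willistoni:36)Sophophora:4,((D_virilis:25,D_mojavensis:25)virilis_mojavensis:5,D_grimshawi:30)subgenus_Drosophila:10)root;
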