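(((Bufo_boreas:1,Bufo_americanus:1):1,(Hyla_versicolor:1,(Pseudacris_crucifer:1,(Pseudacris_regilla:1,(Pseudacris_triseriata:1,Pseudacris_feriarum:1):1):1):1):1):1,((Rana_boylii:1,(Rana_aurora:1,Rana_cascadae:1):1):1,(((Rana_catesbeiana:1,Rana_clamitans:1):1,Rana_sylvatica:1):1,(Rana_pipiens:1,Rana_sphenocephala:1):1):1):1);
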