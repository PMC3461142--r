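species,level,duration_days,estimate,ci_low,ci_high,lag_significant,previously_published
Bufo_boreas,10,4,7.0,4.4,10.0,0,1
Bufo_boreas,50,4,67.7,52.2,91.0,0,1
Bufo_boreas,90,4,653,399,1296,0,1
Bufo_boreas,10,8,7.1,4.8,9.7,0,1
Bufo_boreas,50,8,43.4,35.1,54.6,0,1
Bufo_boreas,90,8,264,184,432,0,1
Bufo_americanus,10,4,19.6,14.6,24.2,0,0
Bufo_americanus,50,4,55.5,46.9,67.2,0,0
Bufo_americanus,90,4,157,119,236,0,0
Bufo_americanus,10,8,20.1,15.2,24.5,0,0
Bufo_americanus,50,8,53.0,45.1,63.8,0,0
Bufo_americanus,90,8,140,107,207,0,0
Pseudacris_triseriata,10,4,22.0,16.3,27.7,0,0
Pseudacris_triseriata,50,4,56.4,46.4,69.1,0,0
Pseudacris_triseriata,90,4,144,112,203,0,0
Pseudacris_triseriata,10,8,21.7,16.2,27.2,0,0
Pseudacris_triseriata,50,8,53.6,44.2,65.7,0,0
Pseudacris_triseriata,90,8,132,103,185,0,0
Pseudacris_feriarum,10,4,2.9,1.8,4.2,0,0
Pseudacris_feriarum,50,4,25.5,21.3,31.4,0,0
Pseudacris_feriarum,90,4,88.6,64.1,144,0,0
Pseudacris_feriarum,10,8,2.9,1.8,4.2,0,0
Pseudacris_feriarum,50,8,25.3,19.5,33.8,0,0
Pseudacris_feriarum,90,8,218,135,430,0,0
Pseudacris_regilla,10,4,2.7,1.8,3.8,0,1
Pseudacris_regilla,50,4,21.3,17.0,26.9,0,1
Pseudacris_regilla,90,4,165,114,271,0,1
Pseudacris_regilla,10,8,1.7,1.1,2.4,0,1
Pseudacris_regilla,50,8,13.9,11.1,17.5,0,1
Pseudacris_regilla,90,8,114,79.0,187,0,1
Pseudacris_crucifer,10,4,22.0,15.1,29.1,1,1
Pseudacris_crucifer,50,4,112,89.4,146,1,1
Pseudacris_crucifer,90,4,571,383,1000,1,1
Pseudacris_crucifer,10,8,0.8,0.4,1.4,1,1
Pseudacris_crucifer,50,8,26.0,18.9,37.0,1,1
Pseudacris_crucifer,90,8,823,420,2120,1,1
Hyla_versicolor,10,4,2.4,1.7,3.0,1,1
Hyla_versicolor,50,4,9.0,7.6,10.7,1,1
Hyla_versicolor,90,4,33.8,25.9,48.4,1,1
Hyla_versicolor,10,8,1.1,0.7,1.5,1,1
Hyla_versicolor,50,8,6.0,4.9,7.3,1,1
Hyla_versicolor,90,8,33.2,24.5,50.0,1,1
Rana_pipiens,10,4,13.0,9.0,17.0,1,0
Rana_pipiens,50,4,51.0,42.1,63.1,1,0
Rana_pipiens,90,4,199,143,322,1,0
Rana_pipiens,10,8,4.4,2.8,6.1,1,0
Rana_pipiens,50,8,28.0,22.3,35.4,1,0
Rana_pipiens,90,8,178,122,297,1,0
Rana_sphenocephala,10,4,0.7,0.5,0.9,1,0
Rana_sphenocephala,50,4,2.8,2.3,3.4,1,0
Rana_sphenocephala,90,4,11.4,8.5,17.2,1,0
Rana_sphenocephala,10,8,1.0,0.8,1.2,1,0
Rana_sphenocephala,50,8,1.9,1.7,2.1,1,0
Rana_sphenocephala,90,8,3.6,3.1,4.6,1,0
Rana_sylvatica,10,4,2.6,1.5,3.9,0,0
Rana_sylvatica,50,4,31.4,23.8,42.6,0,0
Rana_sylvatica,90,4,379,226,779,0,0
Rana_sylvatica,10,8,2.0,1.5,3.9,0,0
Rana_sylvatica,50,8,25.1,19.1,33.7,0,0
Rana_sylvatica,90,8,312,189,626,0,0
Rana_clamitans,10,4,2.0,1.6,2.4,0,1
Rana_clamitans,50,4,3.3,2.8,3.7,0,1
Rana_clamitans,90,4,5.2,4.6,6.1,0,1
Rana_clamitans,10,8,1.7,1.4,2.1,0,1
Rana_clamitans,50,8,3.1,2.7,3.5,0,1
Rana_clamitans,90,8,5.4,4.7,6.4,0,1
Rana_catesbeiana,10,4,0.4,0.2,0.6,0,1
Rana_catesbeiana,50,4,1.3,1.0,1.6,0,1
Rana_catesbeiana,90,4,4.4,3.5,5.9,0,1
Rana_catesbeiana,10,8,0.2,0.1,0.3,0,1
Rana_catesbeiana,50,8,0.9,0.7,1.2,0,1
Rana_catesbeiana,90,8,3.6,2.8,5.0,0,1
Rana_aurora,10,4,2.3,1.6,2.6,1,0
Rana_aurora,50,4,3.7,3.3,4.8,1,0
Rana_aurora,90,4,6.1,4.7,12.6,1,0
Rana_aurora,10,8,1.6,1.3,1.8,1,0
Rana_aurora,50,8,2.4,2.2,2.7,1,0
Rana_aurora,90,8,3.7,3.2,4.5,1,0
Rana_cascadae,10,4,4.8,3.6,5.9,1,1
Rana_cascadae,50,4,15.0,12.7,17.9,1,1
Rana_cascadae,90,4,47.4,37.4,64.0,1,1
Rana_cascadae,10,8,6.0,5.5,6.1,1,1
Rana_cascadae,50,8,6.7,6.5,7.1,1,1
Rana_cascadae,90,8,7.6,7.1,9.0,1,1
Rana_boylii,10,4,2.5,1.7,3.3,1,0
Rana_boylii,50,4,13.0,10.6,16.1,1,0
Rana_boylii,90,4,67.6,49.6,101,1,0
Rana_boylii,10,8,0.9,0.6,1.3,1,0
Rana_boylii,50,8,5.4,4.4,6.6,1,0
Rana_boylii,90,8,30.6,22.1,46.9,1,0
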