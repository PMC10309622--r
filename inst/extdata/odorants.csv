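name,molecular_weight,molar_volume,beta,Da,Dm
2-acetylthiazole,127.16,117,1e-05,6e-06,1e-09
2-(1-mercaptoethyl)furan,128.19,135,0.05,6e-06,1e-09
synthetic-odorant-a,110,105,1e-06,6e-06,1e-09
synthetic-odorant-b,118,112,1e-04,6e-06,1e-09
synthetic-odorant-c,126,120,1e-03,6e-06,1e-09
synthetic-odorant-d,134,128,1e-02,6e-06,1e-09
synthetic-odorant-e,142,136,1e-01,6e-06,1e-09
synthetic-odorant-f,150,144,1,6e-06,
synthetic-odorant-g,158,152,10,,1e-09
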