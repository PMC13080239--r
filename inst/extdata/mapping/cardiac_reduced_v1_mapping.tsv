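reaction_id	protein_id
glut	Slc2a4
glut	Slc2a1
glut	Hk2
glyc	Pfkm
glyc	Aldoa
glyc	Gapdh
glyc	Pgk1
glyc	Pkm
glyc	Eno1
ldh	Slc16a1
ldh	Ldha
ldh	Ldhb
pdh	Pdha1
pdh	Pdhb
pdh	Dlat
fao	Cd36
fao	Cpt1b
fao	Cpt2
fao	Acadvl
fao	Acadl
fao	Hadha
fao	Hadhb
fao	Etfa
ket_bhb	Bdh1
ket_bhb	Oxct1
ket_acac	Oxct1
ket_acac	Acat1
val_t	Slc7a5
leu_t	Slc7a5
ile_t	Slc7a5
bcaa_ox	Bcat2
bcaa_ox	Bckdha
bcaa_ox	Bckdhb
bcaa_ox	Ivd
bcaa_ox	Acadsb
tca	Cs
tca	Aco2
tca	Idh3a
tca	Ogdh
tca	Sdha
tca	Fh1
tca	Mdh2
tca	Sucla2
resp	Ndufs1
resp	Ndufv1
resp	Sdhb
resp	Uqcrc1
resp	Uqcrc2
resp	Cox4i1
resp	Cox5a
resp	Atp5f1a
resp	Atp5f1b
resp	Slc25a4
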