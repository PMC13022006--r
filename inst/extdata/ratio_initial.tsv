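class	Chl b	But Fuco	Hex Fuco	Allo	Fuco	Perid	Zea	DV Chl b	Chl c1+c2	Chl c3	Lut	Neo	Viola	Pras	Chl a
Cyanobacteria1	0	0	0	0	0	0	0.105	0	0	0	0	0	0	0	1
Cyanobacteria2	0	0	0	0	0	0	0.453	0	0	0	0	0	0	0	1
Cyanobacteria4	0.495	0	0	0	0	0	0.224	0.495	0	0	0	0	0	0	1
Prasinophytes3	0.368	0	0	0	0	0	0.033	0	0	0	0.013	0.051	0.035	0.145	1
Cryptophytes	0	0	0	0.359	0	0	0	0	0.145	0	0	0	0	0	1
Diatoms1	0	0	0	0	0.711	0	0	0	0.074	0	0	0	0	0	1
Haptophytes6	0	0.004	0.237	0	0.066	0	0	0	0.178	0.156	0	0	0	0	1
Dinoflagellates1	0	0	0	0	0	0.541	0	0	0.197	0	0	0	0	0	1
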