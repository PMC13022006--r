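class	Chl b	But Fuco	Hex Fuco	Allo	Fuco	Perid	Zea	DV Chl b	Chl c1+c2	Chl c3	Lut	Neo	Viola	Pras	Chl a
Cyanobacteria1	0	0	0	0	0	0	0.101	0	0	0	0	0	0	0	1
Cyanobacteria2	0	0	0	0	0	0	1.343	0	0	0	0	0	0	0	1
Cyanobacteria4	0.432	0	0	0	0	0	0.203	0.363	0	0	0	0	0	0	1
Prasinophytes3	0.605	0	0	0	0	0	0.035	0	0	0	0.013	0.047	0.035	0.082	1
Cryptophytes	0	0	0	0.322	0	0	0	0	0.129	0	0	0	0	0	1
Diatoms1	0	0	0	0	0.609	0	0	0	0.098	0	0	0	0	0	1
Haptophytes6	0	0.009	0.488	0	0.096	0	0	0	0.215	0.211	0	0	0	0	1
Dinoflagellates1	0	0	0	0	0	0.579	0	0	0.236	0	0	0	0	0	1
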