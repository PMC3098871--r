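# synthetic SMAD-like probability matrix, UniPROBE-style dialect (not a database matrix)
A:	0.05	0.05	0.05	0.05	0.80	0.05	0.85	0.05	0.60	0.10
C:	0.05	0.05	0.80	0.05	0.10	0.05	0.05	0.85	0.15	0.60
G:	0.85	0.05	0.10	0.10	0.05	0.85	0.05	0.05	0.15	0.20
T:	0.05	0.85	0.05	0.80	0.05	0.05	0.05	0.05	0.10	0.10
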