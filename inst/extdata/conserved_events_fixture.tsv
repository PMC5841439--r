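gene_a	gene_b	dpsi_a	dpsi_b	conservation	psi_consistency_printed
ABI1	Abi1	-0.133	-0.095	both	Y
ARHGAP12	Arhgap12	-0.069	-0.309	both	Y
ATP5C1	Atp5c1	0.104	0.259	both	Y
CTTN	Cttn	-0.054	-0.159	both	Y
DNM1L	Dnm1l	-0.096	-0.221	both	Y
EXOC1	Exoc1	0.186	0.198	both	Y
FBLN2	Fbln2	-0.172	-0.173	both	Y
FNBP1	Fnbp1	-0.137	-0.269	both	Y
GOLGA2	Golga2	-0.099	-0.144	both	Y
GOLGA4	Golga4	0.058	0.086	both	Y
MYH11	Myh11	-0.064	-0.225	both	Y
MYL6	Myl6	-0.101	-0.294	both	Y
MYO1B	Myo1b	-0.109	-0.206	both	Y
PAM	Pam	-0.096	-0.327	both	Y
SEC31A	Sec31a	-0.105	-0.115	both	Y
SLK	Slk	0.107	0.217	both	Y
SPAG9	Spag9	-0.100	-0.226	both	Y
ZMYND11	Zmynd11	0.061	0.365	both	Y
AXL	Axl	-0.060	0.091	both	N
DMKN	Dmkn	-0.180	-0.078	cross_matched	N
MLX	Mlx	0.089	-0.132	both	N
MPRIP	Mprip	-0.127	0.187	both	N
NDRG2	Ndrg2	0.126	-0.159	both	N
POSTN	Postn	-0.072	-0.195	cross_matched	N
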