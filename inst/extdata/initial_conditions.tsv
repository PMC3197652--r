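name	value	note
V	-77.00	membrane potential, mV
pH_i	7.15	intracellular pH
pH_o	7.40	extracellular pH
Na_i	14.34	mM
Na_o	149.02	mM
K_i	146.7	mM
K_o	5.40	mM
Cl_i	33.77	mM
Cl_o	109.10	mM
Ca_i	0.000335	free myoplasmic calcium, mM
Ca_o	1.80	mM
Ca_jsr	0.605236	free junctional-SR calcium, mM
Ca_nsr	2.352399	network-SR calcium, mM
CO2_i	derived	from pH_i and HCO3_i at the apparent pK 6.10
CO2_o	derived	from pH_o and HCO3_o at the apparent pK 6.10
HCO3_i	7.90	mM
HCO3_o	11.90	mM
Anion_i	0	generic conjugate anion, zero by construction at t = 0
m	0.005751	fast-Na activation gate
h	0.894526	fast-Na inactivation gate
j	0.889565	fast-Na slow inactivation gate
d	0.000022	L-type activation gate
f	0.990176	L-type inactivation gate
x_r	0.005171	rapid delayed-rectifier gate
x_s1	0.059092	slow delayed-rectifier gate 1
x_s2	0.108548	slow delayed-rectifier gate 2
b	0.002925	T-type activation gate
g	0.899522	T-type inactivation gate
m_L	0.018649	late-Na activation gate
h_L	0.741684	late-Na inactivation gate (fast component)
h_Ls	0.741684	late-Na inactivation gate (slow component)
ryr_o	0	ryanodine-receptor activation gate
ryr_i	derived	ryanodine-receptor Ca-inactivation gate at Ca_i
V_myo	2.5847e-5	myoplasmic volume, uL
V_ext	5.172e-6	extracellular volume, uL
Osm_i	310.0	intracellular osmolarity, mOsm
X_i	derived	impermeant intracellular osmolytes from Osm_i
ATP	7.216	mM
ADP	0.036	mM
AMP	0.000184	mM
Pi	0.8	mM
Cr	8.9	mM
PCr	13.3	mM
HBuf1_i	derived	proton-loaded intrinsic buffer 1 at pH_i
HBuf2_i	derived	proton-loaded intrinsic buffer 2 at pH_i
HBuf1_o	derived	proton-loaded intrinsic buffer 1 at pH_o
HBuf2_o	derived	proton-loaded intrinsic buffer 2 at pH_o
t	0	ms
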