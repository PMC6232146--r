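channel	x	y	row
Fp1	-0.4141	0.9	1
Fpz	0	0.9	1
Fp2	0.4141	0.9	1
AF7	-0.7009	0.675	2
AF3	-0.3505	0.675	2
AFz	0	0.675	2
AF4	0.3505	0.675	2
AF8	0.7009	0.675	2
F7	-0.8484	0.45	3
F5	-0.6363	0.45	3
F3	-0.4242	0.45	3
F1	-0.2121	0.45	3
Fz	0	0.45	3
F2	0.2121	0.45	3
F4	0.4242	0.45	3
F6	0.6363	0.45	3
F8	0.8484	0.45	3
FT7	-0.9256	0.225	4
FC5	-0.6942	0.225	4
FC3	-0.4628	0.225	4
FC1	-0.2314	0.225	4
FCz	0	0.225	4
FC2	0.2314	0.225	4
FC4	0.4628	0.225	4
FC6	0.6942	0.225	4
FT8	0.9256	0.225	4
T7	-0.95	0	5
C5	-0.7125	0	5
C3	-0.475	0	5
C1	-0.2375	0	5
Cz	0	0	5
C2	0.2375	0	5
C4	0.475	0	5
C6	0.7125	0	5
T8	0.95	0	5
TP7	-0.9256	-0.225	6
CP5	-0.6942	-0.225	6
CP3	-0.4628	-0.225	6
CP1	-0.2314	-0.225	6
CPz	0	-0.225	6
CP2	0.2314	-0.225	6
CP4	0.4628	-0.225	6
CP6	0.6942	-0.225	6
TP8	0.9256	-0.225	6
P7	-0.8484	-0.45	7
P5	-0.6363	-0.45	7
P3	-0.4242	-0.45	7
P1	-0.2121	-0.45	7
Pz	0	-0.45	7
P2	0.2121	-0.45	7
P4	0.4242	-0.45	7
P6	0.6363	-0.45	7
P8	0.8484	-0.45	7
PO7	-0.7009	-0.675	8
PO3	-0.3505	-0.675	8
POz	0	-0.675	8
PO4	0.3505	-0.675	8
PO8	0.7009	-0.675	8
O1	-0.4141	-0.9	9
Oz	0	-0.9	9
O2	0.4141	-0.9	9
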