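# Idealized (synthetic) unit-sphere coordinates for a 64-channel 10-10 montage.
# Generated by prioEEG::buildMontage(); x right, y anterior, z superior.
# Not digitised head measurements.
channel	x	y	z
Fp1	-0.309017	0.951057	0
Fp2	0.309017	0.951057	0
AF7	-0.587785	0.809017	0
AF3	-0.323124	0.889484	0.323124
AF4	0.323124	0.889484	0.323124
AF8	0.587785	0.809017	0
F7	-0.809017	0.587785	0
F5	-0.682495	0.683658	0.25848
F3	-0.493176	0.716627	0.493176
F1	-0.25848	0.683658	0.682495
Fz	0	0.587785	0.809017
F2	0.25848	0.683658	0.682495
F4	0.493176	0.716627	0.493176
F6	0.682495	0.683658	0.25848
F8	0.809017	0.587785	0
FT9	-0.904508	0.293893	-0.309017
FT7	-0.951057	0.309017	0
FC5	-0.854223	0.389462	0.344417
FC3	-0.64252	0.417535	0.64252
FC1	-0.344417	0.389462	0.854223
FC2	0.344417	0.389462	0.854223
FC4	0.64252	0.417535	0.64252
FC6	0.854223	0.389462	0.344417
FT8	0.951057	0.309017	0
FT10	0.904508	0.293893	-0.309017
T7	-1	0	0
C5	-0.92388	0	0.382683
C3	-0.707107	0	0.707107
C1	-0.382683	0	0.92388
Cz	0	0	1
C2	0.382683	0	0.92388
C4	0.707107	0	0.707107
C6	0.92388	0	0.382683
T8	1	0	0
TP9	-0.904508	-0.293893	-0.309017
TP7	-0.951057	-0.309017	0
CP5	-0.854223	-0.389462	0.344417
CP3	-0.64252	-0.417535	0.64252
CP1	-0.344417	-0.389462	0.854223
CPz	0	-0.309017	0.951057
CP2	0.344417	-0.389462	0.854223
CP4	0.64252	-0.417535	0.64252
CP6	0.854223	-0.389462	0.344417
TP8	0.951057	-0.309017	0
TP10	0.904508	-0.293893	-0.309017
P7	-0.809017	-0.587785	0
P5	-0.682495	-0.683658	0.25848
P3	-0.493176	-0.716627	0.493176
P1	-0.25848	-0.683658	0.682495
Pz	0	-0.587785	0.809017
P2	0.25848	-0.683658	0.682495
P4	0.493176	-0.716627	0.493176
P6	0.682495	-0.683658	0.25848
P8	0.809017	-0.587785	0
PO9	-0.559017	-0.769421	-0.309017
PO7	-0.587785	-0.809017	0
PO3	-0.323124	-0.889484	0.323124
POz	0	-0.809017	0.587785
PO4	0.323124	-0.889484	0.323124
PO8	0.587785	-0.809017	0
PO10	0.559017	-0.769421	-0.309017
O1	-0.309017	-0.951057	0
Oz	0	-0.951057	0.309017
O2	0.309017	-0.951057	0
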