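label	x	y
FP1	-0.3	0.95
FPZ	0	0.95
FP2	0.3	0.95
AF3	-0.35	0.82
AF4	0.35	0.82
F7	-0.8	0.64
F5	-0.6	0.64
F3	-0.4	0.64
F1	-0.2	0.64
FZ	0	0.64
F2	0.2	0.64
F4	0.4	0.64
F6	0.6	0.64
F8	0.8	0.64
FT7	-0.92	0.36
FC5	-0.69	0.36
FC3	-0.46	0.36
FC1	-0.23	0.36
FCZ	0	0.36
FC2	0.23	0.36
FC4	0.46	0.36
FC6	0.69	0.36
FT8	0.92	0.36
T7	-1	0
C5	-0.75	0
C3	-0.5	0
C1	-0.25	0
CZ	0	0
C2	0.25	0
C4	0.5	0
C6	0.75	0
T8	1	0
TP7	-0.92	-0.36
CP5	-0.69	-0.36
CP3	-0.46	-0.36
CP1	-0.23	-0.36
CPZ	0	-0.36
CP2	0.23	-0.36
CP4	0.46	-0.36
CP6	0.69	-0.36
TP8	0.92	-0.36
P7	-0.8	-0.64
P5	-0.6	-0.64
P3	-0.4	-0.64
P1	-0.2	-0.64
PZ	0	-0.64
P2	0.2	-0.64
P4	0.4	-0.64
P6	0.6	-0.64
P8	0.8	-0.64
PO7	-0.6	-0.82
PO5	-0.4	-0.82
PO3	-0.2	-0.82
POZ	0	-0.82
PO4	0.2	-0.82
PO6	0.4	-0.82
PO8	0.6	-0.82
O1	-0.3	-0.95
OZ	0	-0.95
O2	0.3	-0.95
CB1	-0.55	-1.05
CB2	0.55	-1.05
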