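name	role	x	y	z
Fp1	scalp	-0.0954915028125263	0.951056516295154	0.293892626146237
Fpz	scalp	0	0.951056516295154	0.309016994374947
Fp2	scalp	0.0954915028125263	0.951056516295154	0.293892626146237
AF7	scalp	-0.559016994374947	0.809016994374947	0.18163563200134
AF3	scalp	-0.345491502812526	0.809016994374947	0.475528258147577
AF4	scalp	0.345491502812526	0.809016994374947	0.475528258147577
AF8	scalp	0.559016994374947	0.809016994374947	0.18163563200134
F7	scalp	-0.769420884293813	0.587785252292473	0.25
F5	scalp	-0.654508497187474	0.587785252292473	0.475528258147577
F3	scalp	-0.475528258147577	0.587785252292473	0.654508497187474
F1	scalp	-0.25	0.587785252292473	0.769420884293813
Fz	scalp	0	0.587785252292473	0.809016994374947
F2	scalp	0.25	0.587785252292473	0.769420884293813
F4	scalp	0.475528258147577	0.587785252292473	0.654508497187474
F6	scalp	0.654508497187474	0.587785252292473	0.475528258147577
F8	scalp	0.769420884293813	0.587785252292473	0.25
FC5	scalp	-0.769420884293813	0.309016994374947	0.559016994374947
FC3	scalp	-0.559016994374947	0.309016994374947	0.769420884293813
FC1	scalp	-0.293892626146237	0.309016994374947	0.904508497187474
FCz	scalp	0	0.309016994374947	0.951056516295154
FC2	scalp	0.293892626146237	0.309016994374947	0.904508497187474
FC4	scalp	0.559016994374947	0.309016994374947	0.769420884293813
FC6	scalp	0.769420884293813	0.309016994374947	0.559016994374947
T7	scalp	-1	0	6.12323399573677e-17
C5	scalp	-0.809016994374947	0	0.587785252292473
C3	scalp	-0.587785252292473	0	0.809016994374947
C1	scalp	-0.309016994374947	0	0.951056516295154
Cz	scalp	0	0	1
C2	scalp	0.309016994374947	0	0.951056516295154
C4	scalp	0.587785252292473	0	0.809016994374947
C6	scalp	0.809016994374947	0	0.587785252292473
T8	scalp	1	0	6.12323399573677e-17
CP5	scalp	-0.769420884293813	-0.309016994374947	0.559016994374947
CP3	scalp	-0.559016994374947	-0.309016994374947	0.769420884293813
CP1	scalp	-0.293892626146237	-0.309016994374947	0.904508497187474
CPz	scalp	0	-0.309016994374947	0.951056516295154
CP2	scalp	0.293892626146237	-0.309016994374947	0.904508497187474
CP4	scalp	0.559016994374947	-0.309016994374947	0.769420884293813
CP6	scalp	0.769420884293813	-0.309016994374947	0.559016994374947
P7	scalp	-0.769420884293813	-0.587785252292473	0.25
P5	scalp	-0.654508497187474	-0.587785252292473	0.475528258147577
P3	scalp	-0.475528258147577	-0.587785252292473	0.654508497187474
P1	scalp	-0.25	-0.587785252292473	0.769420884293813
Pz	scalp	0	-0.587785252292473	0.809016994374947
P2	scalp	0.25	-0.587785252292473	0.769420884293813
P4	scalp	0.475528258147577	-0.587785252292473	0.654508497187474
P6	scalp	0.654508497187474	-0.587785252292473	0.475528258147577
P8	scalp	0.769420884293813	-0.587785252292473	0.25
PO9	scalp	-0.587785252292473	-0.809016994374947	3.59914663902998e-17
PO7	scalp	-0.559016994374947	-0.809016994374947	0.18163563200134
PO3	scalp	-0.345491502812526	-0.809016994374947	0.475528258147577
POz	scalp	0	-0.809016994374947	0.587785252292473
PO4	scalp	0.345491502812526	-0.809016994374947	0.475528258147577
PO8	scalp	0.559016994374947	-0.809016994374947	0.18163563200134
PO10	scalp	0.587785252292473	-0.809016994374947	3.59914663902998e-17
O1	scalp	-0.0954915028125263	-0.951056516295154	0.293892626146237
Oz	scalp	0	-0.951056516295154	0.309016994374947
O2	scalp	0.0954915028125263	-0.951056516295154	0.293892626146237
Iz	scalp	0	-1	6.12323399573677e-17
HEOGL	eog	-0.81437855769486	0.559885258415216	-0.152695979567786
HEOGR	eog	0.81437855769486	0.559885258415216	-0.152695979567786
VEOGU	eog	0.155126306998506	0.982466610990536	0.103417537999004
VEOGD	eog	0.150946381627988	0.955993750310593	-0.251577302713314
A1	earlobe	-0.952383943522462	-0.0501254707117086	-0.300752824270251
A2	earlobe	0.952383943522462	-0.0501254707117086	-0.300752824270251
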