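method	subject	TMF	DME	FD
LMS	1	12	11	3
LMS	2	11	9	2
LMS	3	7	7	1
LMS	4	9	9	2
LMS	All	39	36	8
OMP	1	12	11	1
OMP	2	11	9	1
OMP	3	7	7	1
OMP	4	9	8	1
OMP	All	39	35	4
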