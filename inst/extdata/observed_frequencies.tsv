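promoter	female_class	generation	quantity	value	sd
nos	2	F2	homing	80.0	7.7
vas	2	F2	homing	80.2	7.4
Ubi	2	F2	homing	78.0	13.2
BicC	2	F2	homing	53.9	9.8
nos	2	F2	r2_w	11.2	6.2
vas	2	F2	r2_w	13.2	5.6
Ubi	2	F2	r2_w	18.6	12.0
BicC	2	F2	r2_w	36.7	7.5
nos	6	F3	homing	11.3	4.8
vas	6	F3	homing	10.8	10.4
Ubi	6	F3	homing	7.4	8.4
BicC	6	F3	homing	7.6	6.2
nos	6	F3	r2_w	81.7	7.5
vas	6	F3	r2_w	82.4	10.4
Ubi	6	F3	r2_w	84.6	9.5
BicC	6	F3	r2_w	81.6	7.1
all	1	F2	homing	69.0	10.8
all	1	F2	r2_w	28.5	12.2
all	5	F3	homing	6.1	4.2
all	5	F3	r2_w	92.6	5.0
all	2	F2	homing	73.0	14.6
all	2	F2	r2_w	19.9	12.8
all	6	F3	homing	9.2	7.5
all	6	F3	r2_w	82.6	8.2
Ubi	2	F2	homing_fig2	67	NA
Ubi	2	F2	r2_w_fig2	27.3	10.0
Ubi	4	F2	homing	88	NA
Ubi	4	F2	r2_w	9.9	5.7
Ubi	1	F2	r2_w	26.5	4.4
BicC	1	F2	homing	59.3	12.3
BicC	1	F2	r2_w	38.7	13.7
Ubi	1	F2	cleavage_y	26	15
BicC	1	F2	cleavage_y	89.4	9.4
nos	1	F2	cleavage_y	0	NA
vas	1	F2	cleavage_y	0	NA
nos	4	F1	som_white	100	NA
nos	4	F1	som_yellow	100	NA
vas	4	F1	som_white	100	NA
vas	4	F1	som_yellow	100	NA
Ubi	4	F1	som_white	100	NA
Ubi	4	F1	som_yellow	91.3	9.7
BicC	4	F1	som_white	64.3	2.6
BicC	4	F1	som_yellow	0	NA
Ubi	2	F2	r1_w	3.4	2.6
Ubi	6	F3	r1_w	9.7	3.1
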