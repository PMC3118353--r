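# Elementary-mode selections of the phase-wise (moving-window) analysis of
# three fed-batch BHK cultures. `em` is the signed mode id (a minus sign
# marks a fully reversible mode selected in the reverse direction);
# `cum_var` is the cumulative explained flux variance (%) after adding it.
culture	phase	rank	em	cum_var
Fed-batch 1	Ph I	1	20	80.69
Fed-batch 1	Ph I	2	2	84.24
Fed-batch 1	Ph I	3	-7	87.54
Fed-batch 1	Ph I	4	86	90.79
Fed-batch 1	Ph I	5	207	91.81
Fed-batch 1	Ph I	6	6	92.79
Fed-batch 1	Ph I	7	1	93.48
Fed-batch 1	Ph I	8	11	93.88
Fed-batch 1	Ph I	9	-5	94.00
Fed-batch 1	Ph I	10	102	94.14
Fed-batch 1	Ph I	11	3	94.22
Fed-batch 1	Ph I	12	9	94.27
Fed-batch 1	Ph I	13	-4	94.31
Fed-batch 1	Ph I	14	72	94.34
Fed-batch 1	Ph II	1	53	58.03
Fed-batch 1	Ph II	2	1	92.43
Fed-batch 1	Ph II	3	6	93.65
Fed-batch 1	Ph II	4	74	94.76
Fed-batch 1	Ph II	5	11	95.54
Fed-batch 1	Ph II	6	-4	96.25
Fed-batch 1	Ph II	7	26	96.95
Fed-batch 1	Ph II	8	102	97.43
Fed-batch 1	Ph II	9	2	97.84
Fed-batch 1	Ph II	10	220	98.08
Fed-batch 1	Ph II	11	41	98.25
Fed-batch 1	Ph II	12	7	98.39
Fed-batch 1	Ph II	13	45	98.45
Fed-batch 1	Ph II	14	43	98.50
Fed-batch 1	Ph II	15	-5	98.52
Fed-batch 1	Ph II	16	3	98.55
Fed-batch 1	Ph III	1	62	69.34
Fed-batch 1	Ph III	2	1	82.00
Fed-batch 1	Ph III	3	6	88.68
Fed-batch 1	Ph III	4	171	92.55
Fed-batch 1	Ph III	5	24	94.38
Fed-batch 1	Ph III	6	43	96.05
Fed-batch 1	Ph III	7	7	96.70
Fed-batch 1	Ph III	8	-4	97.01
Fed-batch 1	Ph III	9	102	97.29
Fed-batch 1	Ph III	10	5	97.52
Fed-batch 1	Ph III	11	2	97.72
Fed-batch 1	Ph III	12	11	97.91
Fed-batch 1	Ph IV	1	62	94.84
Fed-batch 1	Ph IV	2	1	96.22
Fed-batch 1	Ph IV	3	6	97.51
Fed-batch 1	Ph IV	4	49	98.49
Fed-batch 1	Ph IV	5	43	99.21
Fed-batch 1	Ph IV	6	24	99.36
Fed-batch 1	Ph IV	7	26	99.42
Fed-batch 1	Ph IV	8	221	99.46
Fed-batch 1	Ph IV	9	7	99.50
Fed-batch 1	Ph IV	10	87	99.54
Fed-batch 1	Ph IV	11	11	99.56
Fed-batch 1	Ph IV	12	4	99.57
Fed-batch 1	Ph IV	13	5	99.57
Fed-batch 1	Ph IV	14	2	99.58
Fed-batch 2	Ph I	1	245	61.90
Fed-batch 2	Ph I	2	6	77.86
Fed-batch 2	Ph I	3	74	82.59
Fed-batch 2	Ph I	4	11	86.59
Fed-batch 2	Ph I	5	102	88.74
Fed-batch 2	Ph I	6	1	90.68
Fed-batch 2	Ph I	7	202	91.67
Fed-batch 2	Ph I	8	-5	92.21
Fed-batch 2	Ph I	9	86	92.69
Fed-batch 2	Ph I	10	41	93.12
Fed-batch 2	Ph I	11	4	93.43
Fed-batch 2	Ph I	12	87	93.71
Fed-batch 2	Ph I	13	43	93.96
Fed-batch 2	Ph I	14	7	94.15
Fed-batch 2	Ph I	15	14	94.27
Fed-batch 2	Ph I	16	15	94.38
Fed-batch 2	Ph I	17	45	94.48
Fed-batch 2	Ph II	1	62	92.01
Fed-batch 2	Ph II	2	6	95.85
Fed-batch 2	Ph II	3	1	97.69
Fed-batch 2	Ph II	4	4	98.40
Fed-batch 2	Ph II	5	11	99.07
Fed-batch 2	Ph II	6	74	99.30
Fed-batch 2	Ph II	7	89	99.33
Fed-batch 2	Ph II	8	220	99.51
Fed-batch 2	Ph II	9	7	99.61
Fed-batch 2	Ph II	10	43	99.68
Fed-batch 2	Ph II	11	227	99.70
Fed-batch 2	Ph II	12	45	99.72
Fed-batch 2	Ph II	13	14	99.73
Fed-batch 2	Ph II	14	24	99.73
Fed-batch 2	Ph III	1	1	82.42
Fed-batch 2	Ph III	2	158	95.65
Fed-batch 2	Ph III	3	11	97.11
Fed-batch 2	Ph III	4	82	97.72
Fed-batch 2	Ph III	5	139	98.24
Fed-batch 2	Ph III	6	45	98.33
Fed-batch 2	Ph III	7	43	98.40
Fed-batch 2	Ph III	8	-4	98.48
Fed-batch 2	Ph III	9	5	98.52
Fed-batch 2	Ph III	10	42	98.56
Fed-batch 2	Ph III	11	3	98.59
Fed-batch 2	Ph III	12	7	98.61
Fed-batch 2	Ph III	13	6	98.62
Fed-batch 2	Ph III	14	24	98.63
Fed-batch 2	Ph III	15	88	98.64
Fed-batch 2	Ph IV	1	1	29.01
Fed-batch 2	Ph IV	2	126	56.64
Fed-batch 2	Ph IV	3	6	79.18
Fed-batch 2	Ph IV	4	11	85.38
Fed-batch 2	Ph IV	5	82	89.67
Fed-batch 2	Ph IV	6	5	91.12
Fed-batch 2	Ph IV	7	124	92.88
Fed-batch 2	Ph IV	8	3	94.21
Fed-batch 2	Ph IV	9	4	95.08
Fed-batch 2	Ph IV	10	43	95.85
Fed-batch 2	Ph IV	11	7	96.32
Fed-batch 2	Ph IV	12	181	96.59
Fed-batch 2	Ph IV	13	24	96.72
Fed-batch 2	Ph IV	14	112	96.80
Fed-batch 2	Ph IV	15	102	96.86
Fed-batch 2	Ph IV	16	45	96.90
Fed-batch 2	Ph IV	17	15	96.93
Fed-batch 2	Ph V	1	121	34.08
Fed-batch 2	Ph V	2	7	51.99
Fed-batch 2	Ph V	3	6	64.06
Fed-batch 2	Ph V	4	169	73.55
Fed-batch 2	Ph V	5	49	80.98
Fed-batch 2	Ph V	6	164	83.33
Fed-batch 2	Ph V	7	1	84.78
Fed-batch 2	Ph V	8	-4	85.87
Fed-batch 2	Ph V	9	5	86.47
Fed-batch 2	Ph V	10	183	87.03
Fed-batch 2	Ph V	11	3	87.62
Fed-batch 2	Ph V	12	11	88.07
Fed-batch 2	Ph V	13	44	88.38
Fed-batch 2	Ph V	14	120	88.65
Fed-batch 2	Ph V	15	9	88.95
Fed-batch 2	Ph V	16	225	89.20
Fed-batch 3	Ph I	1	110	61.76
Fed-batch 3	Ph I	2	6	69.92
Fed-batch 3	Ph I	3	11	75.82
Fed-batch 3	Ph I	4	-7	81.63
Fed-batch 3	Ph I	5	2	87.34
Fed-batch 3	Ph I	6	5	91.93
Fed-batch 3	Ph I	7	4	94.05
Fed-batch 3	Ph I	8	101	95.86
Fed-batch 3	Ph I	9	43	96.45
Fed-batch 3	Ph I	10	1	97.02
Fed-batch 3	Ph I	11	86	97.55
Fed-batch 3	Ph I	12	45	97.67
Fed-batch 3	Ph I	13	33	97.77
Fed-batch 3	Ph I	14	24	97.83
Fed-batch 3	Ph I	15	41	97.89
Fed-batch 3	Ph I	16	74	97.91
Fed-batch 3	Ph I	17	3	97.92
Fed-batch 3	Ph II	1	250	65.02
Fed-batch 3	Ph II	2	1	89.68
Fed-batch 3	Ph II	3	41	93.81
Fed-batch 3	Ph II	4	28	96.57
Fed-batch 3	Ph II	5	43	97.04
Fed-batch 3	Ph II	6	-4	97.40
Fed-batch 3	Ph II	7	5	97.63
Fed-batch 3	Ph II	8	47	97.84
Fed-batch 3	Ph II	9	6	98.01
Fed-batch 3	Ph II	10	11	98.13
Fed-batch 3	Ph II	11	80	98.24
Fed-batch 3	Ph II	12	102	98.29
Fed-batch 3	Ph II	13	15	98.31
Fed-batch 3	Ph II	14	7	97.34
Fed-batch 3	Ph II	15	87	97.35
Fed-batch 3	Ph II	16	10	97.36
Fed-batch 3	Ph II	17	9	97.37
Fed-batch 3	Ph III	1	62	47.28
Fed-batch 3	Ph III	2	1	90.61
Fed-batch 3	Ph III	3	11	92.80
Fed-batch 3	Ph III	4	6	93.96
Fed-batch 3	Ph III	5	80	95.61
Fed-batch 3	Ph III	6	5	96.28
Fed-batch 3	Ph III	7	43	96.86
Fed-batch 3	Ph III	8	7	97.07
Fed-batch 3	Ph III	9	201	97.14
Fed-batch 3	Ph III	10	-4	97.22
Fed-batch 3	Ph III	11	3	97.27
Fed-batch 3	Ph III	12	45	97.31
Fed-batch 3	Ph III	13	102	97.34
Fed-batch 3	Ph III	14	86	97.35
Fed-batch 3	Ph III	15	81	97.36
Fed-batch 3	Ph III	16	88	97.37
Fed-batch 3	Ph IV	1	62	80.69
Fed-batch 3	Ph IV	2	12	85.98
Fed-batch 3	Ph IV	3	1	89.37
Fed-batch 3	Ph IV	4	86	91.08
Fed-batch 3	Ph IV	5	5	92.29
Fed-batch 3	Ph IV	6	43	93.11
Fed-batch 3	Ph IV	7	7	93.48
Fed-batch 3	Ph IV	8	6	93.88
Fed-batch 3	Ph IV	9	69	94.00
Fed-batch 3	Ph IV	10	11	94.12
Fed-batch 3	Ph IV	11	225	94.16
Fed-batch 3	Ph IV	12	-4	94.19
Fed-batch 3	Ph IV	13	102	94.27
Fed-batch 3	Ph IV	14	79	94.30
Fed-batch 3	Ph V	1	62	84.30
Fed-batch 3	Ph V	2	6	89.43
Fed-batch 3	Ph V	3	1	94.44
Fed-batch 3	Ph V	4	49	97.04
Fed-batch 3	Ph V	5	201	97.53
Fed-batch 3	Ph V	6	119	97.84
Fed-batch 3	Ph V	7	-4	98.14
Fed-batch 3	Ph V	8	11	98.43
Fed-batch 3	Ph V	9	43	98.67
Fed-batch 3	Ph V	10	102	98.87
Fed-batch 3	Ph V	11	5	98.95
Fed-batch 3	Ph V	12	7	99.03
Fed-batch 3	Ph V	13	87	99.11
Fed-batch 3	Ph V	14	15	99.15
Fed-batch 3	Ph V	15	37	99.23
Fed-batch 3	Ph V	16	14	99.27
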