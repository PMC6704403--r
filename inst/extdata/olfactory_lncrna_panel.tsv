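transcript	strand	annotation	expression_group	abundance_VNO	spm_VNO	abundance_MOE	spm_MOE	group
VNO-A	-		High	453.23	0.97	4.87	0.25	VNO_pref
VNO-B	+		High	26.22	0.99	0.88	0.14	VNO_pref
VNO-C	+		High	7.40	1.00	0.00	0.00	VNO_pref
VNO-D	-	Gm33206	Medium	5.00	0.99	0.00	0.00	VNO_pref
VNO-E	-		Medium	4.57	1.00	0.06	0.02	VNO_pref
VNO-F	-		Low	2.38	1.00	0.00	0.00	VNO_pref
VNO-G	+		Low	1.71	1.00	0.00	0.00	VNO_pref
MOE-A	n.d.	Gm31557	High	3.67	0.17	17.62	0.98	MOE_pref
MOE-B	-		High	1.80	0.11	11.93	0.99	MOE_pref
MOE-C	+		Medium	0.29	0.11	7.48	0.94	MOE_pref
MOE-D	+		Medium	0.12	0.09	6.46	1.00	MOE_pref
MOE-E	+		Medium	0.30	0.18	6.29	0.98	MOE_pref
MOE-F	-		Low	0.09	0.11	3.86	0.99	MOE_pref
MOE-G	-		Low	0.00	0.00	2.56	1.00	MOE_pref
VNO/MOE-A	-	Tmem74bos	High	33.00	0.66	92.17	0.72	VNO+MOE_pref
VNO/MOE-B	-	BC051077	High	14.55	0.65	35.40	0.68	VNO+MOE_pref
VNO/MOE-C	+		Medium	8.52	0.76	9.73	0.59	VNO+MOE_pref
VNO/MOE-D	-	Gm20675	Medium	6.51	0.73	9.00	0.68	VNO+MOE_pref
VNO/MOE-E	+		Medium	5.04	0.70	5.29	0.56	VNO+MOE_pref
VNO/MOE-F	+	Gm12996	Medium	4.70	0.70	5.72	0.59	VNO+MOE_pref
VNO/MOE-G	+	Platr3	Low	2.55	0.79	3.42	0.60	VNO+MOE_pref
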