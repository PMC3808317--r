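id	count_ck	count_trt	regulation	significance
miRn3	65	8	down	**
miRn4	1045	574	down	
miRn5	5	0	down	**
miRn11	0	242	up	**
miRn14	0	28	up	**
miRn15	222	34	down	**
miRn17	8	0	down	**
miRn19	0	21	up	**
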