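library	class	unique	total
CK	total	4615663	15779290
CK	miRNA	31280	1771311
CK	rRNA	118421	3186388
CK	snRNA	6539	39651
CK	snoRNA	2354	5761
CK	tRNA	10194	239977
CK	unannotated	4446875	10536202
Cd200	total	4071113	13495250
Cd200	miRNA	28788	1152100
Cd200	rRNA	155413	3328122
Cd200	snRNA	5233	21793
Cd200	snoRNA	1796	4020
Cd200	tRNA	17094	951177
Cd200	unannotated	3862789	8038038
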