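class	unique	total
total	7703916	29274540
shared	982860	20458468
CK_specific	3632803	5042275
Cd200_specific	3088253	3773797
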