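metric	value
clean_reads	25741860
unique_reads	8037807
mapped_unique	6287867
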