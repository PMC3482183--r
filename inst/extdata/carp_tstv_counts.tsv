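class	count
transition	470892
transversion	241150
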