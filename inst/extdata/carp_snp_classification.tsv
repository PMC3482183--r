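category	intra_count
five_prime_utr	35812
three_prime_utr	51238
synonymous	200492
missense	261267
pre_terminated	14681
skip_stop_codon	9664
undefined	138888
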