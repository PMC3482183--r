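strain	intra_snps	strain_specific_snps
mirror	483276	53938
purse_red	486629	53866
xingguo_red	478028	48701
yellow_river	488281	40131
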