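strain_a	strain_b	inter_snps
mirror	purse_red	33081
mirror	xingguo_red	30846
mirror	yellow_river	25789
purse_red	xingguo_red	29911
purse_red	yellow_river	29536
xingguo_red	yellow_river	27427
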