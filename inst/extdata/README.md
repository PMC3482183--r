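# Fixture tables

Published summary counts from a four-strain common carp (mirror, purse
red, Xingguo red, Yellow River) transcriptome cSNP survey, used by the
test suite and the acceptance script to check that the summary
operations reproduce the tables' internal arithmetic (partition
identities, percentages, totals). The counts are inputs, not outputs,
of this package.

- `carp_snp_classification.tsv` — leaf effect-category counts of the
  non-redundant intra-strain SNP set (the derived coding,
  non-synonymous and grand totals are recomputed by
  `classificationTable()`).
- `carp_tstv_counts.tsv` — transition/transversion counts of the same
  set.
- `carp_strain_counts.tsv` — per-strain intra-strain and
  strain-specific SNP counts.
- `carp_interstrain_counts.tsv` — pairwise inter-strain SNP counts.
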