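---
title: "Transcriptome SNP discovery and multi-strain comparison with strainSNP"
author: "strainSNP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome SNP discovery and multi-strain comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainSNP)
```

## The problem

SNPs discovered in transcribed sequence (cSNPs) are directly
gene-associated, which makes them attractive markers for association
studies in species whose genomes are incompletely assembled but whose
transcriptomes are available — aquaculture fishes being the motivating
case. The design this package supports is: RNA from a pool of
individuals per strain is sequenced, reads are aligned to a reference
transcriptome, and the per-strain alignments are summarised as samtools
mpileup text. From those pileups the package calls SNPs per strain,
classifies them against each contig's open reading frame, compares the
call sets across strains, and produces the descriptive summaries the
design needs (minor allele frequency spectra, transition/transversion
ratios, per-contig SNP distributions, validation rates).

Because the samples are pools, not individuals, a "polymorphic site"
here means *allelic variation within the pool*, and allele frequencies
estimated from read counts are pooled transcript frequencies — they
reflect relative transcript abundance of the two alleles, not genotype
frequencies, and transcription biases (allele-specific expression,
unequal pool contributions) are deliberately not modelled.

## Calling model

Each pileup site in each strain is reduced to quality-filtered allele
counts and then called by two thresholds:

* **Base quality ≥ 20** (`minBaseQuality`): a call with Phred quality
  below 20 (error probability above 1%) is discarded before counting.
  The threshold is applied per base; this is the testable reading of a
  "quality ≥ 20" filter without reimplementing genotype likelihoods.
* **Filtered depth ≥ 10** (`minDepth`): sites with fewer than 10
  surviving calls are *uncallable* — too little evidence to assert
  either monomorphism or polymorphism.
* **Minor-allele support ≥ 2** (`minMinorSupport`): among callable
  sites, the two highest-count alleles are retained (biallelic
  reduction; ties broken alphabetically, the earlier base becoming the
  major allele). If the second allele has at least 2 reads the site is
  *polymorphic*, otherwise *monomorphic* for the top allele. A single
  discordant read is indistinguishable from a sequencing error at
  Q20–Q40, hence the support floor; it is exposed as a knob because it
  is a package decision, not an inherent property of the data. A third
  allele reaching the support floor is flagged but the call stays
  biallelic.

"Monomorphic" therefore means "no second allele with sufficient
support", which is robust to singleton errors, rather than "100% one
allele".

For polymorphic sites the **minor allele frequency** is
`minor / (major + minor)` — third and fourth alleles are excluded from
the denominator — so MAF lies in (0, 0.5], with 0.5 reachable at an
exact tie. Substitutions are classed as **transitions** (A↔G, C↔T) or
**transversions** (all other pairs).

## Effect classification

ORF annotations give each contig at most one coding interval
(`cds_start`..`cds_end`, 1-based inclusive, length divisible by 3) and
a strand; on strand `-` the mRNA reads from `cds_end` toward
`cds_start` and the 5′ UTR is the high-coordinate side. A variant is
located as 5′ UTR, 3′ UTR, coding, or *undefined* (contig without an
ORF). Coding variants are classified by extracting the containing
codon in frame, substituting the alternate base, and translating both
codons with the standard genetic code:

| category          | meaning                                          |
|-------------------|--------------------------------------------------|
| `synonymous`      | amino acids equal (including stop → stop)        |
| `missense`        | amino acids differ, neither codon a stop         |
| `pre_terminated`  | sense codon becomes a stop (premature stop)      |
| `skip_stop_codon` | stop codon becomes a sense codon (read-through)  |

Three boundary decisions are worth stating. A change in the terminal
stop codon that yields another stop (TAA → TGA) is synonymous: the
protein product is unchanged. Codon 1 is translated with the plain
code table, with no initiator-codon rule, so ATG → TTG at the start is
missense (M → L); the taxonomy carries no start-lost category. And at
multi-allele sites each (ref, alt) pair gets its own classification;
for per-site roll-ups the most severe is kept
(`skip_stop_codon > pre_terminated > missense > synonymous`), an
ordering of this package's choosing that reports flag as such. The
reference codon always comes from the reference transcriptome, never a
strain consensus, matching calling against a single reference.

## Strain set algebra

All comparisons operate on a `StrainSiteMatrix`: per site × per strain,
the status uncallable / monomorphic(allele) / polymorphic(allele pair).
SNP identity is the coordinate *plus the unordered allele pair*
(`snpKey`), so two strains polymorphic at one coordinate for different
pairs contribute two distinct non-redundant SNPs — the conservative
choice for downstream assay design, since one probe will not type both.

* **Intra-strain set**: sites polymorphic within one strain.
* **Inter-strain set** (per pair): sites where both strains are
  callable and monomorphic but fixed for different alleles; the key's
  pair is the two consensus alleles. By construction this is disjoint
  from either strain's intra-strain set.
* **Non-redundant sets**: the de-duplicated union of intra-strain sets
  across strains, and of inter-strain sets across all unordered pairs.
* **Strain-specific sets**: polymorphic in exactly one strain. By
  default the *other strains must be callable* for specificity to be
  claimed (`requireCallableOthers = TRUE`): a strain with no usable
  coverage cannot testify that it lacks the polymorphism. The relaxed
  rule is available as a flag.
* **Shared set and Venn regions**: the intersection of all intra-strain
  sets, plus counts for every membership region of the Venn partition;
  the regions sum to the non-redundant intra-strain total.

## The synthetic study generator

The study's raw reads are not reproducible at desk scale, so the
generator creates the conditions the pipeline is designed for and every
stage is tested against implanted ground truth:

* **Reference**: `n_contigs` contigs with lengths uniform in
  `contig_length_range`; a fraction carries an embedded ORF (ATG,
  stop-free body, terminal stop, nonempty UTR flanks, random strand).
* **Truth**: per base, with probability `poly_rate` a within-strain
  polymorphism in one uniformly chosen strain (alternate frequency
  uniform in [0.1, 0.5] — pooled samples rarely show rarer alleles
  above the calling floor); with probability `fixed_diff_rate` a fixed
  difference in one strain. One variant type per site; tri-allelic
  behaviour of the caller is exercised with hand-built pileups instead.
* **Pileups**: depth Poisson(`mean_depth`); read bases drawn from the
  strain's true allele frequencies, miscalled uniformly to another base
  with probability `base_error_rate`; Phred qualities Gaussian
  (`quality_mean` 35, `quality_sd` 5 by default — typical HiSeq-era
  base quality), rounded and truncated to [2, 41]; match symbols
  `.`/`,` by read orientation; a small fraction of sites decorated with
  read start/end markers, indel records and deletion placeholders so
  the decoder's discard rules are exercised on realistic lines.

All draws run under an explicit seed with the caller's RNG state
restored, and identical configurations produce byte-identical FASTA,
ORF, truth and pileup files.

What the generator does **not** emulate: read-level effects (adapter
or alignment artefacts beyond the pileup symbols, indel truth, quality
miscalibration), allele-specific expression, positional coverage bias
along transcripts, and genotype-level structure within pools. Passing
recovery tests therefore demonstrate the correctness of the calling
and set logic under the stated sampling model, not robustness to every
artefact of real RNA-Seq alignments.

## Numerical and format choices

* Coordinates are 1-based inclusive everywhere (pileup/VCF convention).
* Qualities are Phred+33 only; no Solexa/+64 autodetection.
* Indels in pileup text are parsed and discarded (substitutions only);
  the deletion placeholder `*` consumes its paired quality character,
  as samtools emits it.
* Percentages are rounded half-up to one decimal for display; raw
  fractions are kept everywhere else.
* MAF histogram bins are left-closed, width 0.05, with the last bin
  right-closed so 0.5 is counted; the bin width is a documented knob,
  not a claim about any particular published figure.
* Per-contig SNP distributions report exact count classes with the
  cumulative percentage taken over SNPs, not contigs; gene maps are
  binned in 1 Mb intervals by default.

## Problem sizes used by the tests

The recovery suite simulates 4 strains × 200 contigs (300–800 bp) at
mean depth 100 with zero sequencing error — roughly 4 × 110,000 pileup
lines — and requires exact recovery: every implanted polymorphism
called with its allele pair (expected minor support ≥ 10 at this
depth), zero false polymorphic calls, and strain-specific/inter-strain
sets equal to the truth-derived sets. Codon classification is checked
against whole-ORF retranslation for every coding position × 3
alternate alleles over 50 contigs (~10⁴ cases), and the set-algebra
axioms over 1,000 random matrices. These sizes were chosen to give the
estimators tight expectations (binomial noise well below the
assertion margins) while keeping a full run in minutes on one core.

## Known limitations

* The caller is a threshold rule, not a likelihood model: it does not
  weigh quality scores beyond the pass/fail filter and has no notion
  of strand bias or mapping quality.
* Pooled MAF estimates conflate allele frequency with expression; they
  should be read as transcript-pool frequencies.
* One ORF per contig; fusion or polycistronic contigs are out of scope,
  as are splice-site effects (transcript contigs have no introns).
* Inter-strain SNP detection requires monomorphism in *both* strains;
  sites polymorphic in one strain and fixed-different in another are
  visible only through the intra-strain sets.
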