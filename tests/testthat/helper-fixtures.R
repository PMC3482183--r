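# Small in-code fixtures shared across test files.

# the worked contig from the effect-annotation examples:
# 5'UTR GGG | ATG TAC AAA TAA | GG 3'UTR
exampleRef <- function() {
    TranscriptomeRef(
        c(c1 = "GGGATGTACAAATAAGG"),
        data.frame(contig_id = "c1", cds_start = 4L, cds_end = 15L,
                   strand = "+", stringsAsFactors = FALSE))
}

# build a one-row call table directly (bypassing pileups) for set tests
makeCall <- function(contig, pos, strain, status, consensus = NA,
                     major = NA, minor = NA) {
    data.frame(contig_id = contig, position = as.integer(pos),
               strain = strain, ref = NA_character_, status = status,
               consensus = as.character(consensus),
               major = as.character(major), minor = as.character(minor),
               major_count = NA_integer_, minor_count = NA_integer_,
               maf = NA_real_, class = NA_character_, third_allele = NA,
               filtered_depth = NA_integer_, stringsAsFactors = FALSE)
}

# random StrainSiteMatrix for property tests: n sites x strains with
# random statuses and allele assignments
randomMatrix <- function(nSites, strains, pUncallable = 0.1,
                         pPoly = 0.3) {
    bases <- c("A", "C", "G", "T")
    rows <- list()
    for (s in strains) {
        u <- runif(nSites)
        status <- ifelse(u < pUncallable, "uncallable",
                         ifelse(u < pUncallable + pPoly, "polymorphic",
                                "monomorphic"))
        keep <- status != "uncallable"
        if (!any(keep)) next
        cons <- sample(bases, nSites, replace = TRUE)
        minor <- vapply(cons, function(b)
            sample(setdiff(bases, b), 1L), character(1))
        poly <- status == "polymorphic" & keep
        mono <- status == "monomorphic" & keep
        rows[[s]] <- rbind(
            if (any(mono)) makeCall("c1", which(mono), s, "monomorphic",
                                    consensus = cons[mono]),
            if (any(poly)) makeCall("c1", which(poly), s, "polymorphic",
                                    major = cons[poly],
                                    minor = minor[poly]))
    }
    buildStrainSiteMatrix(rows)
}

# brute-force effect oracle: mutate the full contig, retranslate the
# whole ORF in mRNA sense, and diff the proteins
oracleEffect <- function(ref, contig, pos, alt) {
    orf <- orfTable(ref)
    row <- orf[orf$contig_id == contig, , drop = FALSE]
    s <- contigSeq(ref, contig)
    if (nrow(row) == 0L) return("undefined")
    inCds <- pos >= row$cds_start & pos <= row$cds_end
    if (!inCds) {
        lowSide <- pos < row$cds_start
        if (row$strand == "+")
            return(if (lowSide) "five_prime_utr" else "three_prime_utr")
        return(if (lowSide) "three_prime_utr" else "five_prime_utr")
    }
    mut <- s
    substr(mut, pos, pos) <- alt
    cdsOf <- function(x) {
        cds <- substr(x, row$cds_start, row$cds_end)
        if (row$strand == "-")
            cds <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(cds)))
        cds
    }
    # no.init.codon: codon 1 must follow the plain code table, not the
    # initiator rule (TTG/CTG read as M), to match per-codon translation
    tr <- function(cds)
        strsplit(as.character(Biostrings::translate(
            Biostrings::DNAString(cds),
            no.init.codon = TRUE)), "")[[1L]]
    pRef <- tr(cdsOf(s))
    pAlt <- tr(cdsOf(mut))
    diff <- which(pRef != pAlt)
    if (!length(diff)) return("synonymous")
    a <- pRef[diff]
    b <- pAlt[diff]
    if (a != "*" && b == "*") return("pre_terminated")
    if (a == "*" && b != "*") return("skip_stop_codon")
    "missense"
}
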