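EFFECT_CATEGORIES <- c("five_prime_utr", "three_prime_utr", "synonymous",
                       "missense", "pre_terminated", "skip_stop_codon",
                       "undefined")

# severity order for rolling up multi-allele sites to one category
EFFECT_SEVERITY <- c(skip_stop_codon = 4L, pre_terminated = 3L,
                     missense = 2L, synonymous = 1L,
                     five_prime_utr = 0L, three_prime_utr = 0L,
                     undefined = 0L)

#' Locate a contig position relative to its ORF
#'
#' Contigs without an ORF annotation yield \code{"undefined"} everywhere.
#' On strand \code{"+"}, positions below \code{cds_start} are 5' UTR and
#' positions above \code{cds_end} are 3' UTR; on strand \code{"-"} the
#' UTR sides are swapped (the 5' UTR is the high-coordinate side).
#'
#' @param position 1-based position(s) on the contig; vectorised.
#' @param ref A \code{\linkS4class{TranscriptomeRef}}.
#' @param contig A single contig id.
#' @return Character vector over positions: \code{"five_prime_utr"},
#'   \code{"three_prime_utr"}, \code{"coding"} or \code{"undefined"}.
#' @examples
#' ref <- TranscriptomeRef(c(c1 = "GGGATGTACAAATAAGG"),
#'   data.frame(contig_id = "c1", cds_start = 4, cds_end = 15, strand = "+"))
#' locateRegion(c(2, 5, 16), ref, "c1")
#' @export
locateRegion <- function(position, ref, contig) {
    len <- contigLengths(ref)[[contig]]
    if (any(position < 1L | position > len))
        stop("position out of bounds for contig ", contig)
    orf <- orfTable(ref)
    row <- orf[orf$contig_id == contig, , drop = FALSE]
    if (nrow(row) == 0L)
        return(rep("undefined", length(position)))
    low <- position < row$cds_start
    high <- position > row$cds_end
    if (row$strand == "+") {
        ifelse(low, "five_prime_utr", ifelse(high, "three_prime_utr",
                                             "coding"))
    } else {
        ifelse(low, "three_prime_utr", ifelse(high, "five_prime_utr",
                                              "coding"))
    }
}

#' Translate a codon with the standard genetic code
#'
#' @param codon 3-base string(s) over A/C/G/T; vectorised.
#' @return One-letter amino acid code, \code{"*"} for the stops TAA, TAG,
#'   TGA. Ambiguity codes are an error.
#' @examples
#' translateCodon(c("ATG", "TAA", "GGG"))
#' @export
translateCodon <- function(codon) {
    codon <- toupper(codon)
    if (any(nchar(codon) != 3L))
        stop("codons must be 3 bases")
    aa <- unname(Biostrings::GENETIC_CODE[codon])
    if (anyNA(aa))
        stop("codon with ambiguity code: ", codon[is.na(aa)][1L])
    aa
}

revcompChar <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify variant effects against contig ORFs
#'
#' For each (contig, position, ref, alt) the containing codon is extracted
#' in the ORF reading frame (reverse-complemented for strand \code{"-"}),
#' the alternate base substituted, both codons translated with the
#' standard genetic code, and the change categorised:
#' \describe{
#'   \item{five_prime_utr / three_prime_utr}{outside the CDS, by strand}
#'   \item{synonymous}{amino acids equal (including stop-to-stop)}
#'   \item{missense}{amino acids differ, neither codon a stop}
#'   \item{pre_terminated}{sense codon becomes a stop (premature
#'     termination)}
#'   \item{skip_stop_codon}{stop codon becomes a sense codon (stop loss /
#'     read-through)}
#'   \item{undefined}{contig without ORF annotation, or an ambiguity code
#'     in the codon (with a warning)}
#' }
#' The reference codon is always taken from the reference transcriptome;
#' the supplied reference allele must match the contig base (forward
#' strand alphabet) at each position.
#'
#' @param ref A \code{\linkS4class{TranscriptomeRef}}.
#' @param variants A \code{data.frame} with columns \code{contig_id},
#'   \code{position}, \code{ref} (reference base, forward strand) and
#'   \code{alt} (alternate base, forward strand).
#' @return The input with columns \code{region}, \code{category},
#'   \code{ref_codon}, \code{alt_codon}, \code{ref_aa}, \code{alt_aa}
#'   (codons in mRNA sense), \code{codon_index} and
#'   \code{position_in_codon} appended; non-coding rows carry \code{NA}
#'   in the codon columns.
#' @examples
#' ref <- TranscriptomeRef(c(c1 = "GGGATGTACAAATAAGG"),
#'   data.frame(contig_id = "c1", cds_start = 4, cds_end = 15, strand = "+"))
#' classifyEffect(ref, data.frame(contig_id = "c1", position = 9,
#'                                ref = "C", alt = "A"))  # Tyr -> stop
#' @export
classifyEffect <- function(ref, variants) {
    needed <- c("contig_id", "position", "ref", "alt")
    if (!all(needed %in% names(variants)))
        stop("variants must have columns ", paste(needed, collapse = ", "))
    n <- nrow(variants)
    variants$position <- as.integer(variants$position)
    variants$ref <- toupper(variants$ref)
    variants$alt <- toupper(variants$alt)
    unknown <- setdiff(variants$contig_id, contigNames(ref))
    if (length(unknown)) stop("unknown contig: ", unknown[1L])
    if (any(variants$ref == variants$alt))
        stop("ref and alt alleles must differ")
    seqbase <- substr(contigSeqs(ref)[variants$contig_id],
                      variants$position, variants$position)
    mism <- seqbase != variants$ref
    if (any(mism))
        stop(sprintf("reference allele %s at %s:%d does not match contig base %s",
                     variants$ref[mism][1L], variants$contig_id[mism][1L],
                     variants$position[mism][1L], seqbase[mism][1L]))
    orf <- orfTable(ref)
    i <- match(variants$contig_id, orf$contig_id)
    cds_start <- orf$cds_start[i]
    cds_end <- orf$cds_end[i]
    strand <- orf$strand[i]
    len <- contigLengths(ref)[variants$contig_id]
    if (any(variants$position < 1L | variants$position > len))
        stop("position out of contig bounds")

    region <- rep("undefined", n)
    ann <- !is.na(i)
    low <- ann & variants$position < cds_start
    high <- ann & variants$position > cds_end
    coding <- ann & !low & !high
    plus <- !is.na(strand) & strand == "+"
    region[low & plus] <- "five_prime_utr"
    region[high & plus] <- "three_prime_utr"
    region[low & !plus] <- "three_prime_utr"
    region[high & !plus] <- "five_prime_utr"
    region[coding] <- "coding"

    category <- region
    ref_codon <- alt_codon <- ref_aa <- alt_aa <- rep(NA_character_, n)
    codon_index <- position_in_codon <- rep(NA_integer_, n)

    if (any(coding)) {
        k <- which(coding)
        pos <- variants$position[k]
        offset <- as.integer(ifelse(plus[k], pos - cds_start[k],
                                    cds_end[k] - pos))
        ci <- offset %/% 3L + 1L
        pc <- offset %% 3L + 1L
        # forward-strand coordinates of the codon
        cstart <- ifelse(plus[k], cds_start[k] + 3L * (ci - 1L),
                         cds_end[k] - 3L * ci + 1L)
        fwd <- substr(contigSeqs(ref)[variants$contig_id[k]],
                      cstart, cstart + 2L)
        refcod <- ifelse(plus[k], fwd, revcompChar(fwd))
        altbase <- ifelse(plus[k], variants$alt[k],
                          unname(COMPLEMENT[variants$alt[k]]))
        altcod <- refcod
        substr(altcod, pc, pc) <- altbase
        altbase[is.na(altbase) | !altbase %in% c("A", "C", "G", "T")] <- "N"
        amb <- grepl("[^ACGT]", refcod) | altbase == "N"
        if (any(amb))
            warning(sum(amb), " coding variant(s) with ambiguity codes ",
                    "classified undefined")
        raa <- aaa <- rep(NA_character_, length(k))
        raa[!amb] <- translateCodon(refcod[!amb])
        aaa[!amb] <- translateCodon(altcod[!amb])
        cat_k <- rep("undefined", length(k))
        ok <- !amb
        cat_k[ok & raa == aaa] <- "synonymous"
        cat_k[ok & raa != aaa & raa != "*" & aaa != "*"] <- "missense"
        cat_k[ok & raa != "*" & aaa == "*"] <- "pre_terminated"
        cat_k[ok & raa == "*" & aaa != "*"] <- "skip_stop_codon"
        category[k] <- cat_k
        ref_codon[k] <- refcod
        alt_codon[k] <- altcod
        ref_aa[k] <- raa
        alt_aa[k] <- aaa
        codon_index[k] <- ci
        position_in_codon[k] <- pc
        region[k] <- "coding"
    }

    cbind(variants,
          data.frame(region = region, category = category,
                     ref_codon = ref_codon, alt_codon = alt_codon,
                     ref_aa = ref_aa, alt_aa = alt_aa,
                     codon_index = codon_index,
                     position_in_codon = position_in_codon,
                     stringsAsFactors = FALSE))
}

#' Roll up several per-allele categories to one site category
#'
#' Multi-allele sites produce one effect per (ref, alt) pair; reports use
#' the most severe: skip_stop_codon > pre_terminated > missense >
#' synonymous > UTR/undefined (non-coding categories are only returned
#' when no coding category is present, where they are all equivalent and
#' the first is kept).
#'
#' @param categories Character vector of effect categories at one site.
#' @return A single category.
#' @export
mostSevereCategory <- function(categories) {
    if (!length(categories)) stop("no categories to roll up")
    bad <- setdiff(categories, EFFECT_CATEGORIES)
    if (length(bad)) stop("unknown category: ", bad[1L])
    categories[which.max(EFFECT_SEVERITY[categories])]
}
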