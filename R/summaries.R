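#' Round half-up to a fixed number of decimals
#'
#' Display rounding for percentages: 66.15 -> 66.2 (base R's
#' \code{round} rounds half to even). Used by the summary tables.
#'
#' @param x Numeric vector (non-negative in this package's usage).
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1) {
    f <- 10^digits
    sign(x) * floor(abs(x) * f + 0.5) / f
}

#' SNP classification table
#'
#' Tallies effect categories and derives the roll-up totals: coding =
#' synonymous + non-synonymous; non-synonymous = missense +
#' pre-terminated + skip-stop-codon; total = 5'UTR + 3'UTR + coding +
#' undefined. The partition identities are checked and violation is an
#' error.
#'
#' @param categories Character vector with one effect category per SNP
#'   (multi-allele sites already rolled up, see
#'   \code{\link{mostSevereCategory}}); or \code{NULL} when \code{counts}
#'   is given.
#' @param counts Alternative input: named numeric vector of per-category
#'   counts (names from the category set).
#' @return A list with per-category counts (\code{five_prime_utr},
#'   \code{three_prime_utr}, \code{synonymous}, \code{missense},
#'   \code{pre_terminated}, \code{skip_stop_codon}, \code{undefined})
#'   and derived \code{non_synonymous}, \code{coding}, \code{total}.
#' @examples
#' classificationTable(c("synonymous", "synonymous", "missense",
#'                       "missense", "missense", "five_prime_utr"))
#' @export
classificationTable <- function(categories = NULL, counts = NULL) {
    if (is.null(counts)) {
        bad <- setdiff(unique(categories), EFFECT_CATEGORIES)
        if (length(bad)) stop("unknown category label: ", bad[1L])
        counts <- table(factor(categories, levels = EFFECT_CATEGORIES))
        counts <- setNames(as.numeric(counts), names(counts))
    } else {
        bad <- setdiff(names(counts), EFFECT_CATEGORIES)
        if (length(bad)) stop("unknown category label: ", bad[1L])
        full <- setNames(numeric(length(EFFECT_CATEGORIES)),
                         EFFECT_CATEGORIES)
        full[names(counts)] <- counts
        counts <- full
    }
    non_syn <- counts[["missense"]] + counts[["pre_terminated"]] +
        counts[["skip_stop_codon"]]
    coding <- counts[["synonymous"]] + non_syn
    total <- counts[["five_prime_utr"]] + counts[["three_prime_utr"]] +
        coding + counts[["undefined"]]
    if (total != sum(counts))
        stop("classification partition identity violated")
    c(as.list(counts),
      list(non_synonymous = non_syn, coding = coding, total = total))
}

#' Transition/transversion summary
#'
#' @param classes Character vector of per-SNP substitution classes
#'   (\code{"transition"}/\code{"transversion"}), or \code{NULL} when the
#'   counts are given directly.
#' @param nTransitions,nTransversions Direct counts (used when
#'   \code{classes} is \code{NULL}).
#' @return A list with \code{n_transitions}, \code{n_transversions},
#'   \code{total}, \code{pct_transitions}, \code{pct_transversions}
#'   (half-up rounded to one decimal; \code{NA} for an empty input) and
#'   \code{ratio} (ts/tv; \code{NA} when there are no transversions).
#' @examples
#' tstvSummary(nTransitions = 470892, nTransversions = 241150)
#' @export
tstvSummary <- function(classes = NULL, nTransitions = NULL,
                        nTransversions = NULL) {
    if (!is.null(classes)) {
        bad <- setdiff(unique(classes), c("transition", "transversion"))
        if (length(bad)) stop("unknown substitution class: ", bad[1L])
        nTransitions <- sum(classes == "transition")
        nTransversions <- sum(classes == "transversion")
    }
    total <- nTransitions + nTransversions
    list(n_transitions = nTransitions, n_transversions = nTransversions,
         total = total,
         pct_transitions = if (total > 0)
             roundHalfUp(100 * nTransitions / total, 1) else NA_real_,
         pct_transversions = if (total > 0)
             roundHalfUp(100 * nTransversions / total, 1) else NA_real_,
         ratio = if (nTransversions > 0)
             nTransitions / nTransversions else NA_real_)
}

#' Minor allele frequency histogram
#'
#' Bins MAF values into left-closed bins of width \code{binWidth} over
#' (0, 0.5]; the last bin is right-closed so that MAF 0.5 is counted.
#'
#' @param mafs Numeric vector of minor allele frequencies in (0, 0.5].
#' @param binWidth Bin width (default 0.05).
#' @return A \code{data.frame} with \code{bin_lower}, \code{bin_upper},
#'   \code{count} and \code{cumulative_pct} (non-decreasing, ending at
#'   100 for non-empty input).
#' @examples
#' mafHistogram(c(0.02, 0.04, 0.5))
#' @export
mafHistogram <- function(mafs, binWidth = 0.05) {
    if (any(mafs <= 0 | mafs > 0.5))
        stop("MAF values must lie in (0, 0.5]")
    edges <- seq(0, 0.5, by = binWidth)
    if (abs(edges[length(edges)] - 0.5) > 1e-12)
        edges <- c(edges, 0.5)
    nbins <- length(edges) - 1L
    bin <- findInterval(mafs, edges, rightmost.closed = TRUE)
    counts <- tabulate(bin, nbins)
    n <- length(mafs)
    data.frame(bin_lower = edges[-length(edges)], bin_upper = edges[-1L],
               count = counts,
               cumulative_pct = if (n > 0) 100 * cumsum(counts) / n
                                else rep(NA_real_, nbins))
}

#' Per-contig SNP count distribution
#'
#' Tallies SNPs per contig, groups contigs into classes by their SNP
#' count, and accumulates the percentage of SNPs (not contigs) over
#' increasing count classes. Contigs carrying no SNP are included when a
#' reference is supplied.
#'
#' @param snpContigs Character vector with one contig id per SNP.
#' @param ref Optional \code{\linkS4class{TranscriptomeRef}}; contigs
#'   absent from \code{snpContigs} then appear as a zero-SNP class.
#' @return A \code{data.frame} with \code{snps_per_contig} (class value,
#'   ascending), \code{n_contigs}, \code{n_snps} (class value x contigs)
#'   and \code{cumulative_pct_snps}.
#' @examples
#' snpsPerContig(c("c1", "c1", "c2", "c3", "c3", "c3"))
#' @export
snpsPerContig <- function(snpContigs, ref = NULL) {
    perContig <- table(snpContigs)
    perContig <- setNames(as.integer(perContig), names(perContig))
    if (!is.null(ref)) {
        unknown <- setdiff(names(perContig), contigNames(ref))
        if (length(unknown)) stop("SNP on unknown contig: ", unknown[1L])
        zeros <- setdiff(contigNames(ref), names(perContig))
        perContig <- c(perContig, setNames(integer(length(zeros)), zeros))
    }
    cls <- sort(unique(unname(perContig)))
    ncontigs <- vapply(cls, function(k) sum(perContig == k), integer(1))
    nsnps <- cls * ncontigs
    totalSnps <- sum(nsnps)
    data.frame(snps_per_contig = cls, n_contigs = ncontigs,
               n_snps = nsnps,
               cumulative_pct_snps = if (totalSnps > 0)
                   100 * cumsum(nsnps) / totalSnps else rep(NA_real_,
                                                            length(cls)))
}

#' Bin genes along chromosomes and mark the SNP-containing subset
#'
#' Lays each chromosome out in fixed-width intervals (default 1 Mb) and
#' counts, per interval, all genes and the subset of genes containing
#' SNPs. A gene at position p falls in interval floor(p / interval).
#'
#' @param geneMap \code{data.frame} with columns \code{gene_id},
#'   \code{chrom}, \code{chrom_pos} (base-pair position of the gene).
#' @param snpGeneIds Character vector of gene ids containing SNPs; must
#'   be a subset of \code{geneMap$gene_id}.
#' @param interval Bin width in base pairs (default 1e6).
#' @return A \code{data.frame} with \code{chrom}, \code{bin_start}
#'   (0-based interval start), \code{n_genes} and \code{n_snp_genes}.
#' @examples
#' gm <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
#'                  chrom_pos = c(5e5, 1.5e6, 1.6e6))
#' binGenesByInterval(gm, c("g2"))
#' @export
binGenesByInterval <- function(geneMap, snpGeneIds, interval = 1e6) {
    needed <- c("gene_id", "chrom", "chrom_pos")
    if (!all(needed %in% names(geneMap)))
        stop("geneMap must have columns ", paste(needed, collapse = ", "))
    missing <- setdiff(snpGeneIds, geneMap$gene_id)
    if (length(missing))
        stop("SNP gene ids absent from gene map: ",
             paste(missing, collapse = ", "))
    bin <- floor(geneMap$chrom_pos / interval) * interval
    hasSnp <- geneMap$gene_id %in% snpGeneIds
    agg <- stats::aggregate(cbind(n_genes = rep(1L, nrow(geneMap)),
                                  n_snp_genes = as.integer(hasSnp)),
                            by = list(chrom = geneMap$chrom,
                                      bin_start = bin), FUN = sum)
    agg[order(agg$chrom, agg$bin_start), , drop = FALSE]
}

#' Validation rate
#'
#' @param nValidated Number of SNPs confirmed by independent assay.
#' @param nTested Number of SNPs tested (> 0).
#' @return Percentage validated, half-up rounded to one decimal.
#' @examples
#' validationRate(12, 25)  # 48
#' @export
validationRate <- function(nValidated, nTested) {
    if (nTested <= 0) stop("nTested must be positive")
    if (nValidated < 0 || nValidated > nTested)
        stop("nValidated must lie in [0, nTested]")
    roundHalfUp(100 * nValidated / nTested, 1)
}
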