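#' Reference transcriptome with optional ORF annotations
#'
#' Container for a set of cDNA contigs and, for a subset of them, the
#' coordinates of a predicted open reading frame. The ORF table uses
#' 1-based inclusive coordinates on the forward strand of the contig;
#' strand \code{"-"} means the coding sequence reads from \code{cds_end}
#' towards \code{cds_start} (the 5' UTR is then the high-coordinate side).
#'
#' @slot sequences A \code{\link[Biostrings]{DNAStringSet}} of uppercase
#'   contig sequences, uniquely named.
#' @slot orf A \code{data.frame} with columns \code{contig_id},
#'   \code{cds_start}, \code{cds_end}, \code{strand}; at most one row per
#'   contig, CDS length divisible by 3, coordinates within the contig.
#'
#' @seealso \code{\link{readFasta}}, \code{\link{readOrfTable}},
#'   \code{\link{generateContigs}}
#' @exportClass TranscriptomeRef
setClass("TranscriptomeRef",
    slots = c(sequences = "DNAStringSet", orf = "data.frame"))

setValidity("TranscriptomeRef", function(object) {
    seqs <- object@sequences
    orf <- object@orf
    ids <- names(seqs)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
        return("all contigs must be named")
    if (anyDuplicated(ids))
        return(sprintf("duplicate contig id: %s",
                       ids[duplicated(ids)][1L]))
    needed <- c("contig_id", "cds_start", "cds_end", "strand")
    if (!all(needed %in% names(orf)))
        return(sprintf("orf table must have columns %s",
                       paste(needed, collapse = ", ")))
    if (nrow(orf) == 0L)
        return(TRUE)
    if (anyDuplicated(orf$contig_id))
        return("at most one ORF per contig")
    bad <- setdiff(orf$contig_id, ids)
    if (length(bad))
        return(sprintf("ORF for unknown contig: %s", bad[1L]))
    if (!all(orf$strand %in% c("+", "-")))
        return(sprintf("unknown strand symbol '%s'",
                       setdiff(orf$strand, c("+", "-"))[1L]))
    len <- Biostrings::width(seqs)[match(orf$contig_id, ids)]
    if (any(orf$cds_start < 1L) || any(orf$cds_end > len))
        return(sprintf("ORF outside contig bounds for %s",
                       orf$contig_id[which(orf$cds_start < 1L |
                                           orf$cds_end > len)[1L]]))
    if (any(orf$cds_start >= orf$cds_end))
        return(sprintf("cds_start must be < cds_end for %s",
                       orf$contig_id[which(orf$cds_start >= orf$cds_end)[1L]]))
    csl <- orf$cds_end - orf$cds_start + 1L
    if (any(csl %% 3L != 0L))
        return(sprintf("CDS length of %s (%d) is not a multiple of 3",
                       orf$contig_id[which(csl %% 3L != 0L)[1L]],
                       csl[which(csl %% 3L != 0L)[1L]]))
    TRUE
})

#' Construct a TranscriptomeRef
#'
#' @param sequences A named \code{DNAStringSet} or named character vector
#'   of contig sequences; lowercase is folded to uppercase.
#' @param orf Optional ORF coordinate table (columns \code{contig_id},
#'   \code{cds_start}, \code{cds_end}, \code{strand}); \code{NULL} means no
#'   contig has an annotated ORF.
#' @return A \code{\linkS4class{TranscriptomeRef}} object.
#' @examples
#' ref <- TranscriptomeRef(
#'   c(c1 = "GGGATGTACAAATAAGG"),
#'   data.frame(contig_id = "c1", cds_start = 4, cds_end = 15, strand = "+"))
#' ref
#' @export
TranscriptomeRef <- function(sequences, orf = NULL) {
    if (is.character(sequences))
        sequences <- Biostrings::DNAStringSet(toupper(sequences))
    if (is.null(orf))
        orf <- data.frame(contig_id = character(), cds_start = integer(),
                          cds_end = integer(), strand = character(),
                          stringsAsFactors = FALSE)
    orf$contig_id <- as.character(orf$contig_id)
    orf$cds_start <- as.integer(orf$cds_start)
    orf$cds_end <- as.integer(orf$cds_end)
    orf$strand <- as.character(orf$strand)
    rownames(orf) <- NULL
    new("TranscriptomeRef", sequences = sequences, orf = orf)
}

#' Per-site, per-strain call status matrix
#'
#' The substrate of the strain set algebra: one row per genomic site that
#' has a call in any strain, one column per strain, each cell recording
#' the call status (\code{uncallable}, \code{monomorphic} or
#' \code{polymorphic}) together with the consensus allele (monomorphic) or
#' the sorted allele pair (polymorphic). Sites absent from a strain's call
#' table are uncallable in that strain.
#'
#' @slot strains Character vector of strain identifiers (column order).
#' @slot sites \code{data.frame} with columns \code{contig_id},
#'   \code{position} (1-based), one row per site.
#' @slot status Character matrix, sites x strains, values in
#'   \code{c("uncallable", "monomorphic", "polymorphic")}.
#' @slot alleles Character matrix, sites x strains: the consensus base for
#'   monomorphic cells, \code{"X/Y"} (alphabetically sorted) for
#'   polymorphic cells, \code{NA} for uncallable cells.
#'
#' @seealso \code{\link{buildStrainSiteMatrix}},
#'   \code{\link{intraStrainSet}}, \code{\link{nonredundantSets}}
#' @exportClass StrainSiteMatrix
setClass("StrainSiteMatrix",
    slots = c(strains = "character", sites = "data.frame",
              status = "matrix", alleles = "matrix"))

setValidity("StrainSiteMatrix", function(object) {
    n <- nrow(object@sites)
    s <- length(object@strains)
    if (anyDuplicated(object@strains))
        return("strain ids must be unique")
    if (!all(c("contig_id", "position") %in% names(object@sites)))
        return("sites must have contig_id and position columns")
    if (!identical(dim(object@status), c(n, s)) ||
        !identical(dim(object@alleles), c(n, s)))
        return("status/alleles dimensions must be sites x strains")
    ok <- object@status %in% c("uncallable", "monomorphic", "polymorphic")
    if (!all(ok))
        return("status values must be uncallable/monomorphic/polymorphic")
    if (anyDuplicated(paste(object@sites$contig_id, object@sites$position)))
        return("duplicate site")
    TRUE
})
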