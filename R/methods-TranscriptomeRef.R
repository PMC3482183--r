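#' @describeIn TranscriptomeRef Number of contigs.
#' @param x,object A \code{TranscriptomeRef}.
#' @export
setMethod("length", "TranscriptomeRef", function(x) length(x@sequences))

#' Accessors for TranscriptomeRef
#'
#' @param x A \code{\linkS4class{TranscriptomeRef}}.
#' @param contig A single contig id.
#' @return \code{contigNames}: character vector of contig ids.
#'   \code{contigLengths}: named integer vector. \code{contigSeqs}: the
#'   \code{DNAStringSet}. \code{contigSeq}: one contig's sequence as a
#'   character string. \code{orfTable}: the ORF coordinate
#'   \code{data.frame}. \code{hasOrf}: logical vector over contigs.
#' @examples
#' ref <- TranscriptomeRef(c(c1 = "GGGATGTACAAATAAGG"),
#'   data.frame(contig_id = "c1", cds_start = 4, cds_end = 15, strand = "+"))
#' contigNames(ref)
#' contigLengths(ref)
#' hasOrf(ref)
#' @export
contigNames <- function(x) names(x@sequences)

#' @rdname contigNames
#' @export
contigLengths <- function(x)
    setNames(Biostrings::width(x@sequences), names(x@sequences))

#' @rdname contigNames
#' @export
contigSeqs <- function(x) x@sequences

#' @rdname contigNames
#' @export
contigSeq <- function(x, contig) {
    if (!contig %in% names(x@sequences))
        stop("unknown contig: ", contig)
    as.character(x@sequences[[contig]])
}

#' @rdname contigNames
#' @export
orfTable <- function(x) x@orf

#' @rdname contigNames
#' @export
hasOrf <- function(x)
    setNames(names(x@sequences) %in% x@orf$contig_id, names(x@sequences))

setMethod("show", "TranscriptomeRef", function(object) {
    n <- length(object@sequences)
    w <- Biostrings::width(object@sequences)
    cat("TranscriptomeRef with", n, "contigs\n")
    if (n) {
        cat(sprintf("  lengths: %d..%d bp (median %d)\n",
                    min(w), max(w), as.integer(stats::median(w))))
        cat(sprintf("  ORF-annotated contigs: %d\n", nrow(object@orf)))
    }
    invisible(NULL)
})

setMethod("show", "StrainSiteMatrix", function(object) {
    cat("StrainSiteMatrix:", nrow(object@sites), "sites x",
        length(object@strains), "strains\n")
    cat("  strains:", paste(object@strains, collapse = ", "), "\n")
    if (nrow(object@sites)) {
        tab <- table(factor(object@status,
                            c("uncallable", "monomorphic", "polymorphic")))
        cat(sprintf("  cells: %d uncallable, %d monomorphic, %d polymorphic\n",
                    tab[["uncallable"]], tab[["monomorphic"]],
                    tab[["polymorphic"]]))
    }
    invisible(NULL)
})

#' @rdname buildStrainSiteMatrix
#' @param x A \code{StrainSiteMatrix}.
#' @export
strainNames <- function(x) x@strains

#' @rdname buildStrainSiteMatrix
#' @export
siteTable <- function(x) x@sites

#' @rdname buildStrainSiteMatrix
#' @export
callStatus <- function(x) x@status

#' @rdname buildStrainSiteMatrix
#' @export
callAlleles <- function(x) x@alleles
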