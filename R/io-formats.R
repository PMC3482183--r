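#' Read a reference transcriptome FASTA
#'
#' Reads contig sequences, uppercases them and truncates record ids at the
#' first whitespace. File order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named \code{\link[Biostrings]{DNAStringSet}}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 some description", "acgt"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
    seqs <- Biostrings::readDNAStringSet(path)
    nm <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(nm))
        stop("duplicate contig id in FASTA: ", nm[duplicated(nm)][1L])
    names(seqs) <- nm
    Biostrings::DNAStringSet(toupper(seqs))
}

#' Write contigs to FASTA
#'
#' @param seqs A named \code{DNAStringSet} or a
#'   \code{\linkS4class{TranscriptomeRef}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path) {
    if (is(seqs, "TranscriptomeRef")) seqs <- contigSeqs(seqs)
    Biostrings::writeXStringSet(seqs, path, width = 70L)
    invisible(path)
}

#' Read an ORF coordinate table
#'
#' Tab-separated file with header \code{contig_id}, \code{cds_start},
#' \code{cds_end}, \code{strand}; coordinates are 1-based inclusive on the
#' contig's forward strand. Structural constraints (start < end, CDS length
#' a multiple of 3, known strand symbol) are checked here; bounds against
#' contig lengths are checked when the table is joined to sequences in
#' \code{\link{TranscriptomeRef}}.
#'
#' @param path Path to the TSV file.
#' @return A \code{data.frame} with one row per contig ORF.
#' @export
readOrfTable <- function(path) {
    orf <- read.delim(path, stringsAsFactors = FALSE)
    needed <- c("contig_id", "cds_start", "cds_end", "strand")
    if (!all(needed %in% names(orf)))
        stop("ORF table must have columns ", paste(needed, collapse = ", "))
    orf <- orf[needed]
    orf$contig_id <- as.character(orf$contig_id)
    if (any(is.na(orf$cds_start)) || any(is.na(orf$cds_end)))
        stop("non-numeric ORF coordinates")
    bad <- orf$strand %in% c("+", "-")
    if (!all(bad))
        stop("unknown strand symbol '", orf$strand[!bad][1L],
             "' for contig ", orf$contig_id[!bad][1L])
    if (any(orf$cds_start >= orf$cds_end)) {
        i <- which(orf$cds_start >= orf$cds_end)[1L]
        stop("cds_start >= cds_end for contig ", orf$contig_id[i])
    }
    len <- orf$cds_end - orf$cds_start + 1L
    if (any(len %% 3L != 0L)) {
        i <- which(len %% 3L != 0L)[1L]
        stop("CDS length of contig ", orf$contig_id[i], " (", len[i],
             ") is not a multiple of 3")
    }
    orf
}

#' @rdname readOrfTable
#' @param orf An ORF coordinate \code{data.frame}.
#' @param path Output path.
#' @export
writeOrfTable <- function(orf, path) {
    write.table(orf, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a samtools mpileup text file for one strain
#'
#' Parses 6-column mpileup text (contig, position, reference base, depth,
#' base string, quality string) and decodes the base string: \code{.} and
#' \code{,} become the reference base, letters are uppercased, read
#' start/end markers (\code{^} with its mapping-quality character,
#' \code{$}) are consumed, indels (\code{+n}/\code{-n} plus n bases) are
#' discarded, and the deletion placeholder \code{*} is discarded together
#' with its paired quality character. Retained calls are paired
#' positionally with Phred+33 qualities; a count mismatch after decoding
#' is an error naming the offending line.
#'
#' @param path Path to a single-sample mpileup text file.
#' @return A \code{data.frame} with columns \code{contig_id},
#'   \code{position}, \code{ref}, \code{depth} (raw mpileup depth),
#'   \code{calls} (decoded retained calls as one string per site) and
#'   \code{quals} (retained Phred+33 quality characters, same length).
#' @seealso \code{\link{parsePileupLine}} for a single decoded site,
#'   \code{\link{callVariants}} for downstream calling.
#' @export
readPileup <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(data.frame(contig_id = character(), position = integer(),
                          ref = character(), depth = integer(),
                          calls = character(), quals = character(),
                          stringsAsFactors = FALSE))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 6L))
        stop("pileup line ", which(nf < 6L)[1L], ": expected 6 fields, got ",
             nf[which(nf < 6L)[1L]])
    m <- matrix(unlist(lapply(fields, `[`, seq_len(6L))), ncol = 6L,
                byrow = TRUE)
    depth <- suppressWarnings(as.integer(m[, 4L]))
    if (anyNA(depth))
        stop("pileup line ", which(is.na(depth))[1L], ": non-numeric depth")
    pos <- suppressWarnings(as.integer(m[, 2L]))
    if (anyNA(pos))
        stop("pileup line ", which(is.na(pos))[1L], ": non-numeric position")
    dec <- decode_pileup_cpp(m[, 5L], m[, 6L], m[, 3L])
    data.frame(contig_id = m[, 1L], position = pos,
               ref = toupper(m[, 3L]), depth = depth,
               calls = dec$calls, quals = dec$quals,
               stringsAsFactors = FALSE)
}

#' Decode one mpileup line into a pileup site
#'
#' @param line A single 6-column mpileup text line (tab-separated).
#' @return A list with \code{contig_id}, \code{position},
#'   \code{reference_base}, \code{depth}, \code{read_bases} (character
#'   vector of retained calls) and \code{base_qualities} (integer Phred
#'   scores, one per retained call).
#' @examples
#' parsePileupLine("c1\t10\tA\t5\t.,.,G\tIIIII")
#' @export
parsePileupLine <- function(line) {
    tmp <- readPileupText(line)
    list(contig_id = tmp$contig_id[1L], position = tmp$position[1L],
         reference_base = tmp$ref[1L], depth = tmp$depth[1L],
         read_bases = strsplit(tmp$calls[1L], "", fixed = TRUE)[[1L]],
         base_qualities = phredFromChars(tmp$quals[1L]))
}

# decode pileup lines given as a character vector (shared by readPileup
# and parsePileupLine)
readPileupText <- function(lines) {
    path <- tempfile(fileext = ".pileup")
    on.exit(unlink(path))
    writeLines(lines, path)
    readPileup(path)
}

phredFromChars <- function(x) {
    if (!nzchar(x)) return(integer())
    utf8ToInt(x) - 33L
}

#' Write SNP calls as a VCF 4.2 file
#'
#' One record per SNP, sorted by contig then position, with \code{##contig}
#' headers taken from the reference. Per-strain quality-filtered allele
#' depths, minor allele frequency, effect category and
#' transition/transversion class are emitted as INFO fields when the
#' corresponding columns are present.
#'
#' @param snps A \code{data.frame} with columns \code{contig_id},
#'   \code{position}, \code{ref}, \code{alt}; optional columns \code{maf},
#'   \code{category}, \code{class} (transition/transversion) and any
#'   column named \code{AD_<strain>} holding "refCount,altCount" strings.
#' @param ref A \code{\linkS4class{TranscriptomeRef}} (used for
#'   \code{##contig} headers and to verify the REF allele against the
#'   reference sequence).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readSnpVcf}} for the inverse.
#' @export
writeSnpVcf <- function(snps, ref, path) {
    needed <- c("contig_id", "position", "ref", "alt")
    if (!all(needed %in% names(snps)))
        stop("snps must have columns ", paste(needed, collapse = ", "))
    if (nrow(snps)) {
        unknown <- setdiff(snps$contig_id, contigNames(ref))
        if (length(unknown))
            stop("SNP on unknown contig: ", unknown[1L])
        refbase <- substr(contigSeqs(ref)[snps$contig_id],
                          snps$position, snps$position)
        bad <- refbase != snps$ref
        if (any(bad))
            stop(sprintf("REF allele %s at %s:%d disagrees with reference base %s",
                         snps$ref[bad][1L], snps$contig_id[bad][1L],
                         snps$position[bad][1L], refbase[bad][1L]))
    }
    hdr <- c("##fileformat=VCFv4.2",
             "##source=strainSNP",
             sprintf("##contig=<ID=%s,length=%d>", contigNames(ref),
                     contigLengths(ref)),
             "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency from quality-filtered reads\">",
             "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Functional category against the contig ORF\">",
             "##INFO=<ID=TSTV,Number=1,Type=String,Description=\"transition or transversion\">")
    adcols <- grep("^AD_", names(snps), value = TRUE)
    hdr <- c(hdr, sprintf("##INFO=<ID=%s,Number=2,Type=Integer,Description=\"Quality-filtered ref,alt allele depth in strain %s\">",
                          adcols, sub("^AD_", "", adcols)))
    hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- character()
    if (nrow(snps)) {
        ord <- order(snps$contig_id, snps$position)
        snps <- snps[ord, , drop = FALSE]
        info <- rep("", nrow(snps))
        addInfo <- function(info, tag, val) {
            piece <- ifelse(is.na(val), NA_character_,
                            paste0(tag, "=", val))
            ifelse(is.na(piece), info,
                   ifelse(nzchar(info), paste(info, piece, sep = ";"), piece))
        }
        if ("maf" %in% names(snps))
            info <- addInfo(info, "MAF", formatC(snps$maf, format = "g",
                                                 digits = 6))
        if ("category" %in% names(snps))
            info <- addInfo(info, "EFF", snps$category)
        if ("class" %in% names(snps))
            info <- addInfo(info, "TSTV", snps$class)
        for (ad in adcols)
            info <- addInfo(info, ad, snps[[ad]])
        info[!nzchar(info)] <- "."
        body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s", snps$contig_id,
                        snps$position, snps$ref, snps$alt, info)
    }
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read a strainSNP VCF back into a call table
#'
#' Parses the fields \code{\link{writeSnpVcf}} emits; used for round-trip
#' checks and for feeding stored call sets back into the summaries.
#'
#' @param path Path to a VCF file.
#' @return A \code{data.frame} with \code{contig_id}, \code{position},
#'   \code{ref}, \code{alt} and any INFO fields present (\code{maf},
#'   \code{category}, \code{class}, \code{AD_*}).
#' @export
readSnpVcf <- function(path) {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#")]
    empty <- data.frame(contig_id = character(), position = integer(),
                        ref = character(), alt = character(),
                        stringsAsFactors = FALSE)
    if (!length(body)) return(empty)
    f <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(f) < 8L)) stop("malformed VCF data line")
    m <- matrix(unlist(lapply(f, `[`, 1:8)), ncol = 8L, byrow = TRUE)
    out <- data.frame(contig_id = m[, 1L], position = as.integer(m[, 2L]),
                      ref = m[, 4L], alt = m[, 5L], stringsAsFactors = FALSE)
    info <- strsplit(m[, 8L], ";", fixed = TRUE)
    getTag <- function(tag) {
        vapply(info, function(kv) {
            hit <- kv[startsWith(kv, paste0(tag, "="))]
            if (length(hit)) sub("^[^=]+=", "", hit[1L]) else NA_character_
        }, character(1))
    }
    tags <- unique(sub("=.*$", "", unlist(info)))
    tags <- setdiff(tags, ".")
    for (tag in tags) {
        val <- getTag(tag)
        col <- switch(tag, MAF = "maf", EFF = "category", TSTV = "class",
                      tag)
        out[[col]] <- if (tag == "MAF") as.numeric(val) else val
    }
    out
}
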