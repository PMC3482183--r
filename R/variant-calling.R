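#' Quality-filter the base calls of one pileup site
#'
#' Counts A/C/G/T calls whose Phred base quality is at least
#' \code{minBaseQuality} (default 20, i.e. an error probability of at most
#' 1 percent). N calls are discarded.
#'
#' @param site A decoded pileup site as returned by
#'   \code{\link{parsePileupLine}} (list with \code{read_bases} and
#'   \code{base_qualities}).
#' @param minBaseQuality Minimum Phred base quality for a call to count.
#' @return Named integer vector of counts for A, C, G, T.
#' @examples
#' site <- list(read_bases = c("A", "A", "G"),
#'              base_qualities = c(30L, 15L, 25L))
#' filterBases(site)  # A:1 G:1 -- the A@15 call is dropped
#' @export
filterBases <- function(site, minBaseQuality = 20) {
    keep <- site$base_qualities >= minBaseQuality
    b <- site$read_bases[keep]
    c(A = sum(b == "A"), C = sum(b == "C"), G = sum(b == "G"),
      T = sum(b == "T"))
}

#' Call one site from quality-filtered allele counts
#'
#' The depth filter and biallelic reduction: a site whose filtered depth
#' is below \code{minDepth} (default 10) is uncallable. Otherwise the two
#' highest-count alleles are retained; if the second allele has at least
#' \code{minMinorSupport} reads the site is polymorphic (major/minor
#' assignment, ties broken alphabetically with the earlier base as
#' major), else monomorphic for the top allele. A third allele reaching
#' \code{minMinorSupport} is flagged but the site is still reduced to the
#' top two.
#'
#' @param counts Named numeric vector of A/C/G/T counts (as from
#'   \code{\link{filterBases}}); missing bases count 0.
#' @param minDepth Minimum filtered depth for a site to be callable.
#' @param minMinorSupport Minimum reads on the second allele to call a
#'   polymorphism; 1 read is indistinguishable from a sequencing error.
#' @return A list with \code{status} (\code{"uncallable"},
#'   \code{"monomorphic"} or \code{"polymorphic"}) and, depending on
#'   status, \code{consensus} or \code{major}, \code{minor},
#'   \code{major_count}, \code{minor_count}, \code{maf}, \code{class}
#'   (transition/transversion) and \code{third_allele} (logical flag).
#' @examples
#' callSite(c(A = 9))          # uncallable: filtered depth below 10
#' callSite(c(A = 6, G = 4))   # polymorphic, MAF 0.4, transition
#' callSite(c(A = 10, G = 1))  # monomorphic A: minor support below 2
#' @export
callSite <- function(counts, minDepth = 10, minMinorSupport = 2) {
    full <- c(A = 0, C = 0, G = 0, T = 0)
    full[names(counts)] <- counts
    depth <- sum(full)
    if (depth < minDepth)
        return(list(status = "uncallable"))
    ord <- order(-full, names(full))  # count desc, then alphabetical
    top <- names(full)[ord]
    cnt <- unname(full[ord])
    if (cnt[2L] >= minMinorSupport) {
        list(status = "polymorphic", major = top[1L], minor = top[2L],
             major_count = cnt[1L], minor_count = cnt[2L],
             maf = computeMaf(cnt[1L], cnt[2L]),
             class = classifySubstitution(top[1L], top[2L]),
             third_allele = cnt[3L] >= minMinorSupport)
    } else {
        list(status = "monomorphic", consensus = top[1L],
             major_count = cnt[1L])
    }
}

#' Minor allele frequency from the two called alleles
#'
#' @param majorCount,minorCount Quality-filtered read counts of the two
#'   called alleles; third and fourth alleles are excluded from the
#'   denominator.
#' @return \code{minorCount / (majorCount + minorCount)}, in (0, 0.5].
#' @examples
#' computeMaf(6, 4)   # 0.4
#' computeMaf(98, 2)  # 0.02
#' @export
computeMaf <- function(majorCount, minorCount) {
    denom <- majorCount + minorCount
    if (any(denom == 0)) stop("zero denominator in MAF")
    minorCount / denom
}

#' Transition or transversion
#'
#' Purine-purine (A<->G) and pyrimidine-pyrimidine (C<->T) substitutions
#' are transitions; all other base pairs are transversions. Symmetric in
#' its arguments; vectorised.
#'
#' @param a,b Distinct bases in A/C/G/T.
#' @return \code{"transition"} or \code{"transversion"} per pair.
#' @examples
#' classifySubstitution("A", "G")  # transition
#' classifySubstitution("A", "C")  # transversion
#' @export
classifySubstitution <- function(a, b) {
    if (any(a == b)) stop("identical alleles have no substitution class")
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    if (!all(ok)) stop("alleles must be A/C/G/T")
    pur <- c("A", "G")
    ifelse((a %in% pur) == (b %in% pur), "transition", "transversion")
}

#' Call all sites of a strain's pileup
#'
#' Vectorised pipeline over a decoded pileup table: per-base quality
#' filtering (\code{minBaseQuality}), depth filtering (\code{minDepth})
#' and biallelic reduction with minor-allele support
#' (\code{minMinorSupport}), as in \code{\link{filterBases}} and
#' \code{\link{callSite}}.
#'
#' @param pileup A pileup \code{data.frame} from \code{\link{readPileup}}.
#' @param strain Strain identifier recorded in the output.
#' @param minDepth,minBaseQuality,minMinorSupport Calling thresholds; see
#'   \code{\link{callSite}}.
#' @return A \code{data.frame} with one row per pileup site:
#'   \code{contig_id}, \code{position}, \code{strain}, \code{ref},
#'   \code{status}, \code{consensus}, \code{major}, \code{minor},
#'   \code{major_count}, \code{minor_count}, \code{maf}, \code{class},
#'   \code{third_allele}, \code{filtered_depth}.
#' @export
callVariants <- function(pileup, strain, minDepth = 10,
                         minBaseQuality = 20, minMinorSupport = 2) {
    n <- nrow(pileup)
    counts <- count_alleles_cpp(pileup$calls, pileup$quals,
                                as.integer(minBaseQuality))
    fdepth <- rowSums(counts)
    bases <- c("A", "C", "G", "T")
    # rank alleles: higher count wins, alphabetically earlier wins ties
    key <- counts * 4L + rep(3:0, each = max(n, 1L))
    if (n == 0L) key <- counts
    top1 <- max.col(key, ties.method = "first")
    key2 <- key
    key2[cbind(seq_len(n), top1)] <- -1L
    top2 <- max.col(key2, ties.method = "first")
    key3 <- key2
    key3[cbind(seq_len(n), top2)] <- -1L
    top3 <- max.col(key3, ties.method = "first")
    c1 <- counts[cbind(seq_len(n), top1)]
    c2 <- counts[cbind(seq_len(n), top2)]
    c3 <- counts[cbind(seq_len(n), top3)]
    status <- ifelse(fdepth < minDepth, "uncallable",
                     ifelse(c2 >= minMinorSupport, "polymorphic",
                            "monomorphic"))
    poly <- status == "polymorphic"
    mono <- status == "monomorphic"
    out <- data.frame(
        contig_id = pileup$contig_id, position = pileup$position,
        strain = strain, ref = pileup$ref, status = status,
        consensus = NA_character_, major = NA_character_,
        minor = NA_character_, major_count = NA_integer_,
        minor_count = NA_integer_, maf = NA_real_, class = NA_character_,
        third_allele = NA, filtered_depth = as.integer(fdepth),
        stringsAsFactors = FALSE)
    out$consensus[mono] <- bases[top1[mono]]
    out$major_count[mono] <- c1[mono]
    out$major[poly] <- bases[top1[poly]]
    out$minor[poly] <- bases[top2[poly]]
    out$major_count[poly] <- c1[poly]
    out$minor_count[poly] <- c2[poly]
    out$maf[poly] <- c2[poly] / (c1[poly] + c2[poly])
    if (any(poly))
        out$class[poly] <- classifySubstitution(out$major[poly],
                                                out$minor[poly])
    out$third_allele[poly] <- c3[poly] >= minMinorSupport
    out
}
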