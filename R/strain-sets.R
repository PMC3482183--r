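#' SNP keys: contig, position and unordered allele pair
#'
#' A SNP is identified by its coordinate and its allele pair, with the
#' pair sorted alphabetically so that key equality is independent of
#' allele order. Two strains polymorphic at one coordinate with different
#' allele pairs therefore contribute distinct SNPs to non-redundant sets.
#'
#' @param contig,position Coordinate of the site.
#' @param a,b The two alleles (distinct).
#' @return Character vector of keys \code{"contig:position:X/Y"}.
#' @examples
#' snpKey("c1", 7, "G", "A")  # "c1:7:A/G"
#' @export
snpKey <- function(contig, position, a, b) {
    if (any(a == b)) stop("allele pair must be two distinct alleles")
    sprintf("%s:%s:%s/%s", contig, position, pmin(a, b), pmax(a, b))
}

#' Build the per-site x per-strain call status matrix
#'
#' Combines per-strain call tables (from \code{\link{callVariants}}) into
#' a \code{\linkS4class{StrainSiteMatrix}} over the union of their sites.
#' A site missing from a strain's table is uncallable in that strain.
#'
#' @param calls A named list of call \code{data.frame}s, one per strain
#'   (names are strain ids; unnamed lists use each table's \code{strain}
#'   column), or a single combined \code{data.frame} with a \code{strain}
#'   column.
#' @return A \code{StrainSiteMatrix}.
#' @seealso \code{\link{intraStrainSet}}, \code{\link{interStrainSet}},
#'   \code{\link{nonredundantSets}}, \code{\link{strainSpecificSets}},
#'   \code{\link{sharedAllSet}}
#' @export
buildStrainSiteMatrix <- function(calls) {
    if (is.data.frame(calls))
        calls <- split(calls, calls$strain)
    if (is.null(names(calls)) || any(!nzchar(names(calls))))
        names(calls) <- vapply(calls, function(d) d$strain[1L], character(1))
    strains <- names(calls)
    all_sites <- unique(do.call(rbind, lapply(calls, function(d)
        d[c("contig_id", "position")])))
    all_sites <- all_sites[order(all_sites$contig_id, all_sites$position), ,
                           drop = FALSE]
    rownames(all_sites) <- NULL
    skey <- paste(all_sites$contig_id, all_sites$position)
    n <- nrow(all_sites)
    status <- matrix("uncallable", n, length(strains),
                     dimnames = list(NULL, strains))
    alleles <- matrix(NA_character_, n, length(strains),
                      dimnames = list(NULL, strains))
    for (s in strains) {
        d <- calls[[s]]
        i <- match(paste(d$contig_id, d$position), skey)
        status[i, s] <- d$status
        mono <- d$status == "monomorphic"
        poly <- d$status == "polymorphic"
        alleles[i[mono], s] <- d$consensus[mono]
        alleles[i[poly], s] <- paste0(pmin(d$major[poly], d$minor[poly]),
                                      "/", pmax(d$major[poly],
                                                d$minor[poly]))
    }
    new("StrainSiteMatrix", strains = strains, sites = all_sites,
        status = status, alleles = alleles)
}

checkStrain <- function(m, strain) {
    if (!strain %in% m@strains) stop("unknown strain: ", strain)
    strain
}

#' Intra-strain SNP set
#'
#' All sites where the given strain is polymorphic, keyed by coordinate
#' and that strain's allele pair.
#'
#' @param m A \code{\linkS4class{StrainSiteMatrix}}.
#' @param strain Strain id.
#' @return Character vector of SNP keys.
#' @export
intraStrainSet <- function(m, strain) {
    checkStrain(m, strain)
    i <- m@status[, strain] == "polymorphic"
    sprintf("%s:%s:%s", m@sites$contig_id[i], m@sites$position[i],
            m@alleles[i, strain])
}

#' Inter-strain SNP set for a strain pair
#'
#' Sites where both strains are callable and monomorphic but fixed for
#' different alleles; the key's allele pair is the two consensus alleles.
#' Monomorphism within each strain is required, so this set is disjoint
#' from both strains' intra-strain sets.
#'
#' @param m A \code{\linkS4class{StrainSiteMatrix}}.
#' @param strainA,strainB Two distinct strain ids.
#' @return Character vector of SNP keys.
#' @export
interStrainSet <- function(m, strainA, strainB) {
    checkStrain(m, strainA)
    checkStrain(m, strainB)
    if (strainA == strainB) stop("inter-strain set needs two distinct strains")
    sa <- m@status[, strainA]
    sb <- m@status[, strainB]
    i <- sa == "monomorphic" & sb == "monomorphic" &
        m@alleles[, strainA] != m@alleles[, strainB]
    snpKey(m@sites$contig_id[i], m@sites$position[i],
           m@alleles[i, strainA], m@alleles[i, strainB])
}

#' Non-redundant SNP sets over all strains
#'
#' \code{intra}: the de-duplicated union of all per-strain intra-strain
#' sets. \code{inter}: the de-duplicated union of
#' \code{\link{interStrainSet}} over all unordered strain pairs.
#'
#' @param m A \code{\linkS4class{StrainSiteMatrix}} with at least 2
#'   strains.
#' @return A list with character vectors \code{intra} and \code{inter}.
#' @export
nonredundantSets <- function(m) {
    if (length(m@strains) < 2L) stop("need at least 2 strains")
    intra <- unique(unlist(lapply(m@strains, intraStrainSet, m = m),
                           use.names = FALSE))
    pairs <- utils::combn(m@strains, 2L)
    inter <- unique(unlist(lapply(seq_len(ncol(pairs)), function(j)
        interStrainSet(m, pairs[1L, j], pairs[2L, j])), use.names = FALSE))
    list(intra = as.character(intra), inter = as.character(inter))
}

#' Strain-specific SNP sets
#'
#' A SNP is specific to strain s when s is polymorphic there and every
#' other strain is not. By default the other strains must also be
#' callable (depth at threshold) for specificity to be claimed: absence
#' of evidence in an uncallable strain is not evidence of specificity.
#' The resulting sets are pairwise disjoint.
#'
#' @param m A \code{\linkS4class{StrainSiteMatrix}}.
#' @param requireCallableOthers If \code{TRUE} (default), sites where any
#'   other strain is uncallable are excluded; if \code{FALSE}, only
#'   polymorphism elsewhere disqualifies a site.
#' @return Named list (per strain) of SNP key vectors.
#' @export
strainSpecificSets <- function(m, requireCallableOthers = TRUE) {
    if (length(m@strains) < 2L) stop("need at least 2 strains")
    poly <- m@status == "polymorphic"
    unc <- m@status == "uncallable"
    npoly <- rowSums(poly)
    nunc <- rowSums(unc)
    out <- lapply(m@strains, function(s) {
        i <- poly[, s] & npoly == 1L
        if (requireCallableOthers) i <- i & nunc == 0L
        sprintf("%s:%s:%s", m@sites$contig_id[i], m@sites$position[i],
                m@alleles[i, s])
    })
    names(out) <- m@strains
    out
}

#' Intra-strain SNPs shared by all strains, with Venn region counts
#'
#' The intersection of all per-strain intra-strain sets, plus counts for
#' every membership region of the Venn partition of their union (2^n - 1
#' non-empty regions for n strains, keyed by the strain names joined
#' with \code{"&"}).
#'
#' @param m A \code{\linkS4class{StrainSiteMatrix}}.
#' @return A list with \code{shared} (keys in every strain's intra set)
#'   and \code{venn} (named integer vector of region counts; regions sum
#'   to the size of the non-redundant intra-strain set).
#' @export
sharedAllSet <- function(m) {
    if (length(m@strains) < 2L) stop("need at least 2 strains")
    sets <- lapply(m@strains, intraStrainSet, m = m)
    names(sets) <- m@strains
    keys <- unique(unlist(sets, use.names = FALSE))
    memb <- vapply(sets, function(s) keys %in% s,
                   logical(length(keys)))
    if (length(keys) == 1L) memb <- matrix(memb, nrow = 1L,
                                           dimnames = list(NULL, m@strains))
    if (length(keys) == 0L)
        memb <- matrix(logical(), 0L, length(m@strains),
                       dimnames = list(NULL, m@strains))
    pattern <- if (length(keys)) apply(memb, 1L, function(r)
        paste(m@strains[r], collapse = "&")) else character(0)
    allPatterns <- unlist(lapply(seq_along(m@strains), function(k)
        apply(utils::combn(m@strains, k), 2L, paste, collapse = "&")))
    venn <- table(factor(pattern, levels = allPatterns))
    shared <- keys[rowSums(memb) == length(m@strains)]
    list(shared = as.character(shared),
         venn = setNames(as.integer(venn), names(venn)))
}
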