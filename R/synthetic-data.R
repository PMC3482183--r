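BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# run expr with a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Configuration for the synthetic study generator
#'
#' Bundles and validates the knobs of the simulated study: a multi-contig
#' cDNA reference with embedded ORFs, per-strain allele configurations
#' (within-strain polymorphisms and fixed between-strain differences at
#' given per-base rates), and pileups at a given mean depth, base-quality
#' distribution and sequencing-error rate.
#'
#' @param n_contigs Number of reference contigs.
#' @param contig_length_range Integer pair (min, max) contig length in
#'   bases; the minimum must be at least 30 so every contig can host a
#'   minimal ORF (start codon, one sense codon, stop codon, nonempty
#'   UTRs).
#' @param orf_fraction Proportion of contigs given an ORF annotation.
#' @param n_strains Number of strains.
#' @param strain_names Strain identifiers (default \code{strain1..N}).
#' @param poly_rate Per-base probability that a site carries a
#'   within-strain polymorphism in one uniformly chosen strain.
#' @param fixed_diff_rate Per-base probability that a site carries a
#'   fixed difference: one strain fixed for a non-reference allele, the
#'   others fixed reference. A site never carries both variant types, so
#'   the two rates must not sum above 1.
#' @param mean_depth Expected reads per site (Poisson).
#' @param base_error_rate Per-base miscall probability in [0, 1).
#' @param quality_mean,quality_sd Phred base qualities are drawn from a
#'   Gaussian with this mean and sd, rounded and truncated to [2, 41]
#'   (the Illumina quality range).
#' @param seed Integer seed; identical configurations yield
#'   byte-identical outputs.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @examples
#' simulationConfig(n_contigs = 3, seed = 7)
#' @export
simulationConfig <- function(n_contigs = 50,
                             contig_length_range = c(300L, 800L),
                             orf_fraction = 0.7, n_strains = 4,
                             strain_names = NULL, poly_rate = 0.002,
                             fixed_diff_rate = 0.001, mean_depth = 30,
                             base_error_rate = 0.001, quality_mean = 35,
                             quality_sd = 5, seed = 1L) {
    stopifnot(n_contigs >= 1, n_strains >= 1, mean_depth > 0,
              quality_sd >= 0, length(contig_length_range) == 2L)
    contig_length_range <- as.integer(contig_length_range)
    if (contig_length_range[1L] < 30L)
        stop("minimum contig length must be at least 30")
    if (contig_length_range[1L] > contig_length_range[2L])
        stop("contig_length_range must be (min, max) with min <= max")
    rates <- c(orf_fraction = orf_fraction, poly_rate = poly_rate,
               fixed_diff_rate = fixed_diff_rate,
               base_error_rate = base_error_rate)
    if (any(rates < 0 | rates > 1))
        stop("all rates must lie in [0, 1]")
    if (base_error_rate >= 1) stop("base_error_rate must be below 1")
    if (poly_rate + fixed_diff_rate > 1)
        stop("poly_rate + fixed_diff_rate must not exceed 1")
    if (is.null(strain_names))
        strain_names <- sprintf("strain%d", seq_len(n_strains))
    if (length(strain_names) != n_strains ||
        anyDuplicated(strain_names))
        stop("strain_names must be n_strains unique ids")
    structure(list(n_contigs = as.integer(n_contigs),
                   contig_length_range = contig_length_range,
                   orf_fraction = orf_fraction,
                   n_strains = as.integer(n_strains),
                   strain_names = strain_names, poly_rate = poly_rate,
                   fixed_diff_rate = fixed_diff_rate,
                   mean_depth = mean_depth,
                   base_error_rate = base_error_rate,
                   quality_mean = quality_mean, quality_sd = quality_sd,
                   seed = as.integer(seed)),
              class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat("SimulationConfig:", x$n_contigs, "contigs (",
        x$contig_length_range[1L], "-", x$contig_length_range[2L],
        "bp ),", x$n_strains, "strains\n")
    cat(sprintf("  orf_fraction %.2f, poly_rate %g, fixed_diff_rate %g\n",
                x$orf_fraction, x$poly_rate, x$fixed_diff_rate))
    cat(sprintf("  mean_depth %g, base_error_rate %g, quality %g+/-%g, seed %d\n",
                x$mean_depth, x$base_error_rate, x$quality_mean,
                x$quality_sd, x$seed))
    invisible(x)
}

senseCodons <- function() {
    all <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
    setdiff(all, STOP_CODONS)
}

#' Generate a synthetic reference transcriptome
#'
#' Contigs of uniform-random length within the configured range; a
#' fraction of them receives an embedded ORF starting with ATG, ending
#' with a stop codon, free of internal stops in frame, with nonempty 5'
#' and 3' UTR flanks, on a random strand. Deterministic given the
#' configuration seed.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return A \code{\linkS4class{TranscriptomeRef}}.
#' @export
generateContigs <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    withSeed(config$seed, {
        sense <- senseCodons()
        ids <- sprintf("contig%04d", seq_len(config$n_contigs))
        lenChoices <- seq(config$contig_length_range[1L],
                          config$contig_length_range[2L])
        lens <- lenChoices[sample.int(length(lenChoices),
                                      config$n_contigs, replace = TRUE)]
        giveOrf <- runif(config$n_contigs) < config$orf_fraction
        seqs <- character(config$n_contigs)
        orf <- vector("list", config$n_contigs)
        for (i in seq_len(config$n_contigs)) {
            L <- lens[i]
            s <- sample(BASES, L, replace = TRUE)
            if (giveOrf[i]) {
                maxCodons <- (L - 2L) %/% 3L
                if (maxCodons < 3L)
                    stop("contig too short to host a minimal ORF")
                k <- (3:maxCodons)[sample.int(maxCodons - 2L, 1L)]
                cdsLen <- 3L * k
                utr5 <- sample(seq_len(L - cdsLen - 1L), 1L)
                cdsStart <- utr5 + 1L
                cdsEnd <- cdsStart + cdsLen - 1L
                cds <- paste0("ATG",
                              paste(sample(sense, k - 2L, replace = TRUE),
                                    collapse = ""),
                              sample(STOP_CODONS, 1L))
                strand <- sample(c("+", "-"), 1L)
                ins <- if (strand == "+") cds else revcompChar(cds)
                s[cdsStart:cdsEnd] <- strsplit(ins, "", fixed = TRUE)[[1L]]
                orf[[i]] <- data.frame(contig_id = ids[i],
                                       cds_start = cdsStart,
                                       cds_end = cdsEnd, strand = strand,
                                       stringsAsFactors = FALSE)
            }
            seqs[i] <- paste(s, collapse = "")
        }
        TranscriptomeRef(setNames(seqs, ids), do.call(rbind, orf))
    })
}

#' Implant ground-truth variants into a reference
#'
#' Each base independently receives, with probability \code{poly_rate}, a
#' within-strain polymorphism in one uniformly chosen strain (alternate
#' allele frequency uniform in [0.1, 0.5]); or, with probability
#' \code{fixed_diff_rate}, a fixed between-strain difference (one
#' uniformly chosen strain fixed for a non-reference allele, the others
#' fixed reference). No site carries both. Deterministic given the seed.
#'
#' @param ref A \code{\linkS4class{TranscriptomeRef}} from
#'   \code{\link{generateContigs}}.
#' @param config The same \code{\link{simulationConfig}}.
#' @return A \code{data.frame} with columns \code{contig_id},
#'   \code{position}, \code{ref} (reference base), \code{type}
#'   (\code{"polymorphic"}/\code{"fixed"}), \code{strain} (the affected
#'   strain; all others are fixed reference), \code{alt} and \code{freq}
#'   (alternate allele frequency for polymorphic sites, \code{NA} for
#'   fixed differences).
#' @export
implantTruth <- function(ref, config) {
    stopifnot(inherits(config, "SimulationConfig"))
    withSeed(config$seed + 1L, {
        ids <- contigNames(ref)
        lens <- contigLengths(ref)
        out <- vector("list", length(ids))
        for (i in seq_along(ids)) {
            L <- lens[[i]]
            u <- runif(L)
            isPoly <- u < config$poly_rate
            isFixed <- !isPoly &
                u < config$poly_rate + config$fixed_diff_rate
            pos <- c(which(isPoly), which(isFixed))
            if (!length(pos)) next
            type <- rep(c("polymorphic", "fixed"),
                        c(sum(isPoly), sum(isFixed)))
            refb <- strsplit(contigSeq(ref, ids[i]), "",
                             fixed = TRUE)[[1L]][pos]
            strain <- config$strain_names[sample.int(config$n_strains,
                                                     length(pos),
                                                     replace = TRUE)]
            shift <- sample.int(3L, length(pos), replace = TRUE)
            alt <- BASES[(match(refb, BASES) - 1L + shift) %% 4L + 1L]
            freq <- ifelse(type == "polymorphic",
                           runif(length(pos), 0.1, 0.5), NA_real_)
            ord <- order(pos)
            out[[i]] <- data.frame(contig_id = ids[i], position = pos[ord],
                                   ref = refb[ord], type = type[ord],
                                   strain = strain[ord], alt = alt[ord],
                                   freq = freq[ord],
                                   stringsAsFactors = FALSE)
        }
        out <- out[!vapply(out, is.null, logical(1))]
        if (!length(out))
            return(data.frame(contig_id = character(),
                              position = integer(), ref = character(),
                              type = character(), strain = character(),
                              alt = character(), freq = numeric(),
                              stringsAsFactors = FALSE))
        res <- do.call(rbind, out)
        rownames(res) <- NULL
        res
    })
}

QCHAR_MIN <- 2L
QCHAR_MAX <- 41L

decorateSite <- function(sym, qual) {
    # sprinkle alignment bookkeeping symbols over one site's reads:
    # read-start (^ + mapping quality), read-end ($), an indel record and
    # a deletion placeholder (*), all of which the decoder must discard
    reads <- strsplit(sym, "", fixed = TRUE)[[1L]]
    n <- length(reads)
    j <- sample.int(n, 1L)
    reads[j] <- paste0("^", intToUtf8(sample(33:90, 1L)), reads[j])
    j <- sample.int(n, 1L)
    reads[j] <- paste0(reads[j], "$")
    if (n >= 2L && runif(1) < 0.5) {
        j <- sample.int(n, 1L)
        indel <- sample(c("+", "-"), 1L)
        ilen <- sample.int(3L, 1L)
        reads[j] <- paste0(reads[j], indel, ilen,
                           paste(sample(BASES, ilen, replace = TRUE),
                                 collapse = ""))
    }
    if (n >= 2L && runif(1) < 0.5) {
        j <- sample.int(n, 1L)
        # strip any decoration already attached, keep it a bare placeholder
        reads[j] <- sub("[.,ACGTacgt]", "*", reads[j])
    }
    paste(reads, collapse = "")
}

#' Simulate per-strain pileup files
#'
#' For every strain and every reference position, a read depth is drawn
#' Poisson(\code{mean_depth}); each read base is drawn from the strain's
#' true allele frequencies at that site (from the truth table), then
#' miscalled uniformly to another base with probability
#' \code{base_error_rate}; Phred qualities are Gaussian around
#' \code{quality_mean}, truncated to [2, 41]. Output is samtools mpileup
#' 6-column text with \code{.}/\code{,} match encoding and mixed read
#' orientation; zero-depth sites are omitted, as samtools does. With
#' \code{artifacts = TRUE} a small fraction of sites additionally carry
#' read-start/read-end markers, indel records and deletion placeholders,
#' which downstream decoding discards. Deterministic given the seed.
#'
#' @param ref A \code{\linkS4class{TranscriptomeRef}}.
#' @param truth Truth table from \code{\link{implantTruth}}.
#' @param config The \code{\link{simulationConfig}}.
#' @param dir Output directory (created if needed).
#' @param artifacts Decorate ~2 percent of sites with alignment
#'   bookkeeping symbols (default \code{TRUE}).
#' @return Named character vector of per-strain pileup paths, invisibly.
#' @export
simulatePileups <- function(ref, truth, config, dir = tempfile("pileups"),
                            artifacts = TRUE) {
    stopifnot(inherits(config, "SimulationConfig"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ids <- contigNames(ref)
    lens <- contigLengths(ref)
    qpool <- QCHAR_MIN:QCHAR_MAX
    paths <- setNames(file.path(dir, paste0(config$strain_names,
                                            ".pileup")),
                      config$strain_names)
    withSeed(config$seed + 2L, {
        for (s in config$strain_names) {
            con <- file(paths[[s]], open = "wt")
            for (i in seq_along(ids)) {
                L <- lens[[i]]
                seqchars <- strsplit(contigSeq(ref, ids[i]), "",
                                     fixed = TRUE)[[1L]]
                d <- rpois(L, config$mean_depth)
                total <- sum(d)
                if (total == 0L) next
                siteIdx <- rep.int(seq_len(L), d)
                base <- seqchars[siteIdx]
                t_c <- truth[truth$contig_id == ids[i] &
                             truth$strain == s, , drop = FALSE]
                altAt <- rep(NA_character_, L)
                freqAt <- rep(NA_real_, L)
                poly <- t_c$type == "polymorphic"
                altAt[t_c$position] <- t_c$alt
                freqAt[t_c$position[poly]] <- t_c$freq[poly]
                # fixed difference: every read carries the alternate
                fixedPos <- t_c$position[!poly]
                isFixed <- siteIdx %in% fixedPos
                base[isFixed] <- altAt[siteIdx][isFixed]
                # polymorphism: reads carry the alternate at its frequency
                f <- freqAt[siteIdx]
                f[is.na(f)] <- 0
                hit <- runif(total) < f
                base[hit] <- altAt[siteIdx][hit]
                if (config$base_error_rate > 0) {
                    err <- runif(total) < config$base_error_rate
                    ne <- sum(err)
                    if (ne) {
                        shift <- sample.int(3L, ne, replace = TRUE)
                        base[err] <- BASES[(match(base[err], BASES) - 1L +
                                            shift) %% 4L + 1L]
                    }
                }
                rev <- runif(total) < 0.5
                mism <- base != seqchars[siteIdx]
                sym <- rep(".", total)
                sym[!mism & rev] <- ","
                mm <- which(mism)
                sym[mm] <- base[mm]
                lowr <- mm[rev[mm]]
                sym[lowr] <- tolower(base[lowr])
                q <- pmin(QCHAR_MAX,
                          pmax(QCHAR_MIN,
                               as.integer(round(rnorm(total,
                                                      config$quality_mean,
                                                      config$quality_sd)))))
                keep <- d > 0L
                ends <- cumsum(d)[keep]
                starts <- ends - d[keep] + 1L
                bigSym <- paste(sym, collapse = "")
                bigQ <- intToUtf8(q + 33L)
                siteSym <- substring(bigSym, starts, ends)
                siteQ <- substring(bigQ, starts, ends)
                if (artifacts) {
                    dec <- which(runif(length(siteSym)) < 0.02)
                    for (j in dec)
                        siteSym[j] <- decorateSite(siteSym[j], siteQ[j])
                }
                writeLines(paste(ids[i], which(keep), seqchars[keep],
                                 d[keep], siteSym, siteQ, sep = "\t"),
                           con)
            }
            close(con)
        }
    })
    invisible(paths)
}

#' Expected call matrix from the truth table
#'
#' The per-site, per-strain call statuses a perfect caller with unlimited
#' error-free depth would produce: monomorphic reference everywhere
#' except at truth sites, where the affected strain is polymorphic
#' (ref/alt pair) or monomorphic for the alternate (fixed difference).
#' Used as the reference point for caller-recovery and set-algebra
#' checks on synthetic data.
#'
#' @param ref A \code{\linkS4class{TranscriptomeRef}}.
#' @param truth Truth table from \code{\link{implantTruth}}.
#' @param strains Strain ids (default: those in the truth table's
#'   configuration order must be supplied explicitly for strains without
#'   truth rows).
#' @return A \code{\linkS4class{StrainSiteMatrix}} over all reference
#'   positions.
#' @export
truthStrainMatrix <- function(ref, truth, strains) {
    ids <- contigNames(ref)
    lens <- contigLengths(ref)
    sites <- data.frame(
        contig_id = rep(ids, lens),
        position = unlist(lapply(lens, seq_len), use.names = FALSE),
        stringsAsFactors = FALSE)
    refb <- unlist(lapply(ids, function(id)
        strsplit(contigSeq(ref, id), "", fixed = TRUE)[[1L]]),
        use.names = FALSE)
    n <- nrow(sites)
    status <- matrix("monomorphic", n, length(strains),
                     dimnames = list(NULL, strains))
    alleles <- matrix(rep(refb, length(strains)), n, length(strains),
                      dimnames = list(NULL, strains))
    if (nrow(truth)) {
        i <- match(paste(truth$contig_id, truth$position),
                   paste(sites$contig_id, sites$position))
        poly <- truth$type == "polymorphic"
        idx <- cbind(i, match(truth$strain, strains))
        status[idx[poly, , drop = FALSE]] <- "polymorphic"
        alleles[idx[poly, , drop = FALSE]] <-
            paste0(pmin(truth$ref[poly], truth$alt[poly]), "/",
                   pmax(truth$ref[poly], truth$alt[poly]))
        alleles[idx[!poly, , drop = FALSE]] <- truth$alt[!poly]
    }
    new("StrainSiteMatrix", strains = strains, sites = sites,
        status = status, alleles = alleles)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: generate the reference, implant truth, simulate
#' pileups, and write the reference FASTA, ORF table and truth table next
#' to the pileups.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param dir Output directory.
#' @param artifacts Passed to \code{\link{simulatePileups}}.
#' @return A list with \code{ref} (\code{TranscriptomeRef}),
#'   \code{truth} (truth table), \code{pileups} (named paths) and
#'   \code{dir}.
#' @export
simulateStudy <- function(config, dir = tempfile("study"),
                          artifacts = TRUE) {
    ref <- generateContigs(config)
    truth <- implantTruth(ref, config)
    pileups <- simulatePileups(ref, truth, config, dir,
                               artifacts = artifacts)
    writeFasta(ref, file.path(dir, "reference.fa"))
    writeOrfTable(orfTable(ref), file.path(dir, "orf.tsv"))
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(ref = ref, truth = truth, pileups = pileups, dir = dir)
}
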