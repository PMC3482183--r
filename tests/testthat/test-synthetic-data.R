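test_that("configuration invariants are enforced", {
    expect_error(simulationConfig(contig_length_range = c(20, 50)),
                 "at least 30")
    expect_error(simulationConfig(poly_rate = 0.7, fixed_diff_rate = 0.5),
                 "not exceed 1")
    expect_error(simulationConfig(poly_rate = -0.1), "rates")
    expect_error(simulationConfig(base_error_rate = 1), "below 1")
    expect_error(simulationConfig(mean_depth = 0), "mean_depth")
})

test_that("contig generation honours counts, lengths and ORF structure", {
    cfg <- simulationConfig(n_contigs = 3, contig_length_range = c(100, 200),
                            orf_fraction = 1, seed = 7)
    ref <- generateContigs(cfg)
    expect_length(ref, 3L)
    expect_true(all(contigLengths(ref) >= 100 & contigLengths(ref) <= 200))
    orf <- orfTable(ref)
    expect_identical(nrow(orf), 3L)
    for (i in seq_len(nrow(orf))) {
        s <- contigSeq(ref, orf$contig_id[i])
        cds <- substr(s, orf$cds_start[i], orf$cds_end[i])
        if (orf$strand[i] == "-")
            cds <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(cds)))
        expect_identical(nchar(cds) %% 3L, 0L)
        expect_identical(substr(cds, 1, 3), "ATG")
        codons <- substring(cds, seq(1, nchar(cds), 3),
                            seq(3, nchar(cds), 3))
        aa <- translateCodon(codons)
        expect_identical(aa[length(aa)], "*")       # terminal stop
        expect_false(any(aa[-length(aa)] == "*"))   # no internal stop
        # nonempty UTR flanks
        expect_gte(orf$cds_start[i], 2L)
        expect_lte(orf$cds_end[i], nchar(s) - 1L)
    }

    none <- generateContigs(simulationConfig(n_contigs = 4,
                                             orf_fraction = 0, seed = 7))
    expect_identical(nrow(orfTable(none)), 0L)
})

test_that("generation is byte-identical under a repeated seed", {
    cfg <- simulationConfig(n_contigs = 4, contig_length_range = c(60, 120),
                            seed = 99, mean_depth = 15)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    st1 <- simulateStudy(cfg, d1)
    st2 <- simulateStudy(cfg, d2)
    for (f in c("reference.fa", "orf.tsv", "truth.tsv",
                basename(st1$pileups)))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), info = f)
})

test_that("truth implantation follows the configured rates and structure", {
    cfg0 <- simulationConfig(n_contigs = 2, poly_rate = 0,
                             fixed_diff_rate = 0, seed = 5)
    ref0 <- generateContigs(cfg0)
    expect_identical(nrow(implantTruth(ref0, cfg0)), 0L)

    cfgAll <- simulationConfig(n_contigs = 1,
                               contig_length_range = c(30, 30),
                               n_strains = 1, poly_rate = 1,
                               fixed_diff_rate = 0, seed = 5)
    refAll <- generateContigs(cfgAll)
    tAll <- implantTruth(refAll, cfgAll)
    expect_identical(nrow(tAll), 30L)
    expect_true(all(tAll$type == "polymorphic"))
    expect_true(all(tAll$freq >= 0.1 & tAll$freq <= 0.5))

    cfg <- simulationConfig(n_contigs = 10,
                            contig_length_range = c(200, 300),
                            n_strains = 4, poly_rate = 0.02,
                            fixed_diff_rate = 0.02, seed = 8)
    ref <- generateContigs(cfg)
    truth <- implantTruth(ref, cfg)
    expect_identical(anyDuplicated(paste(truth$contig_id,
                                         truth$position)), 0L)
    expect_true(all(truth$alt != truth$ref))
    expect_true(all(truth$alt %in% c("A", "C", "G", "T")))
    fixed <- truth[truth$type == "fixed", ]
    expect_gt(nrow(fixed), 0)
    # each fixed-difference site names exactly one carrier strain
    expect_true(all(table(paste(fixed$contig_id, fixed$position)) == 1))
    expect_true(all(fixed$strain %in% cfg$strain_names))
    expect_true(all(is.na(fixed$freq)))
})

test_that("error-free pileups encode monomorphic sites as match symbols", {
    cfg <- simulationConfig(n_contigs = 1, contig_length_range = c(40, 40),
                            n_strains = 1, poly_rate = 0,
                            fixed_diff_rate = 0, mean_depth = 20,
                            base_error_rate = 0, seed = 17)
    st <- simulateStudy(cfg, artifacts = FALSE)
    lines <- readLines(st$pileups[[1]])
    fields <- strsplit(lines, "\t", fixed = TRUE)
    for (f in fields) {
        expect_identical(nchar(f[5]), as.integer(f[4]))
        expect_true(grepl("^[.,]+$", f[5]))
    }
})

test_that("fixed sites at high error-free depth carry only the fixed allele", {
    cfg <- simulationConfig(n_contigs = 3, contig_length_range = c(50, 80),
                            n_strains = 2, poly_rate = 0,
                            fixed_diff_rate = 0.05, mean_depth = 60,
                            base_error_rate = 0, seed = 23)
    st <- simulateStudy(cfg, artifacts = FALSE)
    for (s in names(st$pileups)) {
        pu <- readPileup(st$pileups[[s]])
        t_s <- st$truth[st$truth$strain == s, ]
        for (i in seq_len(nrow(t_s))) {
            row <- pu[pu$contig_id == t_s$contig_id[i] &
                      pu$position == t_s$position[i], ]
            expect_true(grepl(sprintf("^[%s]+$", t_s$alt[i]), row$calls))
        }
    }
})

test_that("sampled allele and depth totals match their distributions", {
    # polymorphic site at frequency 0.5, depth 1000: alternate fraction
    # within 3 binomial standard errors
    ref <- TranscriptomeRef(c(c1 = paste(rep("A", 30), collapse = "")))
    truth <- data.frame(contig_id = "c1", position = 15L, ref = "A",
                        type = "polymorphic", strain = "strain1",
                        alt = "G", freq = 0.5, stringsAsFactors = FALSE)
    cfg <- simulationConfig(n_contigs = 1, n_strains = 1,
                            mean_depth = 1000, base_error_rate = 0,
                            seed = 41)
    pu <- readPileup(simulatePileups(ref, truth, cfg,
                                     artifacts = FALSE)[[1]])
    site <- pu[pu$position == 15L, ]
    k <- nchar(site$calls)
    altFrac <- lengths(regmatches(site$calls,
                                  gregexpr("G", site$calls))) / k
    expect_lt(abs(altFrac - 0.5), 3 * sqrt(0.25 / k))

    # 100 sites at mean depth 30: total reads within 3 Poisson SEs of 3000
    ref2 <- TranscriptomeRef(c(c1 = paste(rep("A", 100), collapse = "")))
    cfg2 <- simulationConfig(n_contigs = 1, n_strains = 1,
                             mean_depth = 30, base_error_rate = 0,
                             seed = 43)
    pu2 <- readPileup(simulatePileups(ref2, truth[0, ], cfg2,
                                      artifacts = FALSE)[[1]])
    expect_lt(abs(sum(pu2$depth) - 3000), 3 * sqrt(3000))
})

test_that("pileup allele counts converge to truth frequencies at depth 1e4", {
    ref <- TranscriptomeRef(c(c1 = paste(rep("C", 20), collapse = "")))
    truth <- data.frame(contig_id = "c1", position = c(5L, 12L),
                        ref = "C", type = "polymorphic",
                        strain = "strain1", alt = c("T", "A"),
                        freq = c(0.3, 0.15), stringsAsFactors = FALSE)
    cfg <- simulationConfig(n_contigs = 1, n_strains = 1,
                            mean_depth = 10000, base_error_rate = 0,
                            seed = 47)
    pu <- readPileup(simulatePileups(ref, truth, cfg,
                                     artifacts = FALSE)[[1]])
    counts <- strainSNP:::count_alleles_cpp(pu$calls, pu$quals, 0L)
    for (i in seq_len(nrow(truth))) {
        row <- which(pu$position == truth$position[i])
        frac <- counts[row, truth$alt[i]] / sum(counts[row, ])
        expect_lt(abs(frac - truth$freq[i]), 0.02)
    }
})

test_that("truth-derived call matrix mirrors the truth table", {
    cfg <- simulationConfig(n_contigs = 3, contig_length_range = c(40, 60),
                            n_strains = 3, poly_rate = 0.05,
                            fixed_diff_rate = 0.05, seed = 29)
    ref <- generateContigs(cfg)
    truth <- implantTruth(ref, cfg)
    m <- truthStrainMatrix(ref, truth, cfg$strain_names)
    expect_identical(nrow(siteTable(m)), sum(contigLengths(ref)))
    poly <- truth[truth$type == "polymorphic", ]
    for (s in cfg$strain_names) {
        keys <- intraStrainSet(m, s)
        expected <- poly[poly$strain == s, ]
        expect_setequal(keys, snpKey(expected$contig_id,
                                     expected$position, expected$ref,
                                     expected$alt))
    }
    fixed <- truth[truth$type == "fixed", ]
    nrInter <- nonredundantSets(m)$inter
    expect_setequal(nrInter, snpKey(fixed$contig_id, fixed$position,
                                    fixed$ref, fixed$alt))
})
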