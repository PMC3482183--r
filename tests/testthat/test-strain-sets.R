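# hand-built 4-strain matrix covering every membership case:
#  site 1: polymorphic only in s1, others monomorphic       -> s1-specific
#  site 2: polymorphic in s1 and s2 with different pairs    -> 2 distinct keys
#  site 3: s1/s2 monomorphic for different alleles          -> inter(s1,s2)
#  site 4: polymorphic in s1, s3 uncallable                 -> not specific
#  site 5: polymorphic in all strains, same pair            -> shared by all
#  site 6: monomorphic everywhere, same allele              -> nothing
toyMatrix <- function() {
    buildStrainSiteMatrix(list(
        s1 = rbind(makeCall("c1", 1, "s1", "polymorphic", major = "A",
                            minor = "G"),
                   makeCall("c1", 2, "s1", "polymorphic", major = "A",
                            minor = "C"),
                   makeCall("c1", 3, "s1", "monomorphic", consensus = "A"),
                   makeCall("c1", 4, "s1", "polymorphic", major = "C",
                            minor = "T"),
                   makeCall("c1", 5, "s1", "polymorphic", major = "G",
                            minor = "T"),
                   makeCall("c1", 6, "s1", "monomorphic", consensus = "T")),
        s2 = rbind(makeCall("c1", 1, "s2", "monomorphic", consensus = "A"),
                   makeCall("c1", 2, "s2", "polymorphic", major = "A",
                            minor = "T"),
                   makeCall("c1", 3, "s2", "monomorphic", consensus = "G"),
                   makeCall("c1", 4, "s2", "monomorphic", consensus = "C"),
                   makeCall("c1", 5, "s2", "polymorphic", major = "G",
                            minor = "T"),
                   makeCall("c1", 6, "s2", "monomorphic", consensus = "T")),
        s3 = rbind(makeCall("c1", 1, "s3", "monomorphic", consensus = "A"),
                   makeCall("c1", 2, "s3", "monomorphic", consensus = "A"),
                   makeCall("c1", 3, "s3", "monomorphic", consensus = "A"),
                   # site 4 absent -> uncallable in s3
                   makeCall("c1", 5, "s3", "polymorphic", major = "G",
                            minor = "T"),
                   makeCall("c1", 6, "s3", "monomorphic", consensus = "T")),
        s4 = rbind(makeCall("c1", 1, "s4", "monomorphic", consensus = "A"),
                   makeCall("c1", 2, "s4", "monomorphic", consensus = "A"),
                   makeCall("c1", 3, "s4", "monomorphic", consensus = "A"),
                   makeCall("c1", 4, "s4", "monomorphic", consensus = "C"),
                   makeCall("c1", 5, "s4", "polymorphic", major = "G",
                            minor = "T"),
                   makeCall("c1", 6, "s4", "monomorphic", consensus = "T"))))
}

test_that("intra-strain sets key polymorphic sites by allele pair", {
    m <- toyMatrix()
    expect_setequal(intraStrainSet(m, "s1"),
                    c("c1:1:A/G", "c1:2:A/C", "c1:4:C/T", "c1:5:G/T"))
    expect_setequal(intraStrainSet(m, "s2"), c("c1:2:A/T", "c1:5:G/T"))
    # same coordinate, different allele pairs: distinct keys
    expect_false(any(intraStrainSet(m, "s1") == "c1:2:A/T"))
    expect_error(intraStrainSet(m, "nope"), "unknown strain")
    allMono <- buildStrainSiteMatrix(list(
        a = makeCall("c1", 1:2, "a", "monomorphic", consensus = "A"),
        b = makeCall("c1", 1:2, "b", "monomorphic", consensus = "A")))
    expect_length(intraStrainSet(allMono, "a"), 0L)
})

test_that("inter-strain sets need fixed different alleles in both strains", {
    m <- toyMatrix()
    expect_identical(interStrainSet(m, "s1", "s2"), "c1:3:A/G")
    # symmetric in strain order
    expect_identical(interStrainSet(m, "s2", "s1"), "c1:3:A/G")
    # site 4 is monomorphic C in s4 but uncallable in s3: excluded
    expect_length(interStrainSet(m, "s3", "s4"), 0L)
    # s2 is fixed G at site 3 against A in s3 and s4
    expect_identical(interStrainSet(m, "s2", "s3"), "c1:3:A/G")
    expect_identical(interStrainSet(m, "s2", "s4"), "c1:3:A/G")
    expect_error(interStrainSet(m, "s1", "s1"), "distinct")
})

test_that("non-redundant sets de-duplicate unions over strains and pairs", {
    m <- toyMatrix()
    nr <- nonredundantSets(m)
    expect_setequal(nr$intra, c("c1:1:A/G", "c1:2:A/C", "c1:2:A/T",
                                "c1:4:C/T", "c1:5:G/T"))
    expect_setequal(nr$inter, c("c1:3:A/G"))
    # the shared site 5 appears once despite 4 contributing strains
    expect_identical(sum(nr$intra == "c1:5:G/T"), 1L)
})

test_that("strain-specific sets respect callability of the other strains", {
    m <- toyMatrix()
    sp <- strainSpecificSets(m)
    expect_identical(sp$s1, "c1:1:A/G")   # site 4 blocked by s3 uncallable
    expect_length(sp$s2, 0L)              # site 2 polymorphic in s1 too
    relaxed <- strainSpecificSets(m, requireCallableOthers = FALSE)
    expect_setequal(relaxed$s1, c("c1:1:A/G", "c1:4:C/T"))
    # pairwise disjoint
    keys <- unlist(sp)
    expect_identical(anyDuplicated(keys), 0L)
})

test_that("shared set and Venn regions partition the non-redundant union", {
    m <- toyMatrix()
    sh <- sharedAllSet(m)
    expect_identical(sh$shared, "c1:5:G/T")
    expect_identical(sum(sh$venn), length(nonredundantSets(m)$intra))
    expect_identical(unname(sh$venn[["s1&s2&s3&s4"]]), 1L)
    expect_identical(unname(sh$venn[["s1"]]), 3L)
    expect_identical(unname(sh$venn[["s2"]]), 1L)

    # identical intra sets: everything lands in the all-strain region
    same <- buildStrainSiteMatrix(list(
        a = makeCall("c1", 1:5, "a", "polymorphic", major = "A",
                     minor = "G"),
        b = makeCall("c1", 1:5, "b", "polymorphic", major = "A",
                     minor = "G")))
    shSame <- sharedAllSet(same)
    expect_length(shSame$shared, 5L)
    expect_identical(unname(shSame$venn[["a&b"]]), 5L)
    expect_identical(sum(shSame$venn), 5L)

    # pairwise-disjoint intra sets share nothing
    disj <- buildStrainSiteMatrix(list(
        a = rbind(makeCall("c1", 1, "a", "polymorphic", major = "A",
                           minor = "G"),
                  makeCall("c1", 2, "a", "monomorphic", consensus = "A")),
        b = rbind(makeCall("c1", 1, "b", "monomorphic", consensus = "A"),
                  makeCall("c1", 2, "b", "polymorphic", major = "C",
                           minor = "T"))))
    expect_length(sharedAllSet(disj)$shared, 0L)
})

test_that("set outputs are invariant under strain input order", {
    m <- toyMatrix()
    calls <- list(
        s1 = rbind(makeCall("c1", 1, "s1", "polymorphic", major = "A",
                            minor = "G"),
                   makeCall("c1", 2, "s1", "monomorphic",
                            consensus = "C")),
        s2 = rbind(makeCall("c1", 1, "s2", "monomorphic",
                            consensus = "A"),
                   makeCall("c1", 2, "s2", "monomorphic",
                            consensus = "T")))
    fwd <- buildStrainSiteMatrix(calls)
    bwd <- buildStrainSiteMatrix(rev(calls))
    expect_setequal(nonredundantSets(fwd)$intra,
                    nonredundantSets(bwd)$intra)
    expect_setequal(nonredundantSets(fwd)$inter,
                    nonredundantSets(bwd)$inter)
    expect_setequal(sharedAllSet(fwd)$shared, sharedAllSet(bwd)$shared)
    expect_mapequal(strainSpecificSets(fwd), strainSpecificSets(bwd))
})

test_that("set identities hold on random matrices", {
    set.seed(31)
    for (rep in 1:25) {
        m <- randomMatrix(15, c("w", "x", "y", "z"))
        intra <- lapply(strainNames(m), intraStrainSet, m = m)
        names(intra) <- strainNames(m)
        sp <- strainSpecificSets(m)
        sh <- sharedAllSet(m)
        nr <- nonredundantSets(m)
        for (s in strainNames(m)) {
            expect_true(all(sp[[s]] %in% intra[[s]]))
            expect_true(all(sh$shared %in% intra[[s]]))
        }
        expect_identical(anyDuplicated(unlist(sp)), 0L)
        expect_lte(length(nr$intra), sum(lengths(intra)))
        expect_identical(sum(sh$venn), length(nr$intra))
        for (pair in list(c("w", "x"), c("y", "z"))) {
            inter <- interStrainSet(m, pair[1], pair[2])
            sameCoord <- function(keys)
                sub(":[ACGT]/[ACGT]$", "", keys)
            expect_length(intersect(sameCoord(inter),
                                    sameCoord(intra[[pair[1]]])), 0L)
            expect_length(intersect(sameCoord(inter),
                                    sameCoord(intra[[pair[2]]])), 0L)
        }
    }
})
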