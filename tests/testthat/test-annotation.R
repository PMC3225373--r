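refs <- matureMirnaReferences()

test_that("homology matching reproduces the documented variant calls", {
    m <- matchMirna("UUCGGAUUGAAGGGAGCUCUA", refs)
    expect_equal(m@family, "miR159")
    expect_equal(m@nInternalMismatches, 1L)
    expect_equal(c(m@fivePrimeOffset, m@threePrimeOffset), c(0L, 0L))
    expect_equal(classifyVariant(m), "internal_mismatch")

    m18 <- matchMirna("UUUGGAUUGAAGGGAGCU", refs)
    expect_equal(m18@family, "miR159")
    expect_equal(m18@nInternalMismatches, 0L)
    expect_equal(m18@threePrimeOffset, -3L)
    expect_equal(classifyVariant(m18), "length_variant_3p")

    m22 <- matchMirna("CUUUGGAUUGAAGGGAGCUCUA", refs)
    expect_equal(m22@fivePrimeOffset, 1L)
    expect_equal(classifyVariant(m22), "length_variant_5p")

    canon <- matchMirna(MIR159, refs)
    expect_equal(classifyVariant(canon), "canonical")

    star <- matchMirna("GGAAUGUUGGCUGGCUCGAGGC", refs)
    expect_true(star@isStar)
    expect_equal(star@family, "miR166*")
})

test_that("matching agrees with the exhaustive Hamming oracle", {
    set.seed(3)
    queries <- c(knownMirnaCountTable()$sequence, randomRna(60, 21),
                 randomRna(30, 18), randomRna(30, 24))
    for (q in queries) {
        got <- matchMirna(q, refs)
        want <- bruteMatchOracle(q, refs)
        if (is.null(want)) {
            expect_null(got)
        } else {
            expect_equal(got@family, want$family, info = q)
            expect_equal(got@nInternalMismatches, want$mm, info = q)
            expect_equal(abs(got@fivePrimeOffset) + abs(got@threePrimeOffset),
                         want$off, info = q)
        }
    }
})

test_that("family tallies and roll-ups follow the star-merge rules", {
    one <- data.frame(sequence = MIR159, length = 21L, family = "miR159",
                      northern_only = FALSE, juvenile = 7L)
    attr(one, "libraries") <- "juvenile"
    t1 <- tallyFamilies(one)
    expect_equal(t1$reads_juvenile, 7L)
    expect_equal(t1$unique_juvenile, 1L)

    tab <- knownMirnaCountTable()
    tall <- tallyFamilies(tab)
    # star strands are merged: no '*' families survive
    expect_false(any(grepl("[*]", tall$family)))
    # merging star reads never decreases a family's read count
    mature_only <- tab[!grepl("[*]", tab$family), ]
    attr(mature_only, "libraries") <- attr(tab, "libraries")
    tall0 <- tallyFamilies(mature_only)
    shared <- intersect(tall$family, tall0$family)
    expect_true(all(tall$reads_total[match(shared, tall$family)] >=
                    tall0$reads_total[match(shared, tall0$family)]))
    expect_error(familyReadTotal(tall, "miR9999"), "unknown")
})

test_that("summaries honour the northern-only flag", {
    tab <- knownMirnaCountTable()
    tall <- tallyFamilies(tab)
    s <- summarizeKnown(tall)
    # miR156/157 is northern-only in juvenile: present overall, absent from
    # the per-library juvenile family count
    expect_equal(s$families_total, 18L)
    expect_equal(s$libraries$juvenile$families, 17L)
    empty <- tallyFamilies(tab[0, ])
    s0 <- summarizeKnown(empty)
    expect_equal(s0$total_matched_reads, 0L)
    expect_equal(s0$families_total, 0L)
})

test_that("per-row annotation of the fixture recovers every printed family", {
    tab <- knownMirnaCountTable()
    ann <- annotateCountTable(tab, refs)
    expect_true(all(!is.na(ann$matched_family)))
    expect_equal(sub("[*]$", "", ann$matched_family),
                 sub("[*]$", "", ann$family))
    expect_true(all(ann$n_mismatches <= 3L))
    expect_true(all(abs(ann$offset_5p) <= 3L & abs(ann$offset_3p) <= 3L))
})
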