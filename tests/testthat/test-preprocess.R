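adapters <- readAdapterConfig()

test_that("adapter stripping recovers inserts and classifies artifacts", {
    a5 <- adapters$five_prime_variants
    a3 <- adapters$three_prime
    expect_equal(stripAdapters(paste0(a5[1], MIR159, a3), adapters)$insert,
                 MIR159)
    expect_equal(stripAdapters(paste0(a5[2], "ACGUACGU", a3),
                               adapters)$insert, "ACGUACGU")
    expect_equal(stripAdapters(paste0(a5[1], a3), adapters)$artifact,
                 "no_insert")
    expect_equal(stripAdapters(paste0(a5[1], "ACGUACGU", a3, a3),
                               adapters)$artifact, "multimer")
    expect_equal(stripAdapters(paste0("GGGGGGGGGG", MIR159, a3),
                               adapters)$artifact, "unrecognized")
    expect_equal(stripAdapters(paste0(a5[1], MIR159), adapters)$artifact,
                 "unrecognized")
    # one mismatch beyond the anchor is tolerated
    mut <- a3
    substr(mut, nchar(mut), nchar(mut)) <- "G"
    expect_equal(stripAdapters(paste0(a5[1], MIR159, mut), adapters)$insert,
                 MIR159)
})

test_that("size filter keeps the closed 18-25 range", {
    lens <- c(17L, 18L, 21L, 25L, 26L)
    seqs <- vapply(lens, function(L) strrep("A", L), "")
    expect_equal(filterSize(seqs), c(FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("complexity filter needs at least three distinct bases", {
    expect_false(filterComplexity("AAAAAAAAAAAAAAAAAA"))
    expect_false(filterComplexity("AUAUAUAUAUAUAUAUAU"))
    expect_true(filterComplexity("AUGAUGAUGAUGAUGAUG"))
})

test_that("ncRNA filter matches substrings with the configured tolerance", {
    set.seed(101)
    refs <- data.frame(id = c("rRNA_x", "tRNA_x"),
                       sequence = randomRna(2, 300))
    planted <- substr(refs$sequence[1], 100, 120)
    expect_false(filterNcrna(planted, refs)[1])
    expect_equal(attr(filterNcrna(planted, refs), "matched_ref")[1], "rRNA_x")
    # reverse complement hit, and the switch that disables it
    rc <- reverseComplementRna(planted)
    expect_false(filterNcrna(rc, refs, both_strands = TRUE)[1])
    expect_true(filterNcrna(rc, refs, both_strands = FALSE)[1])
    # a random 21-mer absent from the references survives (verified by scan)
    repeat {
        q <- randomRna(1, 21)
        inRef <- any(vapply(refs$sequence, function(r)
            grepl(q, r, fixed = TRUE) ||
            grepl(reverseComplementRna(q), r, fixed = TRUE), TRUE))
        if (!inRef) break
    }
    expect_true(filterNcrna(q, refs)[1])
    # 1-mismatch copy: dropped at tolerance 1, kept at 0
    onemm <- planted
    substr(onemm, 10, 10) <- setdiff(c("A", "C", "G", "U"),
                                     substr(onemm, 10, 10))[1]
    if (!grepl(onemm, refs$sequence[1], fixed = TRUE)) {
        expect_false(filterNcrna(onemm, refs, max_mismatches = 1L)[1])
        expect_true(filterNcrna(onemm, refs, max_mismatches = 0L,
                                both_strands = FALSE)[1])
    }
})

test_that("the cascade closes its accounting and is order-independent", {
    set.seed(7)
    refs <- data.frame(id = "rRNA_x", sequence = randomRna(1, 400))
    a5 <- adapters$five_prime_variants
    a3 <- adapters$three_prime
    inserts <- c(rep(MIR159, 3), randomRna(5, 24), strrep("A", 20),
                 randomRna(1, 30), substr(refs$sequence[1], 50, 71))
    reads <- paste0(a5[1], inserts, a3)
    reads <- c(reads, paste0(a5[1], a3), paste0(a5[2], "ACGUACGUACGU", a3, a3))
    lib <- runPreprocess(reads, adapters, refs, label = "t")
    st <- libStats(lib)
    expect_equal(st$raw_reads, length(reads))
    expect_equal(st$adapter_removed_reads, length(inserts))
    expect_equal(sum(st$artifacts),
                 st$raw_reads - st$adapter_removed_reads)
    expect_equal(sum(st$removed),
                 st$adapter_removed_reads - st$filtered_reads)
    expect_equal(st$filtered_reads, totalReads(lib))
    expect_equal(st$unique_sequences, nUnique(lib))
    # monotone accounting
    expect_true(st$raw_reads >= st$adapter_removed_reads)
    expect_true(st$adapter_removed_reads >= st$filtered_reads)
    # shuffling the input reads leaves the library identical
    set.seed(42)
    lib2 <- runPreprocess(sample(reads), adapters, refs, label = "t")
    expect_identical(libCounts(lib), libCounts(lib2))
    expect_identical(libStats(lib), libStats(lib2))
})

test_that("degenerate inputs: all artifacts, and idempotence on clean inserts", {
    a5 <- adapters$five_prime_variants
    a3 <- adapters$three_prime
    lib <- runPreprocess(rep(paste0(a5[1], a3), 5), adapters, NULL)
    expect_equal(libStats(lib)$filtered_reads, 0L)
    expect_equal(nUnique(lib), 0L)
    # feeding already-clean inserts through an adapter-less library builder
    clean <- srnaLibrary(c(MIR159, MIR159, "ACGUACGUACGUACGUACGU"))
    again <- srnaLibrary(libSequences(clean), unname(libCounts(clean)))
    expect_identical(libCounts(clean), libCounts(again))
})
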