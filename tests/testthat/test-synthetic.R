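test_that("generation is deterministic for a fixed seed", {
    cfg <- populationConfig(seed = 5, n_reads_per_library = 800)
    p1 <- generatePopulation(cfg)
    p2 <- generatePopulation(cfg)
    expect_identical(p1, p2)
    ad <- readAdapterConfig()
    r1 <- generateRawReads(p1$libraries$juvenile$inserts, ad, seed = 5)
    r2 <- generateRawReads(p2$libraries$juvenile$inserts, ad, seed = 5)
    expect_identical(r1, r2)
    expect_identical(generateTas3Locus(seed = 3, mir390 = MIR390),
                     generateTas3Locus(seed = 3, mir390 = MIR390))
})

test_that("the realized size distribution stays within binomial error", {
    cfg <- populationConfig(seed = 1, n_reads_per_library = 10000,
                            frac_ncrna_fragments = 0,
                            planted_mirnas = NULL)
    pop <- generatePopulation(cfg)
    ins <- pop$libraries$juvenile$inserts
    share24 <- sum(ins$count[nchar(ins$sequence) == 24]) / sum(ins$count)
    # 99% binomial interval around 0.80 at n = 10,000
    expect_gte(share24, 0.78)
    expect_lte(share24, 0.82)
})

test_that("planted miRNA rows appear in the count table exactly", {
    pop <- generatePopulation(populationConfig(seed = 2,
                                               n_reads_per_library = 2000))
    tab <- plantedCountTable(pop)
    expect_equal(tab$juvenile[tab$sequence == MIR159], 109L)
    expect_equal(tab$adult[tab$sequence == MIR159], 4L)
    expect_equal(sum(tab$juvenile), 132L)
    # and the planted reads are present in the insert pool at those counts
    ins <- pop$libraries$juvenile$inserts
    planted <- ins[ins$category == "planted", ]
    expect_equal(planted$count[planted$sequence == MIR159], 109L)
})

test_that("raw reads are adapter-flanked and artifacts are discardable", {
    ad <- readAdapterConfig()
    raw <- generateRawReads("ACGU", ad, frac_artifacts = 0, seed = 1)
    expected <- paste0(ad$five_prime_variants, "ACGU", ad$three_prime)
    expect_true(raw$sequence %in% expected)
    expect_equal(stripAdapters(raw$sequence, ad)$insert, "ACGU")

    set.seed(1)
    many <- generateRawReads(randomRna(5000, 22), ad,
                             frac_artifacts = 0.02, seed = 9)
    tr <- attr(many, "truth")
    n_art <- tr$n_no_insert + tr$n_multimer
    # binomial sampling error around 100 at n = 5000 (99% interval)
    expect_gte(n_art, 65L)
    expect_lte(n_art, 140L)
    # every artifact read is classified as an artifact by the stripper
    strip <- lapply(many$sequence, stripAdapters, adapters = ad)
    art <- vapply(strip, function(x) x$artifact, "")
    expect_equal(sum(art == "no_insert", na.rm = TRUE), tr$n_no_insert)
    expect_equal(sum(art == "multimer", na.rm = TRUE), tr$n_multimer)
})

test_that("the 5'A bias of the 24-nt class is realized", {
    cfg <- populationConfig(seed = 3, n_reads_per_library = 10000,
                            frac_ncrna_fragments = 0, planted_mirnas = NULL)
    pop <- generatePopulation(cfg)
    ins <- pop$libraries$juvenile$inserts
    lib <- srnaLibrary(ins$sequence, ins$count, label = "juvenile")
    comp <- fivePrimeComposition(lib, 24L)
    expect_equal(unname(comp["A"]), 0.60, tolerance = 0.04)
})

test_that("generator guards reject impossible requests", {
    expect_error(populationConfig(n_reads_per_library = 0), "zero reads")
    expect_error(populationConfig(size_distribution = c("24" = 0.5)),
                 "sum to 1")
    expect_error(generateRaceClones("ACGU", NULL, n_clones = 0), "at least 1")
    expect_error(generateTas3Locus(seed = 1, mir390 = "ACGU"), "20-21")
    expect_error(generateHairpinTranscript("ACGU", seed = 1), "20-24")
})
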