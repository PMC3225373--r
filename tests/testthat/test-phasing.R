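test_that("cleavage point sits opposite the 10/11 boundary, inside the site", {
    set.seed(71)
    tx <- paste0(randomRna(1, 100), reverseComplementRna(MIR390),
                 randomRna(1, 100))
    site <- findSites(MIR390, tx, cutoff = 0)[[1]]
    a <- cleavagePoint(site)
    expect_equal(a, site@end - 10L)
    expect_true(a >= site@start && a <= site@end)
    # the RACE convention agrees: a clone starting just past the anchor
    # reads out as 10/11
    expect_equal(positionInDuplex(a + 1L, site), "10/11")
    short <- new("TargetSite", mirna = "ACGUACGUAC", transcriptId = "t",
                 start = 5L, end = 14L,
                 states = data.frame(state = rep("match", 10),
                                     mir_pos = 1:10), score = 0)
    expect_error(cleavagePoint(short), "too short")
})

test_that("phase windows tile the register without gap or overlap", {
    pr <- enumeratePhases(500L, "toward_five_prime", n = 8L)
    w <- phaseWindows(pr)
    expect_equal(length(w), 8L)
    # Dk covers anchor - 21k + 1 .. anchor - 21(k-1)
    expect_equal(IRanges::start(w)[7], 500L - 147L + 1L)
    expect_equal(IRanges::end(w)[7], 500L - 126L)
    expect_equal(sum(IRanges::width(w)), 21L * 8L)
    # D1 and D2 abut
    expect_equal(IRanges::start(w)[1] - IRanges::end(w)[2], 1L)

    fw <- phaseWindows(enumeratePhases(100L, "toward_three_prime", n = 3L))
    expect_equal(IRanges::start(fw)[1], 101L)
    expect_equal(IRanges::end(fw)[3], 163L)

    tr <- enumeratePhases(60L, "toward_five_prime", n = 5L)
    expect_true(tr@truncated)
    expect_lt(length(phaseWindows(tr)), 5L)
})

test_that("dual miR390 site discovery drives the architecture verdict", {
    loc <- generateTas3Locus(seed = 11, mir390 = MIR390)
    sites <- findMir390Sites(loc$transcript, MIR390)
    expect_equal(length(sites), 2L)
    expect_equal(c(sites[[1]]@start, sites[[1]]@end),
                 loc$truth$five_prime_site)
    expect_equal(c(sites[[2]]@start, sites[[2]]@end),
                 loc$truth$three_prime_site)
    expect_equal(length(findMir390Sites(randomRna(1, 300), MIR390)), 0L)

    ann <- assignTasiarfPhases(loc$transcript, MIR390, tasiarfReference())
    expect_equal(verdict(ann), "full")
    expect_equal(sort(ann@tasiarf$phase), c(7L, 8L))
    expect_equal(ann@tasiarf$mismatches[order(ann@tasiarf$phase)], c(0L, 1L))

    # single-site contig: tasiARFs found, dual-site requirement unmet
    single <- generateTas3Locus(seed = 11, mir390 = MIR390,
                                second_site = FALSE)
    ann1 <- assignTasiarfPhases(single$transcript, MIR390, tasiarfReference())
    expect_equal(verdict(ann1), "partial")
    # removing a site never upgrades the verdict (full > partial > fail)
    expect_true(verdict(ann1) != "full")

    # a contig restricted to the tasiARF region: no sites mappable
    tas_region <- substr(loc$transcript$sequence, loc$truth$D8[1] - 5L,
                         loc$truth$D7[2] + 5L)
    ann2 <- assignTasiarfPhases(tas_region, MIR390, tasiarfReference())
    expect_equal(verdict(ann2), "partial")
    expect_equal(nrow(ann2@tasiarf), 2L)
})

test_that("off-register planted tasiARFs are reported with a nonzero offset", {
    loc <- generateTas3Locus(seed = 12, mir390 = MIR390, tasiarf_shift = 3L)
    ann <- assignTasiarfPhases(loc$transcript, MIR390, tasiarfReference())
    expect_true(all(is.na(ann@tasiarf$phase)))
    expect_true(all(ann@tasiarf$offset != 0L))
    expect_equal(verdict(ann), "fail")
})

test_that("the inter-site register of the generator is configurable", {
    lin <- generateTas3Locus(seed = 13, mir390 = MIR390, in_register = TRUE)
    expect_equal((lin$truth$anchor_3p - lin$truth$anchor_5p) %% 21L, 0L)
    loff <- generateTas3Locus(seed = 13, mir390 = MIR390, in_register = FALSE)
    expect_false((loff$truth$anchor_3p - loff$truth$anchor_5p) %% 21L == 0L)
})

test_that("tasiARF target counting flags dual-site ARF transcripts", {
    arf <- generateArfLocus(seed = 14)
    other <- data.frame(id = "plain", sequence = randomRna(1, 400))
    rep_ <- findTasiarfTargets(tasiarfReference(),
                               rbind(arf$transcript, other), cutoff = 1.5)
    expect_equal(rep_$n_sites[rep_$transcript == "ARF_syn"], 2L)
    expect_true(rep_$dual_site[rep_$transcript == "ARF_syn"])
    expect_equal(rep_$n_sites[rep_$transcript == "plain"], 0L)
    # per-site scores of the planted sites: perfect + single non-core G:U
    sc <- sort(as.numeric(strsplit(
        rep_$scores[rep_$transcript == "ARF_syn"], ",")[[1]]))
    expect_equal(sc, c(0, 0.5))
})
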