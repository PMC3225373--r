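test_that("the folding backend recovers forced stems and exact weights", {
    hp <- paste0(strrep("G", 20), "AAAA", strrep("C", 20))
    f <- foldRna(hp)
    expect_equal(f$energy_score, -60)  # 20 GC pairs x weight 3
    expect_equal(nchar(f$structure), nchar(hp))
    # stem pairs recovered with a loop of >= 3
    expect_true(all(f$pairs[1:20] %in% 25:44))
    expect_true(all(f$pairs[21:24] == 0))
    gc <- paste0(strrep("G", 18), "AACA", strrep("C", 18))
    expect_true(foldRna(gc)$energy_score <= -18 * 3)
    expect_error(foldRna("ACGX"), "alphabet")
})

test_that("the DP equals the recursive enumeration oracle on short sequences", {
    set.seed(5)
    for (i in 1:12) {
        s <- randomRna(1, sample(15:30, 1))
        f <- foldRna(s)
        expect_equal(-f$energy_score, bruteFoldScore(s), info = s)
        # reported structure is consistent with the reported score
        pt <- f$pairs
        w <- 0
        for (p in which(pt > seq_along(pt))) {
            a <- substr(s, p, p); b <- substr(s, pt[p], pt[p])
            w <- w + switch(paste0(a, b), GC = 3, CG = 3, AU = 2, UA = 2,
                            GU = 1, UG = 1, 0)
        }
        expect_equal(w, -f$energy_score, info = s)
        expect_equal(pairTableFromDotBracket(f$structure), pt)
    }
})

test_that("dinucleotide shuffling preserves dinucleotide counts and ends", {
    set.seed(9)
    for (i in 1:8) {
        s <- randomRna(1, 80)
        sh <- dinucleotideShuffle(s)
        expect_equal(nchar(sh), nchar(s))
        expect_equal(dinucCounts(sh), dinucCounts(s))
        expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
        expect_equal(substr(sh, 80, 80), substr(s, 80, 80))
    }
})

test_that("precursor windows cover occurrences, flank settings and truncation", {
    set.seed(2)
    tx <- paste0(randomRna(1, 290), MIR159, randomRna(1, 289))
    w <- extractPrecursorWindows(MIR159, tx)
    # flank settings 50/100/150/200 plus the whole transcript
    expect_equal(length(w), 5L)
    w200 <- w[[4]]
    expect_equal(c(w200@start, w200@end), c(291 - 200, 290 + 21 + 200))
    expect_false(w200@truncated)
    expect_equal(substr(w200@sequence, w200@srnaStart, w200@srnaEnd), MIR159)

    near <- paste0(randomRna(1, 10), MIR159, randomRna(1, 300))
    wn <- extractPrecursorWindows(MIR159, near, 50, 50)[[1]]
    expect_equal(wn@start, 1L)
    expect_true(wn@truncated)

    two <- paste0(randomRna(1, 60), MIR159, randomRna(1, 60), MIR159,
                  randomRna(1, 60))
    w2 <- extractPrecursorWindows(MIR159, two, 50, 50)
    starts <- vapply(w2, function(x) x@srnaStart + x@start - 1L, 1L)
    expect_equal(length(unique(starts)), 2L)

    expect_equal(extractPrecursorWindows(MIR159, randomRna(1, 200)), list())
})

test_that("duplex criteria fire on handcrafted folds", {
    set.seed(4)
    seq80 <- randomRna(1, 80)
    win <- new("PrecursorWindow", transcriptId = "t", start = 1L, end = 80L,
               sequence = seq80, srnaStart = 10L, srnaEnd = 30L,
               truncated = FALSE)
    # clean duplex: sRNA position i pairs 80 - (i - 10)
    pairing <- as.list(setNames(80:60, 10:30))
    ok <- evaluateHairpin(win, fold = makeFold(80, pairing),
                          energy_criterion = FALSE)
    expect_equal(verdict(ok), "PASS")
    expect_equal(ok@arm, "5p")
    # star convention: pairs of sRNA 12..30 plus the 2-nt 3' overhang
    expect_equal(c(ok@starStart, ok@starEnd), c(60L, 80L))

    # six unpaired sRNA bases break the duplex-pairing criterion
    sparse <- pairing[as.character(c(10:24))]  # 15 of 21 paired
    bad <- evaluateHairpin(win, fold = makeFold(80, sparse),
                           energy_criterion = FALSE)
    expect_equal(verdict(bad), "FAIL")
    expect_true("duplex_pairing" %in% bad@failed)

    # a 4-nt asymmetric bulge breaks the bulge criterion
    bulged <- as.list(setNames(c(80:71, 66:56), 10:30))
    bb <- evaluateHairpin(win, fold = makeFold(80, bulged),
                          energy_criterion = FALSE)
    expect_true("bulge" %in% bb@failed)

    # partners on both sides of the sRNA = loop overlap
    split <- c(as.list(setNames(78:72, 10:16)), as.list(setNames(3:9, 24:30)))
    lo <- evaluateHairpin(win, fold = makeFold(80, split),
                          energy_criterion = FALSE)
    expect_true("loop_overlap" %in% lo@failed)
})

test_that("planted hairpins pass and loop-spanning constructs fail", {
    hp <- generateHairpinTranscript(MIR159, seed = 3)
    cand <- callHairpinCandidate(MIR159, hp$transcript, n_shuffle = 40,
                                 shuffle_seed = 3)
    expect_equal(verdict(cand), "PASS")
    # verdicts are deterministic given the shuffle seed
    cand2 <- callHairpinCandidate(MIR159, hp$transcript, n_shuffle = 40,
                                  shuffle_seed = 3)
    expect_equal(cand@duplexStats$null_mean, cand2@duplexStats$null_mean)

    sp <- generateHairpinTranscript(MIR159, seed = 3, span_loop = TRUE)
    bad <- callHairpinCandidate(MIR159, sp$transcript, n_shuffle = 20,
                                shuffle_seed = 3)
    expect_equal(verdict(bad), "FAIL")
    expect_true("loop_overlap" %in% bad@failed ||
                "duplex_pairing" %in% bad@failed)
})

test_that("the thermodynamic backend plugs in behind the same contract", {
    if (nzchar(Sys.which("RNAfold"))) {
        f <- foldRna(paste0(strrep("G", 15), "AAAA", strrep("C", 15)),
                     backend = "rnafold")
        expect_equal(nchar(f$structure), 34L)
        expect_lt(f$energy_score, 0)
        expect_equal(pairTableFromDotBracket(f$structure), f$pairs)
    } else {
        expect_error(foldRna("ACGU", backend = "rnafold"), "RNAfold")
    }
})
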