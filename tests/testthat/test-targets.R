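test_that("alignment scoring follows the position-weighted penalty scheme", {
    # perfect complement
    perfect <- alignMirnaTarget(MIR159, reverseComplementRna(MIR159))
    expect_true(all(perfect$state == "match"))
    expect_equal(scoreAlignment(perfect), 0)
    # single G:U opposite position 20 (outside the core): 0.5 x 1
    states <- rep("match", 21)
    states[20] <- "GU"
    expect_equal(scoreAlignment(states), 0.5)
    # single mismatch at core position 10: 1.0 x 2
    states <- rep("match", 21)
    states[10] <- "mismatch"
    expect_equal(scoreAlignment(states), 2)
})

test_that("single-defect enumeration matches the hand-computed table", {
    for (pos in 1:21) {
        w <- if (pos >= 2 && pos <= 13) 2 else 1
        for (defect in c("mismatch", "GU", "gap_in_target")) {
            states <- rep("match", 21)
            states[pos] <- defect
            pen <- c(mismatch = 1, GU = 0.5, gap_in_target = 2)[[defect]]
            expect_equal(scoreAlignment(states), pen * w,
                         info = paste(defect, pos))
        }
    }
})

test_that("site discovery finds planted sites at their coordinates", {
    set.seed(21)
    mir <- MIR159
    rc <- reverseComplementRna(mir)
    tx <- paste0(randomRna(1, 40), rc, randomRna(1, 40))
    sites <- findSites(mir, tx)
    expect_equal(length(sites), 1L)
    expect_equal(siteScore(sites[[1]]), 0)
    expect_equal(c(sites[[1]]@start, sites[[1]]@end), c(41L, 61L))

    # planted core mismatch (pos 5) + 3' G:U (pos 18): 2 + 0.5
    site <- rc
    # target base opposite miRNA position k sits at site index L - k + 1
    i5 <- 21 - 5 + 1
    b <- substr(mir, 5, 5)
    bad <- setdiff(c("A", "C", "G", "U"),
                   c(chartr("ACGU", "UGCA", b),
                     if (b == "G") "U" else if (b == "U") "G"))[1]
    substr(site, i5, i5) <- bad
    i18 <- 21 - 18 + 1
    stopifnot(substr(mir, 18, 18) == "U")
    substr(site, i18, i18) <- "G"   # U:G wobble
    tx2 <- paste0(randomRna(1, 40), site, randomRna(1, 40))
    s2 <- findSites(mir, tx2)
    expect_equal(siteScore(s2[[1]]), 2.5)
    expect_equal(s2[[1]]@start, 41L)
})

test_that("site discovery equals the exhaustive window enumeration", {
    set.seed(31)
    for (i in 1:4) {
        tx <- paste(c(randomRna(1, 50), reverseComplementRna(MIR390),
                      randomRna(1, 50)), collapse = "")
        got <- findSites(MIR390, tx, cutoff = 4.5)
        want <- bruteSiteScan(MIR390, tx, cutoff = 4.5)
        expect_equal(length(got), nrow(want))
        expect_equal(vapply(got, function(s) s@start, 1L), want$start)
        expect_equal(vapply(got, siteScore, 1), want$score)
    }
})

test_that("scores are half-integers without gaps and shift-invariant", {
    set.seed(41)
    tx <- paste0(randomRna(1, 30), reverseComplementRna(MIR159),
                 randomRna(1, 30))
    sites <- findSites(MIR159, tx, cutoff = 6, max_gaps = 0L)
    scores <- vapply(sites, siteScore, 1)
    expect_true(all(abs(scores * 2 - round(scores * 2)) < 1e-9))
    # 5' padding shifts coordinates, not scores
    pad <- paste0(strrep("A", 17), tx)
    sites2 <- findSites(MIR159, pad, cutoff = 6, max_gaps = 0L)
    expect_equal(vapply(sites2, siteScore, 1), scores)
    expect_equal(vapply(sites2, function(s) s@start, 1L),
                 vapply(sites, function(s) s@start, 1L) + 17L)
})

test_that("target prediction is monotone in the cutoff and exact on truth", {
    set.seed(51)
    mirs <- c(miR159 = MIR159, miR390 = MIR390)
    t1 <- paste0(randomRna(1, 60), reverseComplementRna(MIR159),
                 randomRna(1, 60))
    t2 <- randomRna(1, 140)
    txs <- data.frame(id = c("hit", "none"), sequence = c(t1, t2))
    pred <- predictTargets(mirs, txs, cutoff = 3.5)
    expect_equal(nrow(pred), 1L)
    expect_equal(pred$transcript, "hit")
    expect_equal(pred$mirna, "miR159")
    # cutoff 0 keeps only perfect complements
    pred0 <- predictTargets(mirs, txs, cutoff = 0)
    expect_equal(pred0$best_score, 0)
    # raising the cutoff never removes a reported pair
    pred6 <- predictTargets(mirs, txs, cutoff = 6)
    expect_true(all(paste(pred$mirna, pred$transcript) %in%
                    paste(pred6$mirna, pred6$transcript)))
})
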