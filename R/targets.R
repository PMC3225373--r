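# Position-weighted penalty scoring of miRNA/target complementarity.
# The miRNA is read 5'->3'; its position 1 pairs with the 3' end of the
# target site, so mismatches near the miRNA 5' and central positions (the
# cleavage-competent core, positions 2-13) can be penalized preferentially.

defaultScoringWeights <- function() {
    list(mismatch = 1.0, GU = 0.5, gap = 2.0,
         core = c(2L, 13L), core_weight = 2.0)
}

#' Align a miRNA against one target site
#'
#' Builds the per-position state vector of the antiparallel alignment of a
#' miRNA (5'->3') with a target site (given 5'->3' on the transcript).
#' Without a gap the site must have the miRNA's length; \code{gap} plants a
#' single indel: \code{list(type = "gap_in_target", at = j)} leaves miRNA
#' base j unpaired (site one base shorter), \code{list(type =
#' "gap_in_mirna", at = j)} bulges one extra target base before miRNA base
#' j (site one base longer).
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param site_seq Target site sequence, 5'->3'.
#' @param gap NULL or a list as above.
#' @return data.frame with columns \code{state} (\code{match},
#'   \code{mismatch}, \code{GU}, \code{gap_in_target},
#'   \code{gap_in_mirna}) and \code{mir_pos}.
#' @export
alignMirnaTarget <- function(mirna, site_seq, gap = NULL) {
    mb <- splitBases(normalizeRna(mirna))
    L <- length(mb)
    rs <- rev(splitBases(normalizeRna(site_seq)))
    Ls <- length(rs)
    pairState <- function(m, t) {
        if (isWatsonCrick(m, t)) "match"
        else if (isWobble(m, t)) "GU"
        else "mismatch"
    }
    if (is.null(gap)) {
        if (Ls != L) stop("ungapped site must match the miRNA length")
        states <- mapply(pairState, mb, rs)
        return(data.frame(state = unname(states), mir_pos = seq_len(L)))
    }
    j <- gap$at
    if (gap$type == "gap_in_target") {
        if (Ls != L - 1L) stop("gap_in_target site must be one base shorter")
        state <- character(L); pos <- seq_len(L)
        for (i in seq_len(L)) {
            if (i < j) state[i] <- pairState(mb[i], rs[i])
            else if (i == j) state[i] <- "gap_in_target"
            else state[i] <- pairState(mb[i], rs[i - 1L])
        }
        return(data.frame(state = state, mir_pos = pos))
    }
    if (gap$type == "gap_in_mirna") {
        if (Ls != L + 1L) stop("gap_in_mirna site must be one base longer")
        state <- character(L + 1L); pos <- integer(L + 1L)
        k <- 1L
        for (i in seq_len(L)) {
            if (i == j) {  # bulged target base charged to the next miRNA pos
                state[k] <- "gap_in_mirna"; pos[k] <- j; k <- k + 1L
            }
            off <- if (i >= j) 1L else 0L
            state[k] <- pairState(mb[i], rs[i + off]); pos[k] <- i
            k <- k + 1L
        }
        return(data.frame(state = state, mir_pos = pos))
    }
    stop("unknown gap type")
}

#' Score an alignment state vector
#'
#' score = sum of penalty(state) x weight(miRNA position), with defaults
#' mismatch 1, G:U 0.5, gap 2, and double weight over miRNA positions 2-13
#' (the 5'/central core). All scores are half-integers when gap-free.
#'
#' @param states data.frame from \code{\link{alignMirnaTarget}} (a bare
#'   character vector of states is accepted; positions are then 1..n).
#' @param weights Weight list, see \code{defaultScoringWeights} entries
#'   \code{mismatch}, \code{GU}, \code{gap}, \code{core}, \code{core_weight}.
#' @return The penalty score (numeric, >= 0).
#' @export
scoreAlignment <- function(states, weights = defaultScoringWeights()) {
    if (is.character(states))
        states <- data.frame(state = states, mir_pos = seq_along(states))
    pen <- c(match = 0, mismatch = weights$mismatch, GU = weights$GU,
             gap_in_target = weights$gap, gap_in_mirna = weights$gap)
    p <- pen[states$state]
    w <- ifelse(states$mir_pos >= weights$core[1L] &
                states$mir_pos <= weights$core[2L], weights$core_weight, 1)
    sum(p * w)
}

#' Find target sites of a miRNA on a transcript
#'
#' Scans every window of the transcript (and, with \code{max_gaps = 1}, every
#' single-indel variant) for reverse-complement alignments scoring at or
#' below the cutoff, and reports non-overlapping sites best-first (ties by
#' leftmost start).
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param transcript One-row record (id + sequence) or a character sequence.
#' @param cutoff Maximum penalty score (default 3.5).
#' @param max_gaps 0 or 1 indels per site (default 1).
#' @param weights Scoring weights (see \code{\link{scoreAlignment}}).
#' @return A list of \linkS4class{TargetSite}, best score first.
#' @export
findSites <- function(mirna, transcript, cutoff = 3.5, max_gaps = 1L,
                      weights = defaultScoringWeights()) {
    if (is.data.frame(transcript)) {
        tid <- transcript$id[1L]
        tseq <- normalizeRna(transcript$sequence[1L])
    } else {
        tid <- "transcript"
        tseq <- normalizeRna(transcript)
    }
    mirna <- normalizeRna(mirna)
    L <- nchar(mirna)
    n <- nchar(tseq)
    if (n < L) stop("transcript shorter than the miRNA")
    mb <- splitBases(mirna)
    tb <- splitBases(tseq)
    w <- ifelse(seq_len(L) >= weights$core[1L] &
                seq_len(L) <= weights$core[2L], weights$core_weight, 1)
    # penalty (already position-weighted) of miRNA base i against the
    # target bases at the given transcript indices
    penAt <- function(i, idx) {
        t <- tb[idx]
        p <- ifelse(isWatsonCrick(mb[i], t), 0,
                    ifelse(isWobble(mb[i], t), weights$GU, weights$mismatch))
        p * w[i]
    }
    cand <- list()
    addCands <- function(starts, scores, len, gap) {
        sel <- which(scores <= cutoff)
        for (k in sel)
            cand[[length(cand) + 1L]] <<- list(start = starts[k],
                                               end = starts[k] + len - 1L,
                                               score = scores[k], gap = gap)
    }
    # ungapped: miRNA i pairs target position s + L - i
    sU <- seq_len(n - L + 1L)
    B <- vapply(seq_len(L), function(i) penAt(i, sU + L - i),
                numeric(length(sU)))          # |sU| x L
    if (length(sU) == 1L) B <- matrix(B, nrow = 1L)
    addCands(sU, rowSums(B), L, NULL)
    if (max_gaps >= 1L) {
        gp <- weights$gap
        # one miRNA base j unpaired; site length L-1
        if (n >= L - 1L) {
            sT <- seq_len(n - L + 2L)
            A <- vapply(seq_len(L - 1L), function(i) penAt(i, sT + L - 1L - i),
                        numeric(length(sT)))  # i < j part
            B2 <- vapply(seq_len(L), function(i) {
                if (i == 1L) return(rep(NA_real_, length(sT)))
                penAt(i, sT + L - i)          # i > j part
            }, numeric(length(sT)))
            if (length(sT) == 1L) { A <- matrix(A, 1L); B2 <- matrix(B2, 1L) }
            PA <- cbind(0, t(apply(A, 1L, cumsum)))          # PA[, j] = sum_{i<j}
            B2[, 1L] <- 0
            CB2 <- t(apply(B2, 1L, cumsum))
            tot2 <- CB2[, L]
            for (j in seq_len(L)) {
                sc <- PA[, j] + gp * w[j] + tot2 - CB2[, j]
                addCands(sT, sc, L - 1L,
                         list(type = "gap_in_target", at = j))
            }
        }
        # one bulged target base before miRNA base j; site length L+1
        if (n >= L + 1L) {
            sM <- seq_len(n - L)
            Cm <- vapply(seq_len(L - 1L), function(i) penAt(i, sM + L + 1L - i),
                         numeric(length(sM))) # i < j part
            B3 <- vapply(seq_len(L), function(i) penAt(i, sM + L - i),
                         numeric(length(sM))) # i >= j part
            if (length(sM) == 1L) { Cm <- matrix(Cm, 1L); B3 <- matrix(B3, 1L) }
            PC <- cbind(0, t(apply(Cm, 1L, cumsum)))
            CB3 <- cbind(0, t(apply(B3, 1L, cumsum)))
            tot3 <- CB3[, L + 1L]
            for (j in seq_len(L)) {
                sc <- PC[, j] + gp * w[j] + tot3 - CB3[, j]
                addCands(sM, sc, L + 1L,
                         list(type = "gap_in_mirna", at = j))
            }
        }
    }
    if (!length(cand)) return(list())
    ord <- order(vapply(cand, `[[`, 0, "score"),
                 vapply(cand, `[[`, 0L, "start"))
    kept <- list()
    occupied <- logical(n)
    for (k in ord) {
        span <- cand[[k]]$start:cand[[k]]$end
        if (any(occupied[span])) next
        occupied[span] <- TRUE
        site_seq <- substr(tseq, cand[[k]]$start, cand[[k]]$end)
        states <- alignMirnaTarget(mirna, site_seq, gap = cand[[k]]$gap)
        kept[[length(kept) + 1L]] <- new("TargetSite", mirna = mirna,
            transcriptId = tid, start = cand[[k]]$start,
            end = cand[[k]]$end, states = states,
            score = cand[[k]]$score)
    }
    kept
}

#' Predict targets for a miRNA set over a transcript set
#'
#' Cross-product scan reporting, per (miRNA, transcript) pair with at least
#' one site under the cutoff, the number of sites and their scores
#' (best-first).
#'
#' @param mirnas data.frame of miRNA records (id + sequence) or a named
#'   character vector.
#' @param transcripts data.frame of transcript records (id + sequence).
#' @param cutoff Score cutoff (default 3.5).
#' @param max_gaps Indels per site (default 1).
#' @return data.frame with columns \code{mirna}, \code{transcript},
#'   \code{n_sites}, \code{best_score}, \code{scores} (comma-separated).
#' @export
predictTargets <- function(mirnas, transcripts, cutoff = 3.5, max_gaps = 1L) {
    if (!is.data.frame(mirnas))
        mirnas <- data.frame(id = names(mirnas), sequence = unname(mirnas))
    out <- list()
    for (i in seq_len(nrow(mirnas))) {
        for (j in seq_len(nrow(transcripts))) {
            sites <- findSites(mirnas$sequence[i], transcripts[j, ],
                               cutoff = cutoff, max_gaps = max_gaps)
            if (!length(sites)) next
            sc <- vapply(sites, siteScore, 0)
            out[[length(out) + 1L]] <- data.frame(
                mirna = mirnas$id[i], transcript = transcripts$id[j],
                n_sites = length(sites), best_score = min(sc),
                scores = paste(format(sc, trim = TRUE), collapse = ","))
        }
    }
    if (!length(out))
        return(data.frame(mirna = character(), transcript = character(),
                          n_sites = integer(), best_score = numeric(),
                          scores = character()))
    do.call(rbind, out)
}
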