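#' Fold an RNA sequence
#'
#' The default backend maximizes weighted base pairs (GC=3, AU=2, GU=1,
#' hairpin loops of at least \code{min_loop} nt, no pseudoknots) by dynamic
#' programming; its energy score is minus the total pair weight, in
#' arbitrary units (lower = more stable). The \code{"rnafold"} backend
#' substitutes the ViennaRNA thermodynamic folder (the \code{RNAfold}
#' executable must be on the PATH) behind the same contract, with the score
#' in kcal/mol.
#'
#' @param sequence RNA sequence (length >= 40 for precursor work; shorter
#'   sequences are folded all the same for testing).
#' @param backend \code{"maxpair"} (default) or \code{"rnafold"}.
#' @param min_loop Minimum hairpin loop length (default 3).
#' @return A list: \code{structure} (dot-bracket), \code{energy_score},
#'   \code{pairs} (1-based pair table, 0 = unpaired).
#' @export
foldRna <- function(sequence, backend = c("maxpair", "rnafold"),
                    min_loop = 3L) {
    backend <- match.arg(backend)
    seq <- normalizeRna(sequence)
    if (grepl("[^ACGU]", seq))
        stop("sequence contains characters outside the RNA alphabet")
    if (backend == "maxpair") {
        res <- .nussinovFold(seq, as.integer(min_loop))
        return(list(structure = res$structure,
                    energy_score = -res$weight,
                    pairs = res$pairs))
    }
    if (!nzchar(Sys.which("RNAfold")))
        stop("RNAfold executable not found on PATH")
    out <- system2("RNAfold", args = c("--noPS"), input = seq,
                   stdout = TRUE)
    line <- out[2L]
    db <- sub("\\s.*$", "", line)
    mfe <- as.numeric(gsub("[()]", "", sub("^\\S+\\s+", "", line)))
    list(structure = db, energy_score = mfe,
         pairs = pairTableFromDotBracket(db))
}

#' Pair table from a dot-bracket string
#'
#' @param db Dot-bracket structure.
#' @return Integer vector: position of the partner, 0 when unpaired.
#' @export
pairTableFromDotBracket <- function(db) {
    ch <- splitBases(db)
    pairs <- integer(length(ch))
    stack <- integer()
    for (i in seq_along(ch)) {
        if (ch[i] == "(") stack <- c(stack, i)
        else if (ch[i] == ")") {
            j <- stack[length(stack)]
            stack <- stack[-length(stack)]
            pairs[i] <- j
            pairs[j] <- i
        }
    }
    pairs
}

#' Dinucleotide-preserving shuffle (Altschul-Erikson)
#'
#' Random sequence with exactly the dinucleotide (and hence mononucleotide)
#' counts of the input and the same first and last base, sampled via a
#' random Eulerian walk on the dinucleotide multigraph.
#'
#' @param sequence RNA sequence.
#' @return A shuffled sequence of the same length.
#' @export
dinucleotideShuffle <- function(sequence) {
    b <- splitBases(normalizeRna(sequence))
    n <- length(b)
    if (n < 3L) return(sequence)
    from <- b[-n]
    to <- b[-1L]
    last <- b[n]
    verts <- unique(b)
    # adjacency: outgoing targets per vertex
    adj <- lapply(verts, function(v) to[from == v])
    names(adj) <- verts
    repeat {
        # pick a random candidate last-edge for every vertex but the final one
        lastEdge <- vapply(verts, function(v) {
            if (v == last || !length(adj[[v]])) NA_character_
            else adj[[v]][sample.int(length(adj[[v]]), 1L)]
        }, "")
        # the chosen last edges must lead every vertex into the final one
        ok <- TRUE
        for (v in verts) {
            if (v == last || !length(adj[[v]])) next
            cur <- v
            seen <- character()
            repeat {
                if (cur == last) break
                if (cur %in% seen || is.na(lastEdge[[cur]])) { ok <- FALSE; break }
                seen <- c(seen, cur)
                cur <- lastEdge[[cur]]
            }
            if (!ok) break
        }
        if (ok) break
    }
    ordered <- lapply(verts, function(v) {
        edges <- adj[[v]]
        if (!length(edges)) return(edges)
        if (v == last) return(edges[sample.int(length(edges))])
        le <- lastEdge[[v]]
        drop1 <- match(le, edges)
        rest <- edges[-drop1]
        c(if (length(rest)) rest[sample.int(length(rest))], le)
    })
    names(ordered) <- verts
    used <- setNames(integer(length(verts)), verts)
    out <- character(n)
    out[1L] <- b[1L]
    cur <- b[1L]
    for (i in 2:n) {
        used[cur] <- used[cur] + 1L
        nxt <- ordered[[cur]][used[cur]]
        out[i] <- nxt
        cur <- nxt
    }
    paste(out, collapse = "")
}

#' Extract candidate precursor windows around an sRNA hit
#'
#' One window per occurrence of the sRNA in the transcript per flank
#' setting (flank_min to flank_max in 50-nt steps, then the whole transcript
#' as a fallback), mimicking the practice of refolding with progressively
#' larger context when no local foldback appears. Flanks clipped at a
#' transcript end are flagged.
#'
#' @param srna sRNA sequence.
#' @param transcript A one-row record (id + sequence) or a character
#'   sequence (then id \code{"transcript"}).
#' @param flank_min,flank_max Flank extent per side, in nt (defaults 50 and
#'   200).
#' @return A list of \linkS4class{PrecursorWindow}; empty when the sRNA does
#'   not occur.
#' @export
extractPrecursorWindows <- function(srna, transcript, flank_min = 50L,
                                    flank_max = 200L) {
    if (is.data.frame(transcript)) {
        tid <- transcript$id[1L]
        tseq <- normalizeRna(transcript$sequence[1L])
    } else {
        tid <- "transcript"
        tseq <- normalizeRna(transcript)
    }
    srna <- normalizeRna(srna)
    L <- nchar(tseq)
    hits <- gregexpr(srna, tseq, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) return(list())
    flanks <- unique(c(seq(flank_min, flank_max, by = 50L), flank_max))
    out <- list()
    for (s in as.integer(hits)) {
        e <- s + nchar(srna) - 1L
        spans <- lapply(flanks, function(f)
            c(max(1L, s - f), min(L, e + f), (s - f < 1L) || (e + f > L)))
        spans <- c(spans, list(c(1L, L, FALSE)))
        seen <- character()
        for (sp in spans) {
            key <- paste(sp[1L], sp[2L])
            if (key %in% seen) next
            seen <- c(seen, key)
            out[[length(out) + 1L]] <- new("PrecursorWindow",
                transcriptId = tid, start = as.integer(sp[1L]),
                end = as.integer(sp[2L]),
                sequence = substr(tseq, sp[1L], sp[2L]),
                srnaStart = s - as.integer(sp[1L]) + 1L,
                srnaEnd = e - as.integer(sp[1L]) + 1L,
                truncated = as.logical(sp[3L]))
        }
    }
    out
}

#' Predict the miRNA* region and duplex statistics from a fold
#'
#' The star is the region pairing with the miRNA (ignoring its first two
#' positions) extended by the standard 2-nt 3' overhang of a DCL duplex.
#'
#' @param pairs Pair table (\code{\link{pairTableFromDotBracket}} or
#'   \code{\link{foldRna}}).
#' @param mirnaStart,mirnaEnd miRNA position within the folded sequence.
#' @return A list (\code{star_start}, \code{star_end}, \code{arm},
#'   \code{n_unpaired}, \code{max_asymmetric_bulge}, \code{loop_overlap}),
#'   or NULL when the miRNA is fully unpaired.
#' @export
findStar <- function(pairs, mirnaStart, mirnaEnd) {
    idx <- mirnaStart:mirnaEnd
    pr <- pairs[idx]
    paired <- which(pr != 0L)
    if (!length(paired)) return(NULL)
    partners <- pr[paired]
    right <- partners > mirnaEnd
    left <- partners < mirnaStart
    inside <- !right & !left
    loop_overlap <- any(inside) || (any(right) && any(left))
    arm <- if (sum(right) >= sum(left)) "5p" else "3p"
    good_dir <- if (arm == "5p") right else left
    if (!any(good_dir))
        return(list(star_start = NA_integer_, star_end = NA_integer_,
                    arm = arm, n_unpaired = length(idx),
                    max_asymmetric_bulge = NA_integer_,
                    loop_overlap = TRUE))
    n_unpaired <- length(idx) - sum(good_dir)
    pp <- paired[good_dir]
    max_bulge <- 0L
    if (length(pp) > 1L) {
        for (k in seq_len(length(pp) - 1L)) {
            gap_q <- pp[k + 1L] - pp[k] - 1L
            gap_s <- abs(pr[pp[k]] - pr[pp[k + 1L]]) - 1L
            max_bulge <- max(max_bulge, abs(gap_q - gap_s))
        }
    }
    starpos <- paired[good_dir & paired >= 3L]  # skip miRNA positions 1-2
    if (!length(starpos)) starpos <- paired[good_dir]
    partners2 <- pr[starpos]
    lo <- min(partners2)
    hi <- max(partners2) + 2L
    list(star_start = lo, star_end = min(hi, length(pairs)), arm = arm,
         n_unpaired = as.integer(n_unpaired),
         max_asymmetric_bulge = as.integer(max_bulge),
         loop_overlap = loop_overlap)
}

#' Evaluate the stem-loop precursor criteria for one window
#'
#' PASS requires: (i) the sRNA sits entirely in one stem arm and does not
#' overlap the terminal loop; (ii) at most \code{max_unpaired} sRNA bases
#' are unpaired against the star arm; (iii) the largest asymmetric bulge in
#' the duplex is at most \code{max_bulge}; (iv) the window folds more stably
#' than the mean of \code{n_shuffle} dinucleotide-shuffled versions of
#' itself (one-sided; a seeded null replaces an absolute cutoff because the
#' default backend's score is not in kcal/mol).
#'
#' @param window A \linkS4class{PrecursorWindow}.
#' @param fold Optional precomputed \code{\link{foldRna}} result for the
#'   window sequence.
#' @param max_unpaired Criterion (ii) threshold (default 4).
#' @param max_bulge Criterion (iii) threshold (default 2).
#' @param n_shuffle Shuffled windows for the energy null (default 100).
#' @param shuffle_seed Seed for the shuffle null (default 1).
#' @param backend Folding backend, see \code{\link{foldRna}}.
#' @param energy_criterion Set FALSE to skip criterion (iv).
#' @return A \linkS4class{HairpinCandidate}.
#' @export
evaluateHairpin <- function(window, fold = NULL, max_unpaired = 4L,
                            max_bulge = 2L, n_shuffle = 100L,
                            shuffle_seed = 1L,
                            backend = c("maxpair", "rnafold"),
                            energy_criterion = TRUE) {
    backend <- match.arg(backend)
    stopifnot(is(window, "PrecursorWindow"))
    if (is.null(fold)) fold <- foldRna(window@sequence, backend = backend)
    failed <- character()
    star <- findStar(fold$pairs, window@srnaStart, window@srnaEnd)
    if (is.null(star)) {
        failed <- c(failed, "arm", "duplex_pairing")
        stats <- list(n_unpaired_mirna_bases = window@srnaEnd -
                          window@srnaStart + 1L,
                      max_asymmetric_bulge = NA_integer_,
                      loop_overlap = FALSE, null_mean = NA_real_)
        arm <- NA_character_
        star_start <- NA_integer_; star_end <- NA_integer_
    } else {
        if (star$loop_overlap) failed <- c(failed, "loop_overlap")
        if (star$n_unpaired > max_unpaired)
            failed <- c(failed, "duplex_pairing")
        if (!is.na(star$max_asymmetric_bulge) &&
            star$max_asymmetric_bulge > max_bulge)
            failed <- c(failed, "bulge")
        stats <- list(n_unpaired_mirna_bases = star$n_unpaired,
                      max_asymmetric_bulge = star$max_asymmetric_bulge,
                      loop_overlap = star$loop_overlap,
                      null_mean = NA_real_)
        arm <- star$arm
        star_start <- star$star_start; star_end <- star$star_end
    }
    if (energy_criterion) {
        null_scores <- withSeed(shuffle_seed, {
            vapply(seq_len(n_shuffle), function(i) {
                foldRna(dinucleotideShuffle(window@sequence),
                        backend = backend)$energy_score
            }, 0)
        })
        stats$null_mean <- mean(null_scores)
        if (!(fold$energy_score < stats$null_mean))
            failed <- c(failed, "energy")
    }
    new("HairpinCandidate", window = window, structure = fold$structure,
        energyScore = fold$energy_score, arm = arm,
        starStart = as.integer(star_start), starEnd = as.integer(star_end),
        duplexStats = stats,
        verdict = if (length(failed)) "FAIL" else "PASS",
        failed = unique(failed))
}

#' Call a hairpin candidate over all window settings
#'
#' Evaluates the precursor criteria on every extracted window (increasing
#' flank, whole transcript as fallback) and returns the first PASS, or the
#' last evaluated candidate when none passes -- the analogue of refolding
#' with progressively larger context when no local foldback appears.
#'
#' @param srna Candidate sRNA sequence.
#' @param transcript One-row record (id + sequence) or character sequence.
#' @param flank_min,flank_max Flank settings, see
#'   \code{\link{extractPrecursorWindows}}.
#' @param ... Passed to \code{\link{evaluateHairpin}}.
#' @return A \linkS4class{HairpinCandidate}, or NULL when the sRNA does not
#'   occur in the transcript.
#' @export
callHairpinCandidate <- function(srna, transcript, flank_min = 50L,
                                 flank_max = 200L, ...) {
    windows <- extractPrecursorWindows(srna, transcript, flank_min,
                                       flank_max)
    if (!length(windows)) return(NULL)
    last <- NULL
    for (w in windows) {
        cand <- evaluateHairpin(w, ...)
        if (verdict(cand) == "PASS") return(cand)
        last <- cand
    }
    last
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    expr
}
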