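# Shared fixtures and independent brute-force oracles used across tests.

MIR159 <- "UUUGGAUUGAAGGGAGCUCUA"
MIR390 <- "AAGCUCAGGAGGGAUAGCGCC"

randomRna <- function(n, len) {
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
              collapse = ""), "")
}

# Exhaustive Hamming oracle for miRNA homology matching: every reference x
# every end offset, integer-coded bases, same tie rules as the contract
# (fewest mismatches, then smallest total |offset|, then family name).
bruteMatchOracle <- function(seq, refs, max_mm = 3L, max_ov = 3L) {
    q <- utf8ToInt(seq)
    best <- NULL
    for (r in seq_len(nrow(refs))) {
        cv <- utf8ToInt(refs$sequence[r])
        for (d5 in -max_ov:max_ov) {
            d3 <- length(q) - length(cv) - d5
            if (abs(d3) > max_ov) next
            i <- seq_along(q)
            j <- i - d5
            ov <- j >= 1L & j <= length(cv)
            if (!any(ov)) next
            mm <- sum(q[ov] != cv[j[ov]])
            if (mm > max_mm) next
            key <- c(mm, abs(d5) + abs(d3))
            if (is.null(best) || key[1] < best$mm ||
                (key[1] == best$mm && key[2] < best$off) ||
                (key[1] == best$mm && key[2] == best$off &&
                 refs$family[r] < best$family))
                best <- list(mm = mm, off = key[2], d5 = d5, d3 = d3,
                             family = refs$family[r])
        }
    }
    best
}

# Recursive maximum-weighted-pairing oracle (top-down, memoized) for short
# sequences; same weight scheme as the folding backend contract.
bruteFoldScore <- function(seq, min_loop = 3L) {
    b <- strsplit(seq, "")[[1]]
    n <- length(b)
    wt <- function(a, c) {
        if ((a == "G" && c == "C") || (a == "C" && c == "G")) return(3)
        if ((a == "A" && c == "U") || (a == "U" && c == "A")) return(2)
        if ((a == "G" && c == "U") || (a == "U" && c == "G")) return(1)
        0
    }
    memo <- new.env(hash = TRUE)
    f <- function(i, j) {
        if (i >= j || j - i < min_loop + 1L) return(0)
        key <- paste(i, j)
        hit <- memo[[key]]
        if (!is.null(hit)) return(hit)
        best <- f(i + 1L, j)
        for (k in (i + min_loop + 1L):j) {
            w <- wt(b[i], b[k])
            if (w > 0)
                best <- max(best, w + f(i + 1L, k - 1L) + f(k + 1L, j))
        }
        memo[[key]] <- best
        best
    }
    f(1L, n)
}

# Brute-force target-site scan: every window / single-indel variant scored
# through the public alignment API, then the same greedy non-overlap rule.
bruteSiteScan <- function(mirna, tseq, cutoff, max_gaps = 1L) {
    L <- nchar(mirna)
    n <- nchar(tseq)
    cand <- list()
    add <- function(s, len, states) {
        sc <- scoreAlignment(states)
        if (sc <= cutoff)
            cand[[length(cand) + 1L]] <<- list(start = s, end = s + len - 1L,
                                               score = sc)
    }
    for (s in seq_len(n - L + 1L))
        add(s, L, alignMirnaTarget(mirna, substr(tseq, s, s + L - 1L)))
    if (max_gaps >= 1L) {
        for (s in seq_len(n - L + 2L)) for (j in seq_len(L))
            add(s, L - 1L, alignMirnaTarget(mirna, substr(tseq, s, s + L - 2L),
                gap = list(type = "gap_in_target", at = j)))
        if (n >= L + 1L)
            for (s in seq_len(n - L)) for (j in seq_len(L))
                add(s, L + 1L, alignMirnaTarget(mirna, substr(tseq, s, s + L),
                    gap = list(type = "gap_in_mirna", at = j)))
    }
    if (!length(cand)) return(data.frame(start = integer(),
                                         end = integer(), score = numeric()))
    ord <- order(vapply(cand, `[[`, 0, "score"),
                 vapply(cand, `[[`, 0L, "start"))
    occupied <- logical(n)
    kept <- list()
    for (k in ord) {
        span <- cand[[k]]$start:cand[[k]]$end
        if (any(occupied[span])) next
        occupied[span] <- TRUE
        kept[[length(kept) + 1L]] <- cand[[k]]
    }
    do.call(rbind, lapply(kept, as.data.frame))
}

# Handcrafted fold object (structure + pair table) for duplex-criteria
# tests: `pairing` maps positions to partners (both directions filled in).
makeFold <- function(n, pairing, energy = -50) {
    pairs <- integer(n)
    for (i in names(pairing)) {
        a <- as.integer(i); b <- pairing[[i]]
        pairs[a] <- b; pairs[b] <- a
    }
    db <- rep(".", n)
    db[pairs != 0 & seq_len(n) < pairs] <- "("
    db[pairs != 0 & seq_len(n) > pairs] <- ")"
    list(structure = paste(db, collapse = ""), energy_score = energy,
         pairs = pairs)
}

dinucCounts <- function(seq) {
    b <- strsplit(seq, "")[[1]]
    table(paste0(b[-length(b)], b[-1]))
}
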