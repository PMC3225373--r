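# Filtering cascade: adapter stripping -> N removal -> size -> complexity ->
# ncRNA, with each removed read attributed to the FIRST failing filter so the
# accounting closes exactly.

#' Strip library adapters from one raw read
#'
#' Recognition is exact on the first \code{min_anchor} bases of each adapter,
#' then full-length comparison allowing at most one mismatch beyond the
#' anchor. Artifact classes mirror what 454 sRNA libraries produce: adapter
#' dimers without an insert, multimers with more than one 3' adapter copy,
#' and reads in which either adapter cannot be recognized.
#'
#' @param read A single raw read (character) or a one-row data.frame from
#'   \code{\link{readFastaRecords}}.
#' @param adapters Adapter configuration from \code{\link{readAdapterConfig}}.
#' @return A list with \code{insert} (character or NA) and \code{artifact}
#'   (NA, \code{"no_insert"}, \code{"multimer"} or \code{"unrecognized"}).
#' @export
stripAdapters <- function(read, adapters) {
    if (is.data.frame(read)) read <- read$sequence
    seq <- normalizeRna(read)
    a5 <- adapters$five_prime_variants
    a3 <- adapters$three_prime
    anchor <- adapters$min_anchor

    five_end <- NA_integer_
    for (ad in a5) {
        if (nchar(seq) < nchar(ad)) next
        if (substr(seq, 1L, anchor) != substr(ad, 1L, anchor)) next
        rest_read <- substr(seq, anchor + 1L, nchar(ad))
        rest_ad <- substr(ad, anchor + 1L, nchar(ad))
        if (hammingDistance(rest_read, rest_ad) <= 1L) {
            five_end <- nchar(ad)
            break
        }
    }
    if (is.na(five_end))
        return(list(insert = NA_character_, artifact = "unrecognized"))

    remainder <- substr(seq, five_end + 1L, nchar(seq))
    a3_anchor <- substr(a3, 1L, anchor)
    hits <- integer()
    p <- 1L
    repeat {
        m <- regexpr(a3_anchor, substr(remainder, p, nchar(remainder)),
                     fixed = TRUE)
        if (m == -1L) break
        pos <- p + as.integer(m) - 1L
        cand <- substr(remainder, pos, pos + nchar(a3) - 1L)
        if (nchar(cand) == nchar(a3) &&
            hammingDistance(substr(cand, anchor + 1L, nchar(a3)),
                            substr(a3, anchor + 1L, nchar(a3))) <= 1L)
            hits <- c(hits, pos)
        p <- pos + 1L
        if (p > nchar(remainder)) break
    }
    if (!length(hits))
        return(list(insert = NA_character_, artifact = "unrecognized"))
    if (length(hits) > 1L)
        return(list(insert = NA_character_, artifact = "multimer"))
    if (hits[1L] == 1L)
        return(list(insert = NA_character_, artifact = "no_insert"))
    list(insert = substr(remainder, 1L, hits[1L] - 1L), artifact = NA_character_)
}

#' Size, complexity and ncRNA filters
#'
#' \code{filterSize} keeps inserts inside the closed 18-25 nt range of DCL
#' products; \code{filterComplexity} keeps sequences with at least 3 distinct
#' nucleotides; \code{filterNcrna} drops sequences occurring as a (near)
#' substring of any non-coding RNA reference.
#'
#' @param seq Character vector of insert sequences.
#' @param min_len,max_len Inclusive size bounds.
#' @return Logical vector: TRUE = keep.
#' @export
filterSize <- function(seq, min_len = 18L, max_len = 25L) {
    stopifnot(min_len > 0L, min_len <= max_len)
    n <- nchar(seq)
    n >= min_len & n <= max_len
}

#' @rdname filterSize
#' @param min_distinct_bases Minimum number of distinct nucleotides.
#' @export
filterComplexity <- function(seq, min_distinct_bases = 3L) {
    vapply(strsplit(normalizeRna(seq), ""),
           function(ch) length(unique(ch)), 1L) >= min_distinct_bases
}

#' @rdname filterSize
#' @param ncrna_refs data.frame of reference records
#'   (\code{\link{readFastaRecords}}) for rRNA/tRNA/snRNA/snoRNA.
#' @param max_mismatches Mismatches tolerated in the ungapped match
#'   (default 0: exact substring).
#' @param both_strands Also test the reverse complement (default TRUE).
#' @return \code{filterNcrna}: logical vector, TRUE = keep (no reference
#'   match); the attribute \code{"matched_ref"} carries the id of the first
#'   matching reference for dropped sequences.
#' @export
filterNcrna <- function(seq, ncrna_refs, max_mismatches = 0L,
                        both_strands = TRUE) {
    stopifnot(nrow(ncrna_refs) > 0L)
    refs <- normalizeRna(ncrna_refs$sequence)
    seq <- normalizeRna(seq)
    matched <- rep(NA_character_, length(seq))
    for (i in seq_along(seq)) {
        queries <- seq[i]
        if (both_strands) queries <- c(queries, reverseComplementRna(seq[i]))
        for (q in queries) {
            hit <- ncrnaHit(q, refs, max_mismatches)
            if (!is.na(hit)) { matched[i] <- ncrna_refs$id[hit]; break }
        }
    }
    keep <- is.na(matched)
    attr(keep, "matched_ref") <- matched
    keep
}

# Seed-and-extend ungapped substring match of one query against references.
# Seeds are exact; with m allowed mismatches the query is cut into m+1 chunks
# (pigeonhole: at least one chunk is mismatch-free), each chunk capped at 12
# bases. Returns the index of the first matching reference or NA.
ncrnaHit <- function(query, refs, max_mm) {
    L <- nchar(query)
    if (max_mm == 0L) {
        for (j in seq_along(refs))
            if (grepl(query, refs[j], fixed = TRUE)) return(j)
        return(NA_integer_)
    }
    nchunk <- max_mm + 1L
    bounds <- floor(seq(0L, L, length.out = nchunk + 1L))
    qb <- splitBases(query)
    for (j in seq_along(refs)) {
        ref <- refs[j]
        rb <- splitBases(ref)
        for (k in seq_len(nchunk)) {
            s <- bounds[k] + 1L
            e <- bounds[k + 1L]
            w <- min(12L, e - s + 1L)
            seedseq <- substr(query, s, s + w - 1L)
            p <- 1L
            repeat {
                m <- regexpr(seedseq, substr(ref, p, nchar(ref)), fixed = TRUE)
                if (m == -1L) break
                pos <- p + as.integer(m) - 1L
                start <- pos - (s - 1L)
                if (start >= 1L && start + L - 1L <= nchar(ref)) {
                    mm <- sum(rb[start:(start + L - 1L)] != qb)
                    if (mm <= max_mm) return(j)
                }
                p <- pos + 1L
                if (p > nchar(ref)) break
            }
        }
    }
    NA_integer_
}

#' Run the full preprocessing cascade on raw reads
#'
#' Applies adapter stripping, then drops N-containing inserts, then the
#' size, complexity and ncRNA filters in that order, attributing every
#' removed read to the first failing filter, and de-duplicates the surviving
#' inserts into an \linkS4class{SRNALibrary}.
#'
#' @param reads data.frame of raw reads (\code{\link{readFastaRecords}}) or a
#'   character vector.
#' @param adapters Adapter configuration (\code{\link{readAdapterConfig}}).
#' @param ncrna_refs ncRNA reference records, or NULL to skip that filter.
#' @param label Library label.
#' @param min_len,max_len,min_distinct_bases,max_mismatches,both_strands
#'   Filter parameters, see \code{\link{filterSize}} and friends.
#' @return An \linkS4class{SRNALibrary}.
#' @export
runPreprocess <- function(reads, adapters, ncrna_refs = NULL,
                          label = "library", min_len = 18L, max_len = 25L,
                          min_distinct_bases = 3L, max_mismatches = 0L,
                          both_strands = TRUE) {
    if (is.data.frame(reads)) reads <- reads$sequence
    reads <- normalizeRna(reads)
    raw_n <- length(reads)

    stripped <- lapply(reads, stripAdapters, adapters = adapters)
    artifact <- vapply(stripped, function(x) x$artifact, "")
    inserts <- vapply(stripped, function(x) x$insert, "")
    ok <- is.na(artifact)
    artifacts <- c(
        no_insert = sum(artifact == "no_insert", na.rm = TRUE),
        multimer = sum(artifact == "multimer", na.rm = TRUE),
        unrecognized = sum(artifact == "unrecognized", na.rm = TRUE)
    )
    inserts <- inserts[ok]
    adapter_removed <- length(inserts)

    has_n <- grepl("N", inserts, fixed = TRUE)
    post <- c(contains_n = sum(has_n))
    inserts <- inserts[!has_n]

    keep_size <- filterSize(inserts, min_len, max_len)
    post <- c(post, size = sum(!keep_size))
    inserts <- inserts[keep_size]

    keep_cx <- filterComplexity(inserts, min_distinct_bases)
    post <- c(post, complexity = sum(!keep_cx))
    inserts <- inserts[keep_cx]

    if (!is.null(ncrna_refs) && length(inserts)) {
        uniq <- unique(inserts)
        keep_u <- filterNcrna(uniq, ncrna_refs, max_mismatches, both_strands)
        keep_nc <- keep_u[match(inserts, uniq)]
        post <- c(post, ncrna = sum(!keep_nc))
        inserts <- inserts[keep_nc]
    } else {
        post <- c(post, ncrna = 0L)
    }

    tab <- table(inserts)
    seqs <- as.character(names(tab))
    counts <- as.integer(tab)
    ord <- order(seqs)
    new("SRNALibrary", label = label, sequences = seqs[ord],
        counts = counts[ord],
        stats = list(
            raw_reads = raw_n,
            adapter_removed_reads = adapter_removed,
            filtered_reads = length(inserts),
            unique_sequences = length(seqs),
            artifacts = artifacts,
            removed = post
        ))
}

#' Build an SRNALibrary directly from clean inserts
#'
#' Convenience constructor for already-trimmed sequences (e.g. a count
#' table): de-duplicates and fills the stats block as if every read had
#' passed all filters.
#'
#' @param sequences Character vector of insert sequences (repeated according
#'   to abundance) or unique sequences when \code{counts} is given.
#' @param counts Optional integer counts parallel to \code{sequences}.
#' @param label Library label.
#' @return An \linkS4class{SRNALibrary}.
#' @export
srnaLibrary <- function(sequences, counts = NULL, label = "library") {
    sequences <- normalizeRna(sequences)
    if (is.null(counts)) {
        tab <- table(sequences)
        sequences <- names(tab)
        counts <- as.integer(tab)
    } else {
        stopifnot(length(counts) == length(sequences))
        agg <- tapply(as.integer(counts), sequences, sum)
        sequences <- names(agg)
        counts <- as.integer(agg)
    }
    keep <- counts > 0L
    sequences <- sequences[keep]; counts <- counts[keep]
    ord <- order(sequences)
    total <- sum(counts)
    new("SRNALibrary", label = label, sequences = sequences[ord],
        counts = counts[ord],
        stats = list(raw_reads = total, adapter_removed_reads = total,
                     filtered_reads = total,
                     unique_sequences = length(sequences),
                     artifacts = c(no_insert = 0L, multimer = 0L,
                                   unrecognized = 0L),
                     removed = c(contains_n = 0L, size = 0L,
                                 complexity = 0L, ncrna = 0L)))
}
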