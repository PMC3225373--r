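#' Match one sRNA against a mature miRNA reference set
#'
#' Ungapped, anchored comparison: the query is slid over each canonical
#' sequence with 5' end offsets in \code{[-max_overhang, +max_overhang]}
#' (positive = extension beyond the canonical end, negative = truncation);
#' only the overlapped region is compared, so overhanging bases are tolerated
#' but never penalized. The best assignment has the fewest internal
#' mismatches, ties broken by the smaller total absolute offset, then by the
#' lexicographically smallest family name.
#'
#' @param seq Query sRNA sequence.
#' @param references Reference records with columns \code{sequence},
#'   \code{family} and \code{id} (see \code{\link{matureMirnaReferences}}).
#' @param max_mismatches Maximum internal mismatches (default 3).
#' @param max_overhang Maximum absolute 5'/3' end offset (default 3).
#' @return A \linkS4class{MiRNAMatch}, or NULL when no reference satisfies
#'   the limits.
#' @export
matchMirna <- function(seq, references, max_mismatches = 3L,
                       max_overhang = 3L) {
    stopifnot(nrow(references) > 0L)
    q <- normalizeRna(seq)
    qb <- splitBases(q)
    Lq <- length(qb)
    best <- NULL
    for (r in seq_len(nrow(references))) {
        canon <- normalizeRna(references$sequence[r])
        cb <- splitBases(canon)
        Lc <- length(cb)
        for (d5 in seq(-max_overhang, max_overhang)) {
            d3 <- Lq - Lc - d5
            if (abs(d3) > max_overhang) next
            # query index i aligns to canonical index i - d5
            i <- seq_len(Lq)
            j <- i - d5
            ov <- j >= 1L & j <= Lc
            if (!any(ov)) next
            mm <- sum(qb[ov] != cb[j[ov]])
            if (mm > max_mismatches) next
            cand <- list(mm = mm, d5 = d5, d3 = d3,
                         family = references$family[r],
                         reference = canon)
            if (is.null(best) ||
                cand$mm < best$mm ||
                (cand$mm == best$mm &&
                 abs(cand$d5) + abs(cand$d3) < abs(best$d5) + abs(best$d3)) ||
                (cand$mm == best$mm &&
                 abs(cand$d5) + abs(cand$d3) == abs(best$d5) + abs(best$d3) &&
                 cand$family < best$family))
                best <- cand
        }
    }
    if (is.null(best)) return(NULL)
    new("MiRNAMatch", query = q, family = best$family,
        reference = best$reference,
        nInternalMismatches = as.integer(best$mm),
        fivePrimeOffset = as.integer(best$d5),
        threePrimeOffset = as.integer(best$d3),
        isStar = endsWith(best$family, "*"))
}

#' Classify a miRNA match into its variant class
#'
#' Canonical means identical to the reference (no mismatches, no end
#' offsets). Any nonzero end offset makes the sequence a length variant on
#' the corresponding side (both sides when both offsets are nonzero), with
#' precedence over internal mismatches; otherwise it is an internal-mismatch
#' variant.
#'
#' @param match A \linkS4class{MiRNAMatch}.
#' @return One of \code{"canonical"}, \code{"internal_mismatch"},
#'   \code{"length_variant_5p"}, \code{"length_variant_3p"},
#'   \code{"length_variant_both"}.
#' @export
classifyVariant <- function(match) {
    stopifnot(is(match, "MiRNAMatch"))
    d5 <- match@fivePrimeOffset
    d3 <- match@threePrimeOffset
    mm <- match@nInternalMismatches
    if (mm == 0L && d5 == 0L && d3 == 0L) return("canonical")
    if (d5 != 0L && d3 != 0L) return("length_variant_both")
    if (d5 != 0L) return("length_variant_5p")
    if (d3 != 0L) return("length_variant_3p")
    "internal_mismatch"
}

# Star rows fold into the family of their mature partner.
matureFamily <- function(family) sub("\\*$", "", family)

#' Roll a count table of matched sRNAs up into family tallies
#'
#' Star-strand rows merge into the family of their mature partner. Per
#' library, a family's read count is the sum over its rows and its unique
#' count the number of rows sampled at least once.
#'
#' @param counts A count table (\code{\link{readCountTable}}) whose
#'   \code{family} column carries the homology assignment.
#' @return A data.frame sorted by family name: \code{family}, then per
#'   library \code{reads_<lib>} and \code{unique_<lib>}, plus
#'   \code{reads_total}.
#' @export
tallyFamilies <- function(counts) {
    libs <- attr(counts, "libraries") %||%
        setdiff(names(counts), c("sequence", "length", "family",
                                 "northern_only"))
    fam <- matureFamily(counts$family)
    families <- sort(unique(fam))
    out <- data.frame(family = families, stringsAsFactors = FALSE)
    for (lb in libs) {
        cnt <- counts[[lb]]
        out[[paste0("reads_", lb)]] <-
            vapply(families, function(f) sum(cnt[fam == f]), 1L)
        out[[paste0("unique_", lb)]] <-
            vapply(families, function(f) sum(cnt[fam == f] > 0L), 1L)
    }
    out$reads_total <- rowSums(as.matrix(out[paste0("reads_", libs)]))
    attr(out, "libraries") <- libs
    out
}

#' Summary of known-miRNA content
#'
#' Library-level roll-up of the family tallies: total matched reads and
#' unique sequences per library, the number of families overall and per
#' library. Northern-only rows (all counts zero) contribute to family
#' existence only when \code{include_northern_only} is set.
#'
#' @param tallies Output of \code{\link{tallyFamilies}}.
#' @param include_northern_only Count zero-read families as present
#'   per library (default FALSE).
#' @return A list: \code{total_matched_reads}, \code{families_total}, and
#'   per library \code{reads}, \code{unique}, \code{families}.
#' @export
summarizeKnown <- function(tallies, include_northern_only = FALSE) {
    libs <- attr(tallies, "libraries") %||%
        sub("^reads_", "", grep("^reads_(?!total)", names(tallies),
                                perl = TRUE, value = TRUE))
    per_lib <- lapply(libs, function(lb) {
        reads <- tallies[[paste0("reads_", lb)]]
        uniq <- tallies[[paste0("unique_", lb)]]
        fams <- if (include_northern_only) nrow(tallies) else sum(reads > 0L)
        list(reads = sum(reads), unique = sum(uniq), families = fams)
    })
    names(per_lib) <- libs
    list(
        total_matched_reads = sum(tallies$reads_total),
        families_total = nrow(tallies),
        libraries = per_lib
    )
}

#' Total reads of one family across libraries
#'
#' @param tallies Output of \code{\link{tallyFamilies}}.
#' @param family Family token (star suffix tolerated; it is merged anyway).
#' @return Integer read total.
#' @export
familyReadTotal <- function(tallies, family) {
    family <- matureFamily(family)
    i <- match(family, tallies$family)
    if (is.na(i)) stop("unknown family: ", family)
    tallies$reads_total[i]
}

#' Annotate a count table against a mature reference set
#'
#' Runs \code{\link{matchMirna}} and \code{\link{classifyVariant}} on every
#' row and returns the per-sequence match report.
#'
#' @param counts A count table (\code{\link{readCountTable}}).
#' @param references Reference records (\code{\link{matureMirnaReferences}}).
#' @param max_mismatches,max_overhang See \code{\link{matchMirna}}.
#' @return The count table with added columns \code{matched_family},
#'   \code{n_mismatches}, \code{offset_5p}, \code{offset_3p},
#'   \code{variant_class} (NA for unmatched rows).
#' @export
annotateCountTable <- function(counts, references, max_mismatches = 3L,
                               max_overhang = 3L) {
    n <- nrow(counts)
    counts$matched_family <- NA_character_
    counts$n_mismatches <- NA_integer_
    counts$offset_5p <- NA_integer_
    counts$offset_3p <- NA_integer_
    counts$variant_class <- NA_character_
    for (i in seq_len(n)) {
        m <- matchMirna(counts$sequence[i], references, max_mismatches,
                        max_overhang)
        if (is.null(m)) next
        counts$matched_family[i] <- m@family
        counts$n_mismatches[i] <- m@nInternalMismatches
        counts$offset_5p[i] <- m@fivePrimeOffset
        counts$offset_3p[i] <- m@threePrimeOffset
        counts$variant_class[i] <- classifyVariant(m)
    }
    counts
}
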