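#' Size-class profile of a filtered sRNA library
#'
#' Tallies total reads and unique sequences per length class and their
#' percentage shares, the per-class uniqueness ratio included.
#'
#' @param lib An \linkS4class{SRNALibrary}.
#' @return A data.frame with one row per length present: \code{length},
#'   \code{total_reads}, \code{unique_sequences}, \code{pct_total},
#'   \code{pct_unique}, \code{uniqueness} (unique/total within the class).
#' @export
sizeProfile <- function(lib) {
    stopifnot(is(lib, "SRNALibrary"))
    if (!length(lib@sequences)) stop("empty library")
    len <- nchar(lib@sequences)
    lengths <- sort(unique(len))
    total <- vapply(lengths, function(L) sum(lib@counts[len == L]), 1L)
    uniq <- vapply(lengths, function(L) sum(len == L), 1L)
    data.frame(
        length = lengths,
        total_reads = total,
        unique_sequences = uniq,
        pct_total = 100 * total / sum(total),
        pct_unique = 100 * uniq / sum(uniq),
        uniqueness = uniq / total
    )
}

#' 5' nucleotide composition of one size class
#'
#' Proportion of A/C/G/U at the first position over the unique sequences of
#' a length class; the 24-nt class of heterochromatin-associated siRNAs is
#' expected to be 5'A-enriched (AGO4 loading signature).
#'
#' @param lib An \linkS4class{SRNALibrary}.
#' @param length_class Length in nt.
#' @return Named numeric vector over A, C, G, U summing to 1.
#' @export
fivePrimeComposition <- function(lib, length_class) {
    stopifnot(is(lib, "SRNALibrary"))
    seqs <- lib@sequences[nchar(lib@sequences) == length_class]
    if (!length(seqs)) stop("no sequences of length ", length_class)
    first <- substr(seqs, 1L, 1L)
    counts <- vapply(RNA_BASES, function(b) sum(first == b), 1L)
    counts / sum(counts)
}

#' Reads-per-thousand normalization
#'
#' rpt = 1000 x count / filtered library total, so a whole library sums to
#' 1000 rpt.
#'
#' @param count Read count(s).
#' @param library_total Total filtered reads of the library.
#' @return Numeric rpt value(s).
#' @export
normalizeRpt <- function(count, library_total) {
    if (any(library_total <= 0)) stop("library_total must be positive")
    1000 * count / library_total
}

#' Ratio of two normalized abundances
#'
#' @param a,b rpt values (numerator, denominator).
#' @return \code{a / b}; an error when \code{b} is zero.
#' @export
abundanceRatio <- function(a, b) {
    if (any(b == 0)) stop("division by zero: denominator abundance is 0 rpt")
    a / b
}

#' Display rounding used in size-profile reports
#'
#' Size-class shares are reported to the nearest integer percent, sub-percent
#' classes to one decimal, rpt values to two decimals.
#'
#' @param pct Percentage value(s).
#' @return Rounded value(s).
#' @keywords internal
roundShare <- function(pct) {
    ifelse(pct < 10, round(pct, 1L), round(pct))
}
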