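# Internal sequence helpers shared across modules. All internal comparisons
# happen on the RNA alphabet: T is folded into U on ingest.

RNA_BASES <- c("A", "C", "G", "U")

normalizeRna <- function(x) {
    x <- toupper(x)
    chartr("T", "U", x)
}

#' Reverse complement on the RNA alphabet
#'
#' @param x Character vector of RNA sequences (U/T equivalent; T is folded
#'   into U first).
#' @return Character vector of reverse complements, RNA alphabet.
#' @examples
#' reverseComplementRna("ACGU")  # "ACGU"
#' @export
reverseComplementRna <- function(x) {
    x <- normalizeRna(x)
    comp <- chartr("ACGUN", "UGCAN", x)
    vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

splitBases <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

hammingDistance <- function(a, b) {
    stopifnot(nchar(a) == nchar(b))
    sum(splitBases(a) != splitBases(b))
}

# Watson-Crick pair (RNA)?
isWatsonCrick <- function(a, b) {
    (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

isWobble <- function(a, b) {
    (a == "G" & b == "U") | (a == "U" & b == "G")
}

# Deterministic child seeds: one user seed fans out to per-component streams
# without correlated overlap. Constants are arbitrary odd multipliers; results
# stay inside the 32-bit integer range R requires of set.seed().
childSeed <- function(seed, index) {
    s <- (as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647
    as.integer(s)
}

randomRnaSequence <- function(n, length, first_base_prob = NULL) {
    vapply(seq_len(n), function(i) {
        first <- if (is.null(first_base_prob)) sample(RNA_BASES, 1L)
                 else sample(RNA_BASES, 1L, prob = first_base_prob)
        rest <- sample(RNA_BASES, length - 1L, replace = TRUE)
        paste(c(first, rest), collapse = "")
    }, "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
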