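# RLM-5'RACE cleavage mapping: clone 5' ends are placed on the target
# transcript and expressed in miRNA duplex coordinates ("10/11" = the bond
# opposite the boundary between miRNA positions 10 and 11).

#' Map RACE clone 5' ends onto a transcript
#'
#' Each clone is an internal fragment of the transcript beginning at the
#' cleavage product's 5' end; by default it must match exactly (RACE clones
#' are Sanger-sequenced), a mismatch allowance is config-exposed.
#'
#' @param clones Character vector of clone sequences (or records).
#' @param transcript One-row record (id + sequence) or a character sequence.
#' @param max_mismatches Substitutions tolerated when placing a clone
#'   (default 0).
#' @return Integer vector of transcript coordinates of each clone's first
#'   nucleotide, NA for unmappable clones.
#' @export
mapRaceEnds <- function(clones, transcript, max_mismatches = 0L) {
    if (is.data.frame(clones)) clones <- clones$sequence
    if (is.data.frame(transcript)) transcript <- transcript$sequence[1L]
    tseq <- normalizeRna(transcript)
    clones <- normalizeRna(clones)
    vapply(clones, function(cl) {
        if (max_mismatches == 0L) {
            m <- regexpr(cl, tseq, fixed = TRUE)
            return(if (m == -1L) NA_integer_ else as.integer(m))
        }
        cb <- splitBases(cl)
        L <- length(cb)
        tb <- splitBases(tseq)
        for (s in seq_len(nchar(tseq) - L + 1L)) {
            if (sum(tb[s:(s + L - 1L)] != cb) <= max_mismatches)
                return(s)
        }
        NA_integer_
    }, 1L, USE.NAMES = FALSE)
}

#' Express a transcript position in miRNA duplex coordinates
#'
#' A clone 5' end at transcript position p marks the cleaved bond 5' of p.
#' Inside the site the label is \code{"k/k+1"} where the bond lies opposite
#' the boundary between miRNA positions k and k+1 (the canonical AGO slice
#' site labels \code{"10/11"}); outside it is \code{"upstream n nt"} /
#' \code{"downstream n nt"} relative to the site.
#'
#' @param position Transcript coordinate of the clone 5' end.
#' @param site A \linkS4class{TargetSite}.
#' @return Character label.
#' @export
positionInDuplex <- function(position, site) {
    stopifnot(is(site, "TargetSite"))
    vapply(position, function(p) {
        if (p < site@start)
            return(sprintf("upstream %d nt", site@start - p))
        if (p > site@end)
            return(sprintf("downstream %d nt", p - site@end))
        k <- site@end - p + 1L
        sprintf("%d/%d", k, k + 1L)
    }, "")
}

#' Build a cleavage map from clones, transcript and site
#'
#' @param clones Clone sequences.
#' @param transcript One-row record (id + sequence) or character sequence.
#' @param site The \linkS4class{TargetSite} guiding cleavage.
#' @param max_mismatches Clone placement tolerance, see
#'   \code{\link{mapRaceEnds}}.
#' @return A \linkS4class{CleavageMap}.
#' @export
cleavageMap <- function(clones, transcript, site, max_mismatches = 0L) {
    tid <- if (is.data.frame(transcript)) transcript$id[1L] else "transcript"
    pos <- mapRaceEnds(clones, transcript, max_mismatches)
    mapped <- pos[!is.na(pos)]
    tab <- table(mapped)
    tx_pos <- as.integer(names(tab))
    positions <- data.frame(
        tx_pos = tx_pos,
        label = positionInDuplex(tx_pos, site),
        count = as.integer(tab))
    positions <- positions[order(-positions$count, positions$tx_pos), ,
                           drop = FALSE]
    rownames(positions) <- NULL
    new("CleavageMap", transcriptId = tid, site = site,
        positions = positions, unmapped = sum(is.na(pos)))
}

#' Dominant cleavage position and clone fraction
#'
#' @param map A \linkS4class{CleavageMap} with at least one mapped clone.
#' @return A list: \code{dominant} (character vector of duplex labels; more
#'   than one on a tie), \code{fraction} (string \code{"x/N"} over mapped
#'   clones), \code{tie} flag.
#' @export
tallyCleavage <- function(map) {
    stopifnot(is(map, "CleavageMap"))
    pos <- map@positions
    if (!nrow(pos)) stop("no mapped clones")
    top <- max(pos$count)
    dom <- pos$label[pos$count == top]
    list(dominant = dom,
         fraction = sprintf("%d/%d", top, sum(pos$count)),
         tie = length(dom) > 1L)
}
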