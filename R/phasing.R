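# TAS3 "two-hit" analysis: dual miR390 complementary sites flank the
# tasiRNA-producing region; cleavage at the 3' site sets a 21-nt register
# and the tasiARFs fall in phases D7(+)/D8(+) counted from that anchor.

#' Find miR390 complementary sites on a transcript
#'
#' Delegates to \code{\link{findSites}} with an elevated default cutoff:
#' miR390 sites tolerate more mispairing than cleavable sites (one of the
#' two TAS3 sites is typically non-cleavable).
#'
#' @param transcript One-row record (id + sequence) or character sequence.
#' @param mir390 miR390 sequence, 5'->3' (20-21 nt).
#' @param cutoff Score cutoff (default 4.0).
#' @param max_gaps Indels per site (default 1).
#' @return List of \linkS4class{TargetSite} ordered 5'->3' on the transcript.
#' @export
findMir390Sites <- function(transcript, mir390, cutoff = 4.0, max_gaps = 1L) {
    sites <- findSites(mir390, transcript, cutoff = cutoff,
                       max_gaps = max_gaps)
    sites[order(vapply(sites, function(s) s@start, 0L))]
}

#' Cleavage point of a target site
#'
#' The transcript coordinate of the phosphodiester bond opposite the
#' boundary between miRNA positions 10 and 11, encoded as the last
#' nucleotide of the 5' cleavage fragment (the bond cleaved is
#' anchor|anchor+1).
#'
#' @param site A \linkS4class{TargetSite} of length >= 11.
#' @return Integer transcript coordinate.
#' @export
cleavagePoint <- function(site) {
    stopifnot(is(site, "TargetSite"))
    if (site@end - site@start + 1L < 11L)
        stop("site too short to hold the position 10/11 boundary")
    site@end - 10L
}

#' Enumerate phase windows from a cleavage anchor
#'
#' D1 starts at the first nucleotide past the anchor in the given direction;
#' consecutive windows abut without gap or overlap.
#'
#' @param anchor Cleavage anchor (last nucleotide of the 5' fragment; the
#'   cleaved bond is anchor|anchor+1).
#' @param direction \code{"toward_five_prime"} (the TAS3 geometry from the
#'   3' site) or \code{"toward_three_prime"}.
#' @param n Number of windows requested (>= 1).
#' @param phase_length Window length in nt (default 21).
#' @param transcript_length Optional; windows extending outside
#'   \code{[1, transcript_length]} are dropped and flagged.
#' @return A \linkS4class{PhaseRegister}.
#' @export
enumeratePhases <- function(anchor, direction = c("toward_five_prime",
                                                  "toward_three_prime"),
                            n, phase_length = 21L,
                            transcript_length = NULL) {
    direction <- match.arg(direction)
    stopifnot(n >= 1L)
    anchor <- as.integer(anchor)
    phase_length <- as.integer(phase_length)
    k <- seq_len(n)
    if (direction == "toward_five_prime") {
        starts <- anchor - phase_length * k + 1L
        ends <- anchor - phase_length * (k - 1L)
    } else {
        starts <- anchor + phase_length * (k - 1L) + 1L
        ends <- anchor + phase_length * k
    }
    ok <- starts >= 1L
    if (!is.null(transcript_length)) ok <- ok & ends <= transcript_length
    truncated <- !all(ok)
    w <- IRanges::IRanges(start = starts[ok], end = ends[ok],
                          names = paste0("D", k[ok]))
    new("PhaseRegister", anchor = anchor, direction = direction,
        phaseLength = phase_length, windows = w, truncated = truncated)
}

# Hamming scan of every window of `width` in tseq against one reference.
scanHomologous <- function(tseq, ref, max_mm) {
    tb <- splitBases(tseq)
    rb <- splitBases(ref)
    L <- length(rb)
    n <- length(tb)
    if (n < L) return(integer())
    hits <- integer()
    for (s in seq_len(n - L + 1L)) {
        if (sum(tb[s:(s + L - 1L)] != rb) <= max_mm) hits <- c(hits, s)
    }
    hits
}

#' Annotate the TAS3 architecture of a transcript
#'
#' Finds miR390 complementary sites, locates tasiARF-homologous 21-mers
#' (at most \code{max_mm} mismatches against the supplied references),
#' computes each 21-mer's phase index in the register anchored at the
#' cleavage point of the anchoring miR390 site, and grades the
#' architecture: \code{full} when two adjacent in-register tasiARF windows
#' lie strictly between dual sites, \code{partial} when tasiARFs are found
#' but the dual-site requirement cannot be met (e.g. a truncated contig),
#' \code{fail} otherwise.
#'
#' @param transcript One-row record (id + sequence) or character sequence.
#' @param mir390 miR390 sequence 5'->3'.
#' @param tasiarf_refs Character vector of reference tasiARF 21-mers (or
#'   records with a \code{sequence} column).
#' @param max_mm Mismatch tolerance for tasiARF homology (default 3).
#' @param site_cutoff miR390 site score cutoff (default 4.0).
#' @param anchor \code{"three_prime"} (default; phases counted from the 3'
#'   site toward the 5' site) or \code{"five_prime"} (counted from the 5'
#'   site toward the 3' end) -- the D-register naming convention in the
#'   literature varies.
#' @param sites Optional precomputed miR390 sites.
#' @return A \linkS4class{TAS3Annotation}.
#' @export
assignTasiarfPhases <- function(transcript, mir390, tasiarf_refs,
                                max_mm = 3L, site_cutoff = 4.0,
                                anchor = c("three_prime", "five_prime"),
                                sites = NULL) {
    anchor <- match.arg(anchor)
    if (is.data.frame(transcript)) {
        tid <- transcript$id[1L]
        tseq <- normalizeRna(transcript$sequence[1L])
    } else {
        tid <- "transcript"
        tseq <- normalizeRna(transcript)
    }
    if (is.data.frame(tasiarf_refs)) tasiarf_refs <- tasiarf_refs$sequence
    tasiarf_refs <- normalizeRna(tasiarf_refs)
    if (is.null(sites)) sites <- findMir390Sites(tseq, mir390, site_cutoff)

    # tasiARF-homologous 21-mers: per start, best (fewest-mismatch) reference
    found <- list()
    for (ri in seq_along(tasiarf_refs)) {
        ref <- tasiarf_refs[ri]
        for (s in scanHomologous(tseq, ref, max_mm)) {
            mm <- hammingDistance(substr(tseq, s, s + nchar(ref) - 1L), ref)
            key <- as.character(s)
            if (is.null(found[[key]]) || mm < found[[key]]$mm)
                found[[key]] <- list(start = s, ref = ri, mm = mm,
                                     width = nchar(ref))
        }
    }

    five_site <- list(); three_site <- list()
    if (length(sites) >= 2L) {
        five_site <- sites[1L]
        three_site <- sites[length(sites)]
    } else if (length(sites) == 1L) {
        if (anchor == "three_prime") three_site <- sites[1L]
        else five_site <- sites[1L]
    }

    phase_len <- 21L
    anchorPos <- NA_integer_
    if (anchor == "three_prime" && length(three_site))
        anchorPos <- cleavagePoint(three_site[[1L]])
    if (anchor == "five_prime" && length(five_site))
        anchorPos <- cleavagePoint(five_site[[1L]])

    rows <- lapply(found, function(f) {
        s <- f$start; e <- s + f$width - 1L
        phase <- NA_integer_; offset <- NA_integer_
        if (!is.na(anchorPos)) {
            if (anchor == "three_prime") {
                d <- anchorPos + 1L - s          # Dk starts at anchor-21k+1
            } else {
                d <- e - anchorPos                # Dk ends at anchor+21k
            }
            offset <- as.integer(d %% phase_len)
            if (offset == 0L && d > 0L) phase <- as.integer(d %/% phase_len)
        }
        data.frame(start = s, end = e, ref = f$ref, mismatches = f$mm,
                   phase = phase, offset = offset)
    })
    tasiarf <- if (length(rows)) do.call(rbind, rows)
               else data.frame(start = integer(), end = integer(),
                               ref = integer(), mismatches = integer(),
                               phase = integer(), offset = integer())
    tasiarf <- tasiarf[order(tasiarf$start), , drop = FALSE]
    rownames(tasiarf) <- NULL

    verdict <- "fail"
    inreg <- tasiarf[!is.na(tasiarf$phase), , drop = FALSE]
    if (length(five_site) && length(three_site)) {
        between <- inreg[inreg$start > five_site[[1L]]@end &
                         inreg$end < three_site[[1L]]@start, , drop = FALSE]
        phs <- sort(unique(between$phase))
        if (length(phs) >= 2L && any(diff(phs) == 1L)) verdict <- "full"
        else if (nrow(tasiarf)) verdict <- "fail"
    } else if (nrow(tasiarf)) {
        verdict <- "partial"
    }

    new("TAS3Annotation", transcriptId = tid, fivePrimeSite = five_site,
        threePrimeSite = three_site, tasiarf = tasiarf, verdict = verdict)
}

#' Count tasiARF complementary sites per transcript
#'
#' ARF3/ARF4-like mRNAs carry two tasiARF recognition sites; this reports
#' the per-transcript site count under the cutoff and flags the dual-site
#' transcripts.
#'
#' @param tasiarf tasiARF sequence, 5'->3'.
#' @param transcripts data.frame of transcript records (id + sequence).
#' @param cutoff Score cutoff (default 3.5).
#' @param max_gaps Indels per site (default 1).
#' @return data.frame: \code{transcript}, \code{n_sites}, \code{scores}
#'   (comma-separated, best first), \code{dual_site} flag.
#' @export
findTasiarfTargets <- function(tasiarf, transcripts, cutoff = 3.5,
                               max_gaps = 1L) {
    out <- lapply(seq_len(nrow(transcripts)), function(j) {
        sites <- findSites(tasiarf, transcripts[j, ], cutoff = cutoff,
                           max_gaps = max_gaps)
        sc <- vapply(sites, siteScore, 0)
        data.frame(transcript = transcripts$id[j], n_sites = length(sites),
                   scores = paste(format(sc, trim = TRUE), collapse = ","),
                   dual_site = length(sites) == 2L)
    })
    do.call(rbind, out)
}
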