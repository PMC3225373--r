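#' @import methods
#' @importFrom stats setNames rbinom runif
#' @importFrom utils head read.delim write.table
NULL

#' SRNALibrary: a de-duplicated small-RNA library with filter accounting
#'
#' Holds the unique insert sequences of one sequencing library together with
#' their read counts and the bookkeeping of the filtering cascade that
#' produced them (raw reads, adapter-recognized reads, filtered reads, and
#' per-filter removal counts attributed to the first failing filter).
#'
#' @slot label Library label, e.g. \code{"juvenile"} or \code{"adult"}.
#' @slot sequences Character vector of unique RNA-alphabet sequences.
#' @slot counts Integer read count per sequence (same order as
#'   \code{sequences}).
#' @slot stats Named list with elements \code{raw_reads},
#'   \code{adapter_removed_reads}, \code{filtered_reads},
#'   \code{unique_sequences}, \code{artifacts} (adapter artifact counts,
#'   accounting for raw minus adapter-removed) and \code{removed} (named
#'   integer vector of post-adapter per-filter removal counts, summing to
#'   adapter-removed minus filtered).
#'
#' @export
setClass("SRNALibrary",
    representation(
        label = "character",
        sequences = "character",
        counts = "integer",
        stats = "list"
    ),
    prototype(label = NA_character_, sequences = character(), counts = integer(),
              stats = list())
)

setValidity("SRNALibrary", function(object) {
    msg <- character()
    if (length(object@sequences) != length(object@counts))
        msg <- c(msg, "sequences and counts differ in length")
    if (anyDuplicated(object@sequences))
        msg <- c(msg, "sequences must be unique within a library")
    if (length(object@counts) && any(object@counts < 0L))
        msg <- c(msg, "counts must be non-negative")
    st <- object@stats
    if (length(st)) {
        if (!is.null(st$filtered_reads) &&
            st$filtered_reads != sum(object@counts))
            msg <- c(msg, "stats$filtered_reads must equal the sum of counts")
        if (!is.null(st$unique_sequences) &&
            st$unique_sequences != length(object@sequences))
            msg <- c(msg, "stats$unique_sequences must equal the number of entries")
        if (!is.null(st$removed) && !is.null(st$adapter_removed_reads) &&
            !is.null(st$filtered_reads) &&
            sum(st$removed) != st$adapter_removed_reads - st$filtered_reads)
            msg <- c(msg, "removal counts must close the accounting exactly")
    }
    if (length(msg)) msg else TRUE
})

#' TargetSite: a scored miRNA/transcript complementarity site
#'
#' One alignment of a miRNA (5'->3') against the reverse complement of a
#' transcript window, with the per-position pairing states and the
#' position-weighted penalty score.
#'
#' @slot mirna miRNA sequence, 5'->3', RNA alphabet.
#' @slot transcriptId Identifier of the target transcript.
#' @slot start,end 1-based closed interval of the site on the transcript.
#' @slot states data.frame with columns \code{state} (one of \code{match},
#'   \code{mismatch}, \code{GU}, \code{gap_in_mirna}, \code{gap_in_target})
#'   and \code{mir_pos} (the miRNA position, from the 5' end, each state is
#'   charged to).
#' @slot score Non-negative penalty score (half-integers when gap-free).
#'
#' @export
setClass("TargetSite",
    representation(
        mirna = "character",
        transcriptId = "character",
        start = "integer",
        end = "integer",
        states = "data.frame",
        score = "numeric"
    )
)

setValidity("TargetSite", function(object) {
    msg <- character()
    if (object@score < 0) msg <- c(msg, "score must be >= 0")
    if (object@end < object@start) msg <- c(msg, "end must be >= start")
    L <- nchar(object@mirna)
    if (abs((object@end - object@start + 1L) - L) > 2L)
        msg <- c(msg, "site length must be within +/-2 of the miRNA length")
    if (!all(c("state", "mir_pos") %in% names(object@states)))
        msg <- c(msg, "states needs columns state and mir_pos")
    if (length(msg)) msg else TRUE
})

#' PrecursorWindow: transcript window around a candidate miRNA
#'
#' @slot transcriptId Transcript identifier.
#' @slot start,end 1-based closed window coordinates on the transcript.
#' @slot sequence Window sequence (RNA alphabet).
#' @slot srnaStart,srnaEnd Position of the candidate sRNA inside the window
#'   (1-based, relative to the window).
#' @slot truncated TRUE when a flank had to be clipped at a transcript end.
#'
#' @export
setClass("PrecursorWindow",
    representation(
        transcriptId = "character",
        start = "integer",
        end = "integer",
        sequence = "character",
        srnaStart = "integer",
        srnaEnd = "integer",
        truncated = "logical"
    )
)

setValidity("PrecursorWindow", function(object) {
    msg <- character()
    if (nchar(object@sequence) != object@end - object@start + 1L)
        msg <- c(msg, "sequence length must match the window coordinates")
    if (object@srnaStart < 1L || object@srnaEnd > nchar(object@sequence))
        msg <- c(msg, "the sRNA must lie inside the window")
    if (length(msg)) msg else TRUE
})

#' HairpinCandidate: a folded precursor window with its stem-loop verdict
#'
#' @slot window A \linkS4class{PrecursorWindow}.
#' @slot structure Dot-bracket string, same length as the window sequence.
#' @slot energyScore Folding score (arbitrary units, lower = more stable;
#'   minus the total base-pair weight under the default backend).
#' @slot arm \code{"5p"}, \code{"3p"} or \code{NA} (miRNA arm of the stem).
#' @slot starStart,starEnd Predicted miRNA* coordinates within the window
#'   (NA when the miRNA is unpaired).
#' @slot duplexStats Named list: \code{n_unpaired_mirna_bases},
#'   \code{max_asymmetric_bulge}, \code{loop_overlap}, \code{null_mean}
#'   (mean energy of dinucleotide-shuffled windows).
#' @slot verdict \code{"PASS"} or \code{"FAIL"}.
#' @slot failed Character vector naming the failed criteria (empty on PASS).
#'
#' @export
setClass("HairpinCandidate",
    representation(
        window = "PrecursorWindow",
        structure = "character",
        energyScore = "numeric",
        arm = "character",
        starStart = "integer",
        starEnd = "integer",
        duplexStats = "list",
        verdict = "character",
        failed = "character"
    )
)

setValidity("HairpinCandidate", function(object) {
    msg <- character()
    if (nchar(object@structure) != nchar(object@window@sequence))
        msg <- c(msg, "structure length must equal sequence length")
    n_open <- lengths(regmatches(object@structure, gregexpr("\\(", object@structure)))
    n_close <- lengths(regmatches(object@structure, gregexpr("\\)", object@structure)))
    if (n_open != n_close) msg <- c(msg, "unbalanced brackets in structure")
    if (!object@verdict %in% c("PASS", "FAIL"))
        msg <- c(msg, "verdict must be PASS or FAIL")
    if (object@verdict == "PASS" && length(object@failed))
        msg <- c(msg, "a PASS verdict cannot carry failed criteria")
    if (length(msg)) msg else TRUE
})

#' PhaseRegister: cleavage-anchored 21-nt phase windows
#'
#' Consecutive, non-overlapping windows D1..Dn counted from a miRNA-guided
#' cleavage anchor, either toward the transcript 5' end (the usual TAS3
#' geometry, anchored at the 3' miR390 site) or toward the 3' end.
#'
#' @slot anchor Transcript coordinate of the cleaved phosphodiester bond,
#'   encoded as the last nucleotide of the 5' cleavage fragment.
#' @slot direction \code{"toward_five_prime"} or \code{"toward_three_prime"}.
#' @slot phaseLength Window length in nt (21 for DCL4 products).
#' @slot windows \link[IRanges]{IRanges} named D1..Dn.
#' @slot truncated TRUE when windows past the transcript end were dropped.
#'
#' @export
setClass("PhaseRegister",
    representation(
        anchor = "integer",
        direction = "character",
        phaseLength = "integer",
        windows = "IRanges",
        truncated = "logical"
    )
)

setValidity("PhaseRegister", function(object) {
    msg <- character()
    if (!object@direction %in% c("toward_five_prime", "toward_three_prime"))
        msg <- c(msg, "unknown direction")
    w <- object@windows
    if (length(w)) {
        if (any(IRanges::width(w) != object@phaseLength))
            msg <- c(msg, "all windows must have width phaseLength")
        if (length(w) > 1L) {
            s <- sort(IRanges::start(w))
            if (any(diff(s) != object@phaseLength))
                msg <- c(msg, "windows must tile without gap or overlap")
        }
    }
    if (length(msg)) msg else TRUE
})

#' TAS3Annotation: dual miR390 site architecture and tasiARF phases
#'
#' @slot transcriptId Transcript identifier.
#' @slot fivePrimeSite,threePrimeSite \linkS4class{TargetSite} lists of
#'   length 0 or 1 (a site may be absent on truncated contigs).
#' @slot tasiarf data.frame of tasiARF-homologous 21-mers: columns
#'   \code{start}, \code{end}, \code{ref}, \code{mismatches}, \code{phase}
#'   (integer index, NA when off-register), \code{offset} (nt remainder
#'   modulo the phase length).
#' @slot verdict \code{"full"}, \code{"partial"} or \code{"fail"}.
#'
#' @export
setClass("TAS3Annotation",
    representation(
        transcriptId = "character",
        fivePrimeSite = "list",
        threePrimeSite = "list",
        tasiarf = "data.frame",
        verdict = "character"
    )
)

setValidity("TAS3Annotation", function(object) {
    msg <- character()
    if (!object@verdict %in% c("full", "partial", "fail"))
        msg <- c(msg, "verdict must be full, partial or fail")
    if (object@verdict == "full") {
        if (!length(object@fivePrimeSite) || !length(object@threePrimeSite))
            msg <- c(msg, "a full verdict requires both miR390 sites")
    }
    if (length(msg)) msg else TRUE
})

#' CleavageMap: RACE clone 5'-end positions in duplex coordinates
#'
#' @slot transcriptId Transcript identifier.
#' @slot site The \linkS4class{TargetSite} the map is expressed against.
#' @slot positions data.frame with columns \code{tx_pos} (transcript
#'   coordinate of the clone 5' end), \code{label} (duplex coordinate such
#'   as \code{"10/11"}, or \code{"upstream 11 nt"}), \code{count}.
#' @slot unmapped Number of clones that could not be placed on the transcript.
#'
#' @export
setClass("CleavageMap",
    representation(
        transcriptId = "character",
        site = "TargetSite",
        positions = "data.frame",
        unmapped = "integer"
    )
)

setValidity("CleavageMap", function(object) {
    msg <- character()
    need <- c("tx_pos", "label", "count")
    if (!all(need %in% names(object@positions)))
        msg <- c(msg, "positions needs columns tx_pos, label, count")
    if (length(msg)) msg else TRUE
})

#' MiRNAMatch: one homology assignment of an sRNA to a mature miRNA
#'
#' @slot query Query sRNA sequence.
#' @slot family Family token of the best reference (e.g. \code{"miR159"};
#'   star strands keep their printed \code{"*"} suffix).
#' @slot reference Canonical mature sequence matched against.
#' @slot nInternalMismatches Substitutions inside the overlapped region.
#' @slot fivePrimeOffset,threePrimeOffset Signed end offsets (positive =
#'   extension beyond the canonical end, negative = truncation).
#' @slot isStar TRUE when the reference is a star strand.
#'
#' @export
setClass("MiRNAMatch",
    representation(
        query = "character",
        family = "character",
        reference = "character",
        nInternalMismatches = "integer",
        fivePrimeOffset = "integer",
        threePrimeOffset = "integer",
        isStar = "logical"
    )
)
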