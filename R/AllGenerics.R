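#' Accessors for workflow objects
#'
#' Small accessor generics for the S4 containers: library label, unique
#' sequences and counts, filter statistics, read totals, site coordinates
#' and scores, and verdicts.
#'
#' @param object An object of the documented classes.
#' @return The slot value; \code{totalReads} and \code{nUnique} return single
#'   integers.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("libLabel", function(object) standardGeneric("libLabel"))
#' @rdname accessors
#' @export
setGeneric("libSequences", function(object) standardGeneric("libSequences"))
#' @rdname accessors
#' @export
setGeneric("libCounts", function(object) standardGeneric("libCounts"))
#' @rdname accessors
#' @export
setGeneric("libStats", function(object) standardGeneric("libStats"))
#' @rdname accessors
#' @export
setGeneric("totalReads", function(object) standardGeneric("totalReads"))
#' @rdname accessors
#' @export
setGeneric("nUnique", function(object) standardGeneric("nUnique"))
#' @rdname accessors
#' @export
setGeneric("siteScore", function(object) standardGeneric("siteScore"))
#' @rdname accessors
#' @export
setGeneric("siteRange", function(object) standardGeneric("siteRange"))
#' @rdname accessors
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))
#' @rdname accessors
#' @export
setGeneric("phaseWindows", function(object) standardGeneric("phaseWindows"))

#' @rdname accessors
setMethod("libLabel", "SRNALibrary", function(object) object@label)
#' @rdname accessors
setMethod("libSequences", "SRNALibrary", function(object) object@sequences)
#' @rdname accessors
setMethod("libCounts", "SRNALibrary",
    function(object) setNames(object@counts, object@sequences))
#' @rdname accessors
setMethod("libStats", "SRNALibrary", function(object) object@stats)
#' @rdname accessors
setMethod("totalReads", "SRNALibrary", function(object) sum(object@counts))
#' @rdname accessors
setMethod("nUnique", "SRNALibrary", function(object) length(object@sequences))

#' @rdname accessors
setMethod("siteScore", "TargetSite", function(object) object@score)
#' @rdname accessors
setMethod("siteRange", "TargetSite",
    function(object) IRanges::IRanges(object@start, object@end,
                                      names = object@transcriptId))
#' @rdname accessors
setMethod("verdict", "HairpinCandidate", function(object) object@verdict)
#' @rdname accessors
setMethod("verdict", "TAS3Annotation", function(object) object@verdict)
#' @rdname accessors
setMethod("phaseWindows", "PhaseRegister", function(object) object@windows)

setMethod("show", "SRNALibrary", function(object) {
    st <- object@stats
    cat("SRNALibrary '", object@label, "': ", length(object@sequences),
        " unique sequences, ", sum(object@counts), " reads\n", sep = "")
    if (length(st)) {
        cat("  raw: ", st$raw_reads, "  adapter-removed: ",
            st$adapter_removed_reads, "  filtered: ", st$filtered_reads,
            "\n", sep = "")
        if (!is.null(st$artifacts) && sum(st$artifacts))
            cat("  adapter artifacts: ",
                paste(names(st$artifacts), st$artifacts, sep = "=",
                      collapse = ", "), "\n", sep = "")
        if (!is.null(st$removed) && length(st$removed))
            cat("  removed by filter: ",
                paste(names(st$removed), st$removed, sep = "=",
                      collapse = ", "), "\n", sep = "")
    }
})

setMethod("show", "TargetSite", function(object) {
    cat("TargetSite ", object@transcriptId, ":", object@start, "-",
        object@end, "  score=", format(object@score), "\n", sep = "")
    cat("  miRNA 5'->3': ", object@mirna, "\n", sep = "")
})

setMethod("show", "HairpinCandidate", function(object) {
    cat("HairpinCandidate on ", object@window@transcriptId, " [",
        object@window@start, "-", object@window@end, "]  verdict: ",
        object@verdict, "\n", sep = "")
    if (length(object@failed))
        cat("  failed: ", paste(object@failed, collapse = ", "), "\n", sep = "")
    cat("  energy score: ", format(object@energyScore), " (shuffle-null mean ",
        format(object@duplexStats$null_mean), ")\n", sep = "")
})

setMethod("show", "PhaseRegister", function(object) {
    cat("PhaseRegister: anchor after position ", object@anchor, ", ",
        sub("_", " ", object@direction), ", ", length(object@windows),
        " x ", object@phaseLength, "-nt windows\n", sep = "")
})

setMethod("show", "TAS3Annotation", function(object) {
    cat("TAS3Annotation ", object@transcriptId, ": verdict ", object@verdict,
        "\n  miR390 sites: 5'=", length(object@fivePrimeSite) > 0,
        " 3'=", length(object@threePrimeSite) > 0,
        "; tasiARF windows: ", nrow(object@tasiarf), "\n", sep = "")
})

setMethod("show", "CleavageMap", function(object) {
    cat("CleavageMap on ", object@transcriptId, ": ",
        sum(object@positions$count), " mapped clones at ",
        nrow(object@positions), " position(s), ", object@unmapped,
        " unmapped\n", sep = "")
})

setMethod("show", "MiRNAMatch", function(object) {
    cat("MiRNAMatch: ", object@query, " -> ", object@family,
        " (mm=", object@nInternalMismatches, ", 5'=",
        sprintf("%+d", object@fivePrimeOffset), ", 3'=",
        sprintf("%+d", object@threePrimeOffset), ")\n", sep = "")
})
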