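#' Read a multi-record FASTA file into sequence records
#'
#' Parsing is delegated to \code{\link[Biostrings]{readBStringSet}} after a
#' light line-level validation pass so that malformed input is rejected with
#' the offending line number. Sequences are upper-cased; with
#' \code{as_rna = TRUE} (the default) T is folded into U so that DNA adapters
#' and RNA reads live on one alphabet.
#'
#' @param path Path to a FASTA file.
#' @param as_rna Normalize T to U (default TRUE).
#' @return A data.frame with columns \code{id}, \code{sequence},
#'   \code{description} (text after the first whitespace in the header,
#'   \code{""} when absent), one row per record, input order preserved.
#' @export
readFastaRecords <- function(path, as_rna = TRUE) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    nonempty <- which(nzchar(trimws(lines)))
    if (!length(nonempty)) stop("FASTA parse error at line 1: empty file")
    if (!startsWith(trimws(lines[nonempty[1L]]), ">"))
        stop("FASTA parse error at line ", nonempty[1L],
             ": expected a '>' header")
    hdr <- which(startsWith(trimws(lines), ">"))
    for (i in seq_along(hdr)) {
        h <- hdr[i]
        if (!nzchar(sub("^>", "", trimws(lines[h]))))
            stop("FASTA parse error at line ", h, ": empty header")
        upto <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
        body <- lines[seq(h + 1L, length.out = max(0L, upto - h))]
        if (!any(nzchar(trimws(body))))
            stop("FASTA parse error at line ", h,
                 ": record with empty sequence")
    }
    set <- Biostrings::readBStringSet(path)
    full <- names(set)
    id <- sub("\\s.*$", "", full)
    desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
    dup <- anyDuplicated(id)
    if (dup) stop("duplicate FASTA id: ", id[dup])
    seqs <- toupper(as.character(set))
    if (as_rna) seqs <- chartr("T", "U", seqs)
    data.frame(id = id, sequence = unname(seqs), description = desc,
               stringsAsFactors = FALSE)
}

#' Read a small-RNA count table
#'
#' Expects a TSV whose header is \code{sequence, length, family} followed by
#' one column per library. The count cell \code{"N"} marks a sequence that
#' was detected by northern blot only: it is parsed as count 0 with the
#' \code{northern_only} flag set.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns \code{sequence}, \code{length},
#'   \code{family}, \code{northern_only}, then one integer count column per
#'   library. The attribute \code{"libraries"} names the library columns.
#' @export
readCountTable <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = "character", check.names = FALSE)
    need <- c("sequence", "length", "family")
    if (!all(need %in% names(tab)))
        stop("count table must have columns sequence, length, family")
    libs <- setdiff(names(tab), need)
    if (!length(libs)) stop("count table names no library columns")
    tab$sequence <- normalizeRna(tab$sequence)
    tab$length <- as.integer(tab$length)
    bad <- which(tab$length != nchar(tab$sequence))
    if (length(bad))
        stop("length column disagrees with sequence length at row ", bad[1L],
             " (", tab$sequence[bad[1L]], ")")
    northern <- rep(FALSE, nrow(tab))
    for (lb in libs) {
        isN <- tab[[lb]] == "N"
        northern <- northern | isN
        tab[[lb]][isN] <- "0"
        cnt <- suppressWarnings(as.integer(tab[[lb]]))
        if (anyNA(cnt)) stop("non-numeric count in library column ", lb)
        if (any(cnt < 0L)) stop("negative count in library column ", lb)
        tab[[lb]] <- cnt
    }
    zero <- rowSums(as.matrix(tab[libs])) == 0L
    if (any(zero & !northern))
        stop("all-zero counts allowed only for northern-only rows (row ",
             which(zero & !northern)[1L], ")")
    out <- data.frame(sequence = tab$sequence, length = tab$length,
                      family = tab$family, northern_only = northern,
                      stringsAsFactors = FALSE, check.names = FALSE)
    for (lb in libs) out[[lb]] <- tab[[lb]]
    attr(out, "libraries") <- libs
    out
}

#' Write / re-read a tabular report
#'
#' Deterministic TSV output (columns in the given order, no quoting, no row
#' names) that round-trips through \code{readReportTsv}.
#'
#' @param table A data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeReportTsv <- function(table, path) {
    stopifnot(is.data.frame(table))
    write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    invisible(path)
}

#' @rdname writeReportTsv
#' @export
readReportTsv <- function(path) {
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read an adapter configuration
#'
#' YAML with keys \code{three_prime} (DNA string), \code{five_prime_variants}
#' (list of DNA strings) and \code{min_anchor} (integer). Adapters are
#' normalized to the RNA alphabet; every adapter must be at least
#' \code{min_anchor} long and \code{min_anchor} at least 6.
#'
#' @param path Path to the YAML file, or NULL for the packaged 454-style
#'   default.
#' @return A list with elements \code{three_prime}, \code{five_prime_variants}
#'   and \code{min_anchor}.
#' @export
readAdapterConfig <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "adapters.yml", package = "oliveSRNA",
                            mustWork = TRUE)
    cfg <- yaml::read_yaml(path)
    cfg$three_prime <- normalizeRna(cfg$three_prime)
    cfg$five_prime_variants <- normalizeRna(unlist(cfg$five_prime_variants))
    cfg$min_anchor <- as.integer(cfg$min_anchor)
    if (cfg$min_anchor < 6L) stop("min_anchor must be at least 6")
    lens <- nchar(c(cfg$three_prime, cfg$five_prime_variants))
    if (any(lens < cfg$min_anchor))
        stop("all adapters must be at least min_anchor bases long")
    cfg
}

#' Packaged fixtures
#'
#' \code{knownMirnaCountTable} loads the packaged count table of known-miRNA
#' sequence and length polymorphisms in the juvenile and adult olive shoot
#' libraries; \code{matureMirnaReferences} loads the matching canonical
#' mature reference set (one most-abundant sequence per family, two members
#' for the divergent miR482 family), with the family token in the
#' \code{family} column.
#'
#' @return A data.frame (see \code{\link{readCountTable}} and
#'   \code{\link{readFastaRecords}}).
#' @export
knownMirnaCountTable <- function() {
    readCountTable(system.file("extdata", "known_mirna_variants.tsv",
                               package = "oliveSRNA", mustWork = TRUE))
}

#' @rdname knownMirnaCountTable
#' @export
matureMirnaReferences <- function() {
    recs <- readFastaRecords(system.file("extdata", "mature_mirna_refs.fa",
                                         package = "oliveSRNA",
                                         mustWork = TRUE))
    recs$family <- ifelse(nzchar(recs$description), recs$description, recs$id)
    recs
}
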