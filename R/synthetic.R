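# Seeded synthetic inputs with the statistical structure the analysis
# assumes: two shoot libraries dominated by 24-nt reads, ncRNA degradation
# contamination (including >25-nt fragments), low-count conserved-miRNA
# variant blocks planted at fixed per-library abundances, plus structured
# loci (hairpin precursor, TAS3, ARF) with recorded ground truth.

#' Default planted miRNA block
#'
#' The default variant spectrum mirrors the most sequence-rich conserved
#' family in the two shoot libraries: one canonical 21-mer at high juvenile
#' abundance, several internal-mismatch variants and several 5'/3' length
#' variants, all at fixed per-library counts.
#'
#' @return data.frame with columns \code{sequence}, \code{family} and one
#'   count column per library.
#' @export
defaultPlantedMirnas <- function() {
    tab <- knownMirnaCountTable()
    block <- tab[tab$family == "miR159",
                 c("sequence", "family", attr(tab, "libraries"))]
    rownames(block) <- NULL
    block
}

#' Population configuration for the synthetic read generator
#'
#' Defaults transcribe the study conditions: 10,000 reads per library for
#' two libraries (juvenile/adult), a size distribution with 80 percent of
#' the mass on 24 nt (0.8 percent on 21 nt, 1.3 percent on 22 nt, the
#' 23-25 nt range carrying 96 percent), 35 percent ncRNA degradation
#' contamination, 2 percent adapter artifacts, and a 0.60 proportion of 5'
#' terminal A among 24-nt sequences.
#'
#' @param seed Integer master seed; every sub-generator derives its own
#'   child stream from it.
#' @param n_reads_per_library Reads per library before artifacts.
#' @param size_distribution Named probability vector over read lengths.
#' @param frac_ncrna_fragments Proportion of reads that are ncRNA
#'   degradation fragments.
#' @param frac_adapter_artifacts Proportion of adapter artifacts appended
#'   by \code{\link{generateRawReads}}.
#' @param planted_mirnas data.frame of planted rows (sequence, family, one
#'   count column per library), or NULL for none.
#' @param five_prime_A_bias_24nt P(5' A) for background 24-mers.
#' @param libraries Library labels.
#' @return A validated config list of class \code{PopulationConfig}.
#' @export
populationConfig <- function(seed = 1L,
                             n_reads_per_library = 10000L,
                             size_distribution = c(
                                 "18" = 0.003, "19" = 0.003, "20" = 0.003,
                                 "21" = 0.008, "22" = 0.013, "23" = 0.08,
                                 "24" = 0.80, "25" = 0.08, "26" = 0.0034,
                                 "27" = 0.0033, "28" = 0.0033),
                             frac_ncrna_fragments = 0.35,
                             frac_adapter_artifacts = 0.02,
                             planted_mirnas = defaultPlantedMirnas(),
                             five_prime_A_bias_24nt = 0.60,
                             libraries = c("juvenile", "adult")) {
    if (abs(sum(size_distribution) - 1) > 1e-9)
        stop("size_distribution probabilities must sum to 1")
    for (p in c(frac_ncrna_fragments, frac_adapter_artifacts,
                five_prime_A_bias_24nt))
        if (p < 0 || p > 1) stop("proportions must lie in [0, 1]")
    if (n_reads_per_library < 1L) stop("zero reads requested")
    cfg <- list(seed = as.integer(seed),
                n_reads_per_library = as.integer(n_reads_per_library),
                size_distribution = size_distribution,
                frac_ncrna_fragments = frac_ncrna_fragments,
                frac_adapter_artifacts = frac_adapter_artifacts,
                planted_mirnas = planted_mirnas,
                five_prime_A_bias_24nt = five_prime_A_bias_24nt,
                libraries = libraries)
    class(cfg) <- "PopulationConfig"
    cfg
}

# Synthetic ncRNA reference transcripts (degradation sources).
generateNcrnaRefs <- function(seed, n = 3L, length = 600L) {
    withSeed(childSeed(seed, 9901L), {
        data.frame(id = paste0(c("rRNA", "tRNA", "snoRNA")[seq_len(n)],
                               "_syn"),
                   sequence = randomRnaSequence(n, length),
                   description = "synthetic ncRNA reference")
    })
}

#' Generate a synthetic sRNA population with ground truth
#'
#' For each library: planted miRNA rows at their fixed configured counts,
#' background sRNA reads drawn from the size distribution (with the 5'A
#' bias on the 24-nt class), and ncRNA degradation fragments copied from
#' synthetic reference transcripts (lengths 18-35, so some exceed the DCL
#' size range). Background sequences colliding with the ncRNA references or
#' the planted set are re-sampled so that the recorded truth is exact. The
#' truth block predicts, per library, the outcome of the default filter
#' cascade (first-failing-filter attribution) and the surviving entries.
#'
#' @param config A \code{\link{populationConfig}}.
#' @return A list: \code{config}, \code{ncrna_refs}, and \code{libraries}
#'   (per label: \code{inserts} data.frame(sequence, count, category) and
#'   \code{truth} with \code{expected_stats}, \code{clean_entries},
#'   \code{category_reads}).
#' @export
generatePopulation <- function(config = populationConfig()) {
    stopifnot(inherits(config, "PopulationConfig"))
    ncrna_refs <- generateNcrnaRefs(config$seed)
    refseqs <- ncrna_refs$sequence
    planted <- config$planted_mirnas
    planted_seqs <- if (is.null(planted)) character() else planted$sequence

    inNcrna <- function(s) {
        rc <- reverseComplementRna(s)
        any(vapply(refseqs, function(r)
            grepl(s, r, fixed = TRUE) || grepl(rc, r, fixed = TRUE), TRUE))
    }

    libs <- lapply(seq_along(config$libraries), function(li) {
        lb <- config$libraries[li]
        withSeed(childSeed(config$seed, li), {
            n <- config$n_reads_per_library
            n_planted <- if (is.null(planted)) 0L else sum(planted[[lb]])
            n_nc <- rbinom(1L, n, config$frac_ncrna_fragments)
            n_bg <- n - n_nc - n_planted
            if (n_bg < 0L) stop("planted counts exceed the library size")

            lens <- sample(as.integer(names(config$size_distribution)),
                           n_bg, replace = TRUE,
                           prob = config$size_distribution)
            bias <- c(config$five_prime_A_bias_24nt,
                      rep((1 - config$five_prime_A_bias_24nt) / 3, 3))
            bg <- vapply(lens, function(L) {
                repeat {
                    s <- randomRnaSequence(1L, L,
                        first_base_prob = if (L == 24L)
                            c(A = bias[1L], C = bias[2L], G = bias[3L],
                              U = bias[4L]) else NULL)
                    if (!(s %in% planted_seqs) && !inNcrna(s)) return(s)
                }
            }, "")

            nc <- vapply(seq_len(n_nc), function(i) {
                L <- sample(18:35, 1L)
                ref <- refseqs[sample.int(length(refseqs), 1L)]
                s <- sample.int(nchar(ref) - L + 1L, 1L)
                substr(ref, s, s + L - 1L)
            }, "")

            rows <- list()
            if (n_planted > 0L)
                rows$planted <- data.frame(sequence = planted$sequence,
                                           count = planted[[lb]],
                                           category = "planted")
            if (n_bg > 0L) {
                t_bg <- table(bg)
                rows$background <- data.frame(sequence = names(t_bg),
                                              count = as.integer(t_bg),
                                              category = "background")
            }
            if (n_nc > 0L) {
                t_nc <- table(nc)
                rows$ncrna <- data.frame(sequence = names(t_nc),
                                         count = as.integer(t_nc),
                                         category = "ncrna")
            }
            inserts <- do.call(rbind, unname(rows))
            inserts <- inserts[inserts$count > 0L, , drop = FALSE]
            rownames(inserts) <- NULL

            # Truth: first-failing-filter attribution under default params
            len <- nchar(inserts$sequence)
            distinct <- vapply(strsplit(inserts$sequence, ""),
                               function(ch) length(unique(ch)), 1L)
            fate <- rep("keep", nrow(inserts))
            fate[len < 18L | len > 25L] <- "size"
            sel <- fate == "keep" & distinct < 3L
            fate[sel] <- "complexity"
            fate[fate == "keep" & inserts$category == "ncrna"] <- "ncrna"
            removed <- c(contains_n = 0L,
                         size = sum(inserts$count[fate == "size"]),
                         complexity = sum(inserts$count[fate == "complexity"]),
                         ncrna = sum(inserts$count[fate == "ncrna"]))
            keep <- inserts[fate == "keep", , drop = FALSE]
            agg <- tapply(keep$count, keep$sequence, sum)
            clean <- data.frame(sequence = names(agg),
                                count = as.integer(agg))
            clean <- clean[order(clean$sequence), , drop = FALSE]
            rownames(clean) <- NULL
            truth <- list(
                category_reads = tapply(inserts$count, inserts$category, sum),
                expected_stats = list(
                    raw_reads = sum(inserts$count),
                    adapter_removed_reads = sum(inserts$count),
                    filtered_reads = sum(clean$count),
                    unique_sequences = nrow(clean),
                    removed = removed),
                clean_entries = clean)
            list(inserts = inserts, truth = truth)
        })
    })
    names(libs) <- config$libraries
    list(config = config, ncrna_refs = ncrna_refs, libraries = libs)
}

#' Count table of the planted miRNA rows of a population
#'
#' @param population Output of \code{\link{generatePopulation}}.
#' @return A count table data.frame in the layout of
#'   \code{\link{readCountTable}}.
#' @export
plantedCountTable <- function(population) {
    planted <- population$config$planted_mirnas
    if (is.null(planted)) stop("no miRNAs were planted")
    libs <- population$config$libraries
    out <- data.frame(sequence = planted$sequence,
                      length = nchar(planted$sequence),
                      family = planted$family,
                      northern_only = FALSE)
    for (lb in libs) out[[lb]] <- planted[[lb]]
    attr(out, "libraries") <- libs
    out
}

#' Generate adapter-flanked raw reads for a library
#'
#' Every insert becomes 5' adapter + insert + 3' adapter (a 5' variant is
#' drawn per read). A configured fraction of artifact reads is appended:
#' adapter dimers with no insert and double-3'-adapter multimers, half and
#' half in expectation. The attribute \code{"truth"} records the artifact
#' counts.
#'
#' @param inserts data.frame(sequence, count) (e.g. one library of
#'   \code{\link{generatePopulation}}), or a character vector of inserts.
#' @param adapters Adapter configuration (\code{\link{readAdapterConfig}}).
#' @param frac_artifacts Artifact fraction (default 0.02).
#' @param seed Integer seed.
#' @return data.frame(id, sequence) of raw reads, shuffled, with attribute
#'   \code{"truth"} = list(n_no_insert, n_multimer).
#' @export
generateRawReads <- function(inserts, adapters, frac_artifacts = 0.02,
                             seed = 1L) {
    if (is.character(inserts))
        inserts <- data.frame(sequence = inserts,
                              count = rep(1L, length(inserts)))
    withSeed(childSeed(seed, 7L), {
        seqs <- rep(inserts$sequence, inserts$count)
        a5 <- adapters$five_prime_variants
        a3 <- adapters$three_prime
        reads <- paste0(a5[sample.int(length(a5), length(seqs),
                                      replace = TRUE)], seqs, a3)
        n_art <- rbinom(1L, length(seqs), frac_artifacts)
        art <- character(n_art)
        is_multimer <- logical(n_art)
        for (i in seq_len(n_art)) {
            v <- a5[sample.int(length(a5), 1L)]
            if (runif(1L) < 0.5) {
                art[i] <- paste0(v, a3)
            } else {
                art[i] <- paste0(v, randomRnaSequence(1L, 21L), a3, a3)
                is_multimer[i] <- TRUE
            }
        }
        all_reads <- c(reads, art)
        ord <- sample.int(length(all_reads))
        out <- data.frame(id = paste0("read_", seq_along(all_reads)),
                          sequence = all_reads[ord])
        attr(out, "truth") <- list(n_no_insert = sum(!is_multimer),
                                   n_multimer = sum(is_multimer))
        out
    })
}

#' Synthetic tasiARF reference 21-mer
#'
#' A fixed synthetic stand-in for the conserved ARF-targeting tasiRNA used
#' as the homology reference by the phasing module and the locus
#' generators. It is an invented sequence with a realistic base
#' composition, not a transcribed database entry.
#'
#' @return A 21-nt RNA string.
#' @export
tasiarfReference <- function() "UUCUUGACCUUGUAAGACCUU"

#' Generate a synthetic TAS3 locus with dual miR390 sites
#'
#' Transcript layout 5'->3': random flank, 5' miR390 complementary site,
#' spacer, tasiARF at phase D8 (one planted mismatch by default), tasiARF
#' at phase D7 (exact), spacer, 3' miR390 complementary site, random
#' flank. Phases are counted from the 3'-site cleavage point toward the 5'
#' site, so the planted tasiARFs occupy D7 and D8 with mismatch profile
#' (0, 1). Spacer lengths are chosen so the distance between the two
#' cleavage points is a multiple of 21 when \code{in_register} is TRUE.
#'
#' @param seed Integer seed for the random parts.
#' @param mir390 miR390 sequence 5'->3' (20-21 nt).
#' @param tasiarf Reference tasiARF 21-mer (default
#'   \code{\link{tasiarfReference}}).
#' @param flank Random flank length on each side (default 60).
#' @param d8_mismatch Plant one mismatch in the D8 copy (default TRUE).
#' @param in_register Make the inter-site cleavage distance = 0 mod 21
#'   (default TRUE).
#' @param tasiarf_shift Shift the tasiARF block off the register by this
#'   many nt (default 0; nonzero breaks phase recovery by construction).
#' @param second_site Plant the 5' site (default TRUE; FALSE gives the
#'   single-site negative control).
#' @return A list: \code{kind = "TAS3"}, \code{transcript} (one-row record)
#'   and \code{truth} (site and window coordinates, anchors).
#' @export
generateTas3Locus <- function(seed = 1L, mir390, tasiarf = tasiarfReference(),
                              flank = 60L, d8_mismatch = TRUE,
                              in_register = TRUE, tasiarf_shift = 0L,
                              second_site = TRUE) {
    mir390 <- normalizeRna(mir390)
    L390 <- nchar(mir390)
    if (L390 < 20L || L390 > 21L) stop("miR390 must be 20-21 nt")
    tasiarf <- normalizeRna(tasiarf)
    withSeed(childSeed(seed, 33L), {
        site <- reverseComplementRna(mir390)
        d7 <- tasiarf
        d8 <- tasiarf
        d8_pos <- NA_integer_
        if (d8_mismatch) {
            d8_pos <- 11L
            b <- substr(d8, d8_pos, d8_pos)
            substr(d8, d8_pos, d8_pos) <- setdiff(RNA_BASES, b)[sample.int(3L, 1L)]
        }
        gapA <- 11L + tasiarf_shift + if (in_register) 0L else 3L
        spacer2 <- 136L - L390 - tasiarf_shift
        if (gapA < 0L || spacer2 < 0L)
            stop("transcript too short to hold the phase register")
        site5 <- if (second_site) site else randomRnaSequence(1L, L390)
        parts <- c(randomRnaSequence(1L, flank), site5,
                   randomRnaSequence(1L, gapA), d8, d7,
                   randomRnaSequence(1L, spacer2), site,
                   randomRnaSequence(1L, flank))
        tx <- paste(parts, collapse = "")
        s5 <- flank + 1L
        e5 <- flank + L390
        d8_start <- e5 + gapA + 1L
        d7_start <- d8_start + 21L
        s3 <- d7_start + 21L + spacer2
        e3 <- s3 + L390 - 1L
        a3 <- e3 - 10L
        a5 <- e5 - 10L
        if (a3 - 21L * 8L < 1L)
            stop("transcript too short to hold 8 phases")
        list(kind = "TAS3",
             transcript = data.frame(id = "TAS3_syn", sequence = tx),
             truth = list(
                 five_prime_site = c(s5, e5), three_prime_site = c(s3, e3),
                 anchor_3p = a3, anchor_5p = a5,
                 D7 = c(d7_start, d7_start + 20L),
                 D8 = c(d8_start, d8_start + 20L),
                 tasiarf = tasiarf, d8_mismatch_at = d8_pos,
                 in_register = in_register, shift = tasiarf_shift,
                 second_site = second_site))
    })
}

#' Generate a synthetic hairpin-bearing transcript
#'
#' Embeds the miRNA in the 5' arm of a stem-loop (star arm = reverse
#' complement with \code{star_mismatches} planted substitutions, separated
#' by a short loop) inside random flanks. Attempt-and-verify construction:
#' random flanks are re-drawn (deterministically from the seed) until the
#' folded construct satisfies the structural duplex criteria, so the
#' planted locus is compliant by construction. With \code{span_loop} the
#' miRNA is instead placed across the terminal loop of a flank-paired stem,
#' a construction that must fail evaluation.
#'
#' @param mirna miRNA sequence (20-24 nt).
#' @param seed Integer seed.
#' @param flank Flank length on each side (default 50, within the 50-200
#'   window convention used for precursor folding).
#' @param loop_len Terminal loop length (default 8).
#' @param star_mismatches Substitutions planted in the star arm (default 0).
#' @param span_loop Build the loop-spanning negative control (default
#'   FALSE).
#' @return A list: \code{kind = "hairpin"}, \code{transcript}, and
#'   \code{truth} (miRNA/star/loop coordinates, attempt count).
#' @export
generateHairpinTranscript <- function(mirna, seed = 1L, flank = 50L,
                                      loop_len = 8L, star_mismatches = 0L,
                                      span_loop = FALSE) {
    mirna <- normalizeRna(mirna)
    L <- nchar(mirna)
    if (L < 20L || L > 24L) stop("miRNA must be 20-24 nt")
    withSeed(childSeed(seed, 55L), {
        if (span_loop) {
            stemlen <- 30L
            stem <- randomRnaSequence(1L, stemlen)
            tx <- paste0(randomRnaSequence(1L, flank), stem, mirna,
                         reverseComplementRna(stem),
                         randomRnaSequence(1L, flank))
            s <- flank + stemlen + 1L
            return(list(kind = "hairpin",
                        transcript = data.frame(id = "hairpin_syn",
                                                sequence = tx),
                        truth = list(mirna = c(s, s + L - 1L), star = NA,
                                     loop = c(s, s + L - 1L),
                                     span_loop = TRUE, attempts = 1L)))
        }
        star <- reverseComplementRna(mirna)
        if (star_mismatches > 0L) {
            pos <- sample.int(nchar(star), star_mismatches)
            for (p in pos) {
                b <- substr(star, p, p)
                substr(star, p, p) <- setdiff(RNA_BASES, b)[sample.int(3L, 1L)]
            }
        }
        for (attempt in seq_len(40L)) {
            loop <- randomRnaSequence(1L, loop_len)
            tx <- paste0(randomRnaSequence(1L, flank), mirna, loop, star,
                         randomRnaSequence(1L, flank))
            s <- flank + 1L
            e <- flank + L
            fold <- foldRna(tx)
            duplex <- findStar(fold$pairs, s, e)
            ok <- !is.null(duplex) && !duplex$loop_overlap &&
                duplex$n_unpaired <= 4L && duplex$max_asymmetric_bulge <= 2L
            if (ok)
                return(list(kind = "hairpin",
                            transcript = data.frame(id = "hairpin_syn",
                                                    sequence = tx),
                            truth = list(mirna = c(s, e),
                                         star = c(e + loop_len + 1L,
                                                  e + loop_len + nchar(star)),
                                         loop = c(e + 1L, e + loop_len),
                                         span_loop = FALSE,
                                         attempts = attempt)))
        }
        stop("no compliant hairpin construct found for this seed")
    })
}

#' Generate a synthetic ARF-like transcript with two tasiARF sites
#'
#' Plants two tasiARF complementary sites (one perfect, one with a single
#' non-core G:U wobble, scores 0 and 0.5) in a random transcript.
#'
#' @param seed Integer seed.
#' @param tasiarf tasiARF sequence (default \code{\link{tasiarfReference}}).
#' @param length Transcript length (default 400).
#' @return A list: \code{kind = "ARF"}, \code{transcript}, \code{truth}
#'   (site coordinates).
#' @export
generateArfLocus <- function(seed = 1L, tasiarf = tasiarfReference(),
                             length = 400L) {
    tasiarf <- normalizeRna(tasiarf)
    Lt <- nchar(tasiarf)
    withSeed(childSeed(seed, 77L), {
        site1 <- reverseComplementRna(tasiarf)
        site2 <- site1
        # single G:U at a non-core miRNA position (>= 14): target base
        # opposite tasiARF position k sits at site index Lt - k + 1
        k <- which(splitBases(tasiarf) %in% c("G", "U") &
                   seq_len(Lt) >= 14L)[1L]
        i <- Lt - k + 1L
        substr(site2, i, i) <- if (substr(tasiarf, k, k) == "G") "U" else "G"
        p1 <- 100L
        p2 <- 250L
        tx <- randomRnaSequence(1L, length)
        substr(tx, p1, p1 + Lt - 1L) <- site1
        substr(tx, p2, p2 + Lt - 1L) <- site2
        list(kind = "ARF",
             transcript = data.frame(id = "ARF_syn", sequence = tx),
             truth = list(site1 = c(p1, p1 + Lt - 1L),
                          site2 = c(p2, p2 + Lt - 1L),
                          wobble_mir_pos = k))
    })
}

#' Generate RACE clone 5'-end fragments for a target site
#'
#' Clones start at the nucleotide just past the cleavage point (the target
#' base opposite miRNA position 10); a configured fraction start at
#' off-positions within 3 nt of it.
#'
#' @param transcript One-row record (id + sequence) or character sequence.
#' @param site The guiding \linkS4class{TargetSite}.
#' @param n_clones Number of clones (>= 1).
#' @param noise Fraction of clones at off-positions (default 0).
#' @param seed Integer seed.
#' @param clone_length Clone extent downstream of its 5' end (default 120,
#'   clipped at the transcript end).
#' @return Character vector of clone sequences.
#' @export
generateRaceClones <- function(transcript, site, n_clones, noise = 0,
                               seed = 1L, clone_length = 120L) {
    if (n_clones < 1L) stop("n_clones must be at least 1")
    tseq <- if (is.data.frame(transcript))
        normalizeRna(transcript$sequence[1L]) else normalizeRna(transcript)
    p0 <- cleavagePoint(site) + 1L
    withSeed(childSeed(seed, 11L), {
        offs <- integer(n_clones)
        n_off <- rbinom(1L, n_clones, noise)
        if (n_off > 0L)
            offs[sample.int(n_clones, n_off)] <-
                sample(c(-3:-1, 1:3), n_off, replace = TRUE)
        vapply(offs, function(o) {
            p <- max(1L, p0 + o)
            substr(tseq, p, min(nchar(tseq), p + clone_length - 1L))
        }, "")
    })
}
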