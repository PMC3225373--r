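---
title: "Methods: small RNA annotation, homology and phasing in oliveSRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA annotation, homology and phasing in oliveSRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oliveSRNA)
```

This vignette is the package's account of its methods: the models and
procedures each stage implements, the parameters that matter and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the design choices made where the design was genuinely open.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The analysis problem

Deep-sequenced plant sRNA libraries are mixtures: DCL-derived silencing
RNAs of 18–25 nt (miRNAs, siRNAs, tasiRNAs) sit on top of degradation
fragments of abundant non-coding RNAs, adapter-ligation artifacts, and
low-complexity junk. For a species without a usable genome assembly, the
analysis must work from the reads and a cDNA collection alone:

1. clean and de-duplicate the reads with exact accounting,
2. profile the size classes (the 24-nt heterochromatic class is the
   diagnostic signature; its 5' adenosine bias points at AGO4 loading),
3. assign reads to known miRNA families by homology with explicit variant
   typing, since polymorphic ends cannot be resolved to gene loci,
4. evaluate candidate precursors by folding cDNA context around sRNA hits,
5. predict and validate targets through complementarity scoring and
   RACE-mapped cleavage positions, and
6. recognize the miR390/TAS3 two-hit architecture and its 21-nt phase
   register to tie tasiARFs to their precursors.

## Alphabet, coordinates and containers

All comparisons happen on the RNA alphabet; T is folded into U on ingest
(`readFastaRecords`, `readCountTable`) because library adapters are DNA
while inserts are RNA. All coordinates in reports are 1-based closed
intervals, matching how duplex positions ("position 10 to 11") are quoted
in the field. Central objects are S4 with validity invariants:
`SRNALibrary` (entries must sum to the filtered total; removal counts must
close the accounting), `TargetSite` (score ≥ 0, site length within ±2 of
the miRNA), `PhaseRegister` (windows tile without gap or overlap),
`TAS3Annotation` (a `full` verdict requires both sites). Library labels
are free strings; "juvenile"/"adult" are fixture conventions, not
hard-coded.

## Preprocessing

Adapter recognition is exact on the first `min_anchor` (default 8) bases
of each adapter and tolerates one mismatch over the remainder. The 454
chemistry motivates the artifact classes: adapter dimers (no insert),
double-3'-adapter multimers, and unrecognizable reads. The filter order is
fixed — artifacts, then N-containing inserts, then size 18–25, then
complexity (≥3 distinct bases), then ncRNA match — and each removed read
is attributed to the *first* failing filter. The order of the three
content filters does not change the surviving set, only the attribution;
fixing it makes the per-filter statistics deterministic. Reads containing
N are dropped up front so the library holds alphabet-clean sequences only.

The ncRNA filter is a deterministic seed-and-extend substring matcher
(exact 12-mer seeds, pigeonhole-partitioned when mismatches are allowed,
ungapped verification, both strands by default). A heuristic aligner's
dialect (E-values, word sizes) is deliberately not reproduced: the
contract "drop iff the read occurs in a reference with ≤ m mismatches" is
exact and testable against a brute-force Hamming scan.

## Profiling

`sizeProfile` reports exact integer tallies with percentage shares;
display rounding follows the conventions used for such tables: integer
percent for major size classes, one decimal below 10%, two decimals for
rpt values. Averages across the two libraries are unweighted means of the
per-library percentages. rpt (reads per thousand) is 1000·count/filtered
total, so each library sums to 1000 and the measure is invariant under
duplicating the whole library. One denominator subtlety is surfaced by the
profiling tests: a juvenile miR159 value of 1.15 rpt is not derivable from
any count/denominator pair in the packaged tallies (132/105,794 = 1.25;
113/105,794 = 1.07), so ratio computations take published rpt values as
inputs rather than recomputing that one.

## miRNA homology and variant taxonomy

`matchMirna` slides the query over each canonical mature sequence with 5'
end offsets in ±3 and requires the implied 3' offset to stay within ±3;
only the overlapped region is compared (up to 3 internal mismatches), so
overhanging bases are tolerated but never penalized. Best match = fewest
internal mismatches, then smallest total |offset|, then lexicographically
smallest family. Variant classes are mutually exclusive: canonical (no
mismatch, no offset), otherwise any nonzero offset makes a length variant
(side per offset; length takes precedence over mismatches, whose count is
still reported), otherwise internal mismatch.

The packaged reference set carries one canonical per family — the most
abundant sequence of the family in the packaged count table, ties broken
by first listing — because a database download cannot be assumed. miR482
is the one family whose two printed members are mutually farther than the
mismatch budget, so the reference keeps both (the family genuinely has
multiple divergent members). Star strands (`miR166*` etc.) are separate
references whose reads merge into the mature family in all tallies. The
merged label "miR156/157" is kept as printed. Northern-only rows (count
cells "N") parse as zero counts with a flag; they contribute to family
existence but not to per-library family counts unless requested.

## Folding and hairpin criteria

The default folding backend maximizes weighted base pairs (GC=3, AU=2,
GU=1, hairpin loops ≥3 nt, no pseudoknots) by Nussinov-style dynamic
programming in C++ with a deterministic traceback (first optimal branch,
smallest partner). Its `energy_score` is minus the total pair weight —
arbitrary units, lower is more stable. The contract is pluggable:
`foldRna(backend = "rnafold")` substitutes the ViennaRNA thermodynamic
folder when the executable is available, returning kcal/mol behind the
same interface. The DP is verified against a recursive enumeration oracle
on short sequences.

Precursor windows take 50–200 nt of context per side in 50-nt steps with
the whole transcript as a fallback; `callHairpinCandidate` accepts the
first window setting that passes, mirroring the practice of refolding
with larger context when no local foldback appears. The stem-loop
criteria are explicit because the literature they come from is a
qualitative checklist rather than printed thresholds: (i) the sRNA lies in
one stem arm without touching the terminal loop, (ii) at most 4 sRNA
bases unpaired against the star arm, (iii) asymmetric bulges ≤ 2 nt,
(iv) the window folds below the mean score of 100 dinucleotide-shuffled
versions of itself (Altschul–Erikson shuffle, fixed seed). The shuffle
null replaces an absolute energy cutoff because the default backend's
units are not kcal/mol; preserving dinucleotide counts keeps stacking
composition comparable. The predicted star is the region pairing with the
miRNA (ignoring its first two positions) extended by the standard 2-nt
3' overhang of a DCL duplex — reported even when no star was sequenced.

## Target scoring

Penalties follow the plant target-prediction convention: mismatch 1, G:U
wobble 0.5, indel 2, doubled over miRNA positions 2–13 (the 5'/central
core whose pairing is required for cleavage), cutoff 3.5 by default, at
most one indel per site. The exact constants are config-exposed
(`defaultScoringWeights`); with gaps disabled every score is a
half-integer, which is the form such published score tables take. Site
scans are vectorized over all windows and single-indel variants,
candidates are pruned to non-overlapping sites best-first (ties leftmost),
and the whole scan is property-tested against exhaustive window
enumeration. miR390 site detection reuses the same scanner at an elevated
cutoff of 4.0, since one of the two TAS3 sites typically tolerates more
mispairing than a cleavable site.

## Cleavage coordinates and phasing

With the miRNA 5' end opposite the site's 3' end, the target base
opposite miRNA position k is `site_end − k + 1`. AGO slices the bond
between the bases opposite positions 10 and 11, so the 3' cleavage
fragment — what RLM-5'RACE clones — starts at `site_end − 9`, and the
anchor (`cleavagePoint`) is encoded as the last base of the 5' fragment,
`site_end − 10`. A clone 5' end at position p inside the site reads out
as "k/k+1" with k = `site_end − p + 1`; ends outside the site are
reported as "upstream/downstream n nt". These conventions make the
round trip generator → mapper exact: zero-noise clones give N/N dominance
at 10/11.

Phase windows are consecutive 21-mers from the anchor: D1 starts at the
first nucleotide past the cleaved bond in the chosen direction. The TAS3
register is anchored at the *3'* miR390 site and counted toward the 5'
site, which is the direction that puts tasiARFs at phases 7–8; because
the D-naming convention varies in the literature and the anchoring
direction is not derivable from the printed material alone, a
`five_prime` anchor switch is provided. A tasiARF window is in register
when its start is congruent to the anchor modulo 21 (offset 0); the
architecture verdict is `full` only when two adjacent in-register tasiARF
windows lie strictly between dual sites, `partial` when tasiARFs are
found but the dual-site requirement cannot be assessed (truncated
contigs), `fail` otherwise — so removing a site can never upgrade a
verdict.

## The synthetic generator: what it emulates, and what not

`generatePopulation` emulates the structure the analysis assumes: two
libraries of 10,000 reads; a size distribution with 0.80 of the mass on
24 nt, 0.008 on 21 nt and 0.013 on 22 nt (the printed shares), the
23–25 nt range carrying 0.96 in total and the remainder spread thinly
over 18–20 and 26–28 nt; 35% ncRNA degradation fragments (18–35 nt,
copied from synthetic reference transcripts, so some exceed the DCL
range — matching the observed ~40% contamination among unfiltered
reads); a 0.60 5'A proportion on 24-nt reads; and a planted conserved
miRNA block mirroring the most sequence-rich family's variant spectrum
(canonical at 109/4 reads per library plus internal-mismatch and length
variants) at fixed counts. Adapter artifacts are appended binomially at
2%. One master seed drives every sub-generator through deterministic
child seeds; identical seeds give byte-identical output.

Construction-level guarantees keep the recorded truth exact: background
reads are re-sampled if they collide with the ncRNA references (either
strand) or the planted sequences, and the hairpin generator re-draws its
random flanks (deterministically, up to a bounded number of attempts)
until the folded construct satisfies the structural duplex criteria — the
generator's contract is a *compliant* planted precursor, and a
maximum-pairing fold of random flanking sequence can otherwise entangle
the planted stem. The TAS3 generator derives its spacer lengths from the
register arithmetic so the planted tasiARFs fall at phases 7 and 8 with
mismatch profile (0, 1), with switches to break the inter-site register
or shift the tasiARF block off phase for negative controls.

What the generator does not emulate — and hence what passing tests do not
show about real data: 454 homopolymer sequencing errors and quality
values; genomic multi-mapping and repeat structure; expression dispersion
between biological replicates (planted counts are fixed, not sampled);
chimeric ligation products beyond the two artifact classes; and real
secondary-structure thermodynamics (the default backend is a base-pairing
maximizer, not an energy model — which is why the hairpin criteria are
calibrated against a shuffle null rather than an absolute ΔG).

## Problem sizes and determinism

The test suite and acceptance script run at desk scale: 10,000-read
libraries for the accounting closure, 20 planted and 100 random windows
of ~121 nt (100 shuffles each) for the hairpin operating characteristics,
50 seeded TAS3 loci for phase recovery, and 16-clone RACE simulations —
sizes at which the binomial sampling bounds asserted by the tests are
meaningful and the whole suite completes in about a minute. All
randomness flows from explicit seeds; the shuffle null restores the
caller's RNG state.

## Known limitations

* Homology classification is reference-bound: a family absent from the
  supplied mature set cannot be found, and variants are not resolved to
  *MIRNA* loci.
* The ncRNA filter is substring-based; diverged ncRNA fragments beyond
  the mismatch budget pass through.
* The folding backend ignores stacking thermodynamics and coaxial
  effects; its verdicts are calibrated only relative to the shuffle null.
* Gapped target alignment is limited to one indel per site, adequate for
  near-contiguous plant sites but not for bulged animal-style sites.
* Phasing analysis is anchored at annotated miR390 sites; it does not
  compute genome-wide phasing statistics (phase scores or p-values).
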