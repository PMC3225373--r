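# 454-style sRNA library adapters. The 3' adapter is the pre-adenylated DNA
# oligo; the 5' adapters are the two chimeric DNA/RNA variants. All are
# normalized to the RNA alphabet on ingest (T -> U).
three_prime: CTGTAGGCACCATCAAT
five_prime_variants:
  - atcgtAGGCACCUGAUA
  - atcgtAGGCCACUGAUA
min_anchor: 8
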