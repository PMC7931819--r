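Package: htslite
Title: Lightweight Alignment and Variant Processing Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compact, tested toolkit for high-throughput sequencing data:
    SAM alignment and VCF variant data models with text I/O, BGZF block
    compression with virtual-offset random access and a linear coordinate
    index, FASTA random access (faidx), alignment utilities (filtering,
    sorting, merging, statistics, mate fixing, duplicate marking, MD/NM
    recalculation, FASTQ export), a pileup engine with per-base alignment
    quality (BAQ) adjustment, genotype-likelihood based variant callers
    (biallelic consensus and multiallelic with EM allele frequencies under
    Hardy-Weinberg priors, gVCF capable), VCF manipulation (normalize,
    merge, concat, isec, annotate, consensus, query, filter, stats,
    gtcheck), a runs-of-homozygosity hidden Markov model, and deterministic
    simulators that make every component testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
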