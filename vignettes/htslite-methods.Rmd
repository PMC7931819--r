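---
title: "Models and design choices in htslite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in htslite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

htslite is a compact, fully tested toolkit for alignment and variant data:
SAM and VCF models with text I/O, BGZF block compression with random-access
indexing, alignment utilities, a pileup engine with per-base alignment
quality (BAQ), two genotype-likelihood variant callers, the usual VCF
manipulations, a runs-of-homozygosity HMM, and deterministic simulators.
This vignette describes the statistical models, the numerical choices, and
the places where the design was genuinely open.

## Coordinates and data model

Internally every coordinate is 0-based, half-open. Conversion to the
1-based inclusive conventions of SAM POS, VCF POS and `faidx` region
strings happens only when text is read or written. A single convention
everywhere removes the most common class of off-by-one defects in this
kind of software.

Alignment records and variant records live in plain data frames, one row
per record, with per-record text fields (optional SAM tags, VCF INFO and
per-sample columns) kept verbatim so that parse-then-format is the exact
identity; typed accessors (`sam_tag_get()`, `vcf_info_get()`,
`vcf_format_get()`) decode on demand against the header declarations.
Reference sequences and positions are carried as doubles, which hold exact
integers to 2^53 and therefore accommodate chromosomes beyond the 2 Gb
limit of 32-bit integers.

## BGZF and the linear index

BGZF is a blockwise gzip variant: independent gzip members (each at most
64 KiB of payload, carrying their compressed size in a "BC" extra
subfield) terminated by a fixed 28-byte empty block. A *virtual offset*,
`coffset * 2^16 + uoffset`, addresses any byte of the uncompressed stream
and sorts in file order. Deflate bodies come from base R's `memCompress`
(its zlib header and Adler32 trailer replaced by a gzip wrapper with a
table-driven CRC32); the compression level is therefore zlib's default.
Chunks that deflate to more than 64 KiB — essentially incompressible
data — are split recursively, as the reference implementations do.

The index is the classic *linear* index: per reference, each 16 kb window
maps to the smallest virtual offset of any record whose interval reaches
that window or later. Because records are position-sorted, that offset
belongs to the first record in file order reaching the window, so the
array is filled in a single pass while the file is being written. Region
queries seek to the window's offset, scan forward, keep overlapping
records and stop at the first record starting past the query. This gives
exactly the results of a full scan with an overlap filter; the worst case
(many long-spanning records) is slower than a hierarchical binning index
but identical in output, which is the right trade at desk scale. The
serialized layout (magic `SVLI1`, per-reference window arrays of
little-endian packed offsets) is self-consistent but deliberately not
interoperable with third-party index formats. Truncated BGZF files
(missing the end sentinel) decompress as far as possible with a warning
rather than a hard error, so partial files remain inspectable.

## Genotype likelihoods

For one pileup column and one sample, each read contributes an error
probability $\varepsilon = 10^{-q/10}$ with
$q = \min(\text{base quality after BAQ}, \text{mapping quality})$. The
per-read probability of its base under a homozygous allele $a$ is
$1-\varepsilon$ when the base equals $a$ and $\varepsilon/3$ otherwise;
heterozygous genotypes average the two allele channels. Log-likelihoods
over all diploid genotypes are scaled to integer Phred PLs with minimum 0,
ordered by the standard triangular index $k(k+1)/2+j$ for genotype
$(j,k)$, $j \le k$ (`genotype_index()`; the quadratic growth of this
vector with the allele count is why the ordering is a contract, not an
implementation detail).

Indels are alleles-as-symbols: each distinct inserted sequence or deleted
reference run observed in the column's indel fields becomes a candidate
allele. Evidence is scored through a two-channel model — a base channel at
the anchor column and a gap channel with a flat per-read gap quality
(default Q30). Under any base allele, a read carrying an indel is a gap
error (factor $\varepsilon_g$); under an indel allele the gap channel
scores whether the read's indel matches. The symmetric gap factor matters:
without it a heterozygous deletion cannot beat hom-ref, because
indel-carrying reads match the reference at their anchor base. There is
no per-read indel realignment; this is a deliberate simplification that
keeps the caller small and testable while preserving the architecture.

When a column shows no non-reference evidence, a placeholder unobserved
allele (`<X>`) is appended so hom-ref confidence is still quantified.

## The two callers

The **consensus caller** considers one alternate allele (highest quality
sum) with a fixed genotype prior, by default
$P(\text{het}) = 10^{-3}$, $P(\text{hom-alt}) = 5\times10^{-4}$. Per
sample, posterior $\propto$ likelihood $\times$ prior, GT is the argmax,
GQ the Phred of one minus its posterior, and site QUAL the Phred of the
probability that every sample is hom-ref.

The **multiallelic caller** ranks alleles by total quality sum (ties
alphabetical), keeps at most 3 alternates, estimates allele frequencies
$f$ by EM under Hardy–Weinberg equilibrium, and computes per-sample
posteriors $\propto GL(g)\,\mathrm{HWE}(g\mid f)$. The EM update is the
expected allele dosage over $2N$; the HWE log-likelihood is asserted
non-decreasing each iteration. Convergence is declared at
$\max|\Delta f| < 10^{-10}$; because EM converges only linearly when the
maximizer sits near a frequency boundary, the iteration cap is generous
(2000; an iteration is a handful of flops per sample). User-supplied
frequencies replace the EM estimate entirely.

One addition proved necessary: a prior on *site variability*, `theta`
(default $1.1\times10^{-3}$, the conventional human SNP rate), scaling
the prior of any genotype that carries an alternate allele. With a single
sample the EM frequencies are fit to the same reads being genotyped, so
without this prior a lone Q30 error read among eight makes heterozygous
the maximum-posterior genotype and every sequencing error becomes a
variant site. With it, isolated errors are absorbed while true variants
(whose likelihood ratios are hundreds of dB at 30x) are untouched. At
matched settings ($f = (\tfrac12,\tfrac12)$,
$\theta = P(\text{hom-alt})/P(\text{hom-ref})$, valid because the default
consensus priors satisfy $P(\text{het}) = 2P(\text{hom-alt})$) the two
callers agree genotype-for-genotype, which is tested.

In variants-only mode a site is emitted when any sample's called genotype
carries an alternate allele — a likelihood-driven criterion rather than a
QUAL threshold. gVCF mode merges consecutive, position-adjacent hom-ref
sites whose GQ falls in the same bin (bounds 1, 20, 60 by default) into
blocks carrying `END`, `MIN_DP` and an elementwise-minimum representative
PL — the least confident choice, so a block never overstates the evidence
for any site it covers.

## BAQ

Base qualities describe sequencing error but not local misalignment,
which near indels and in low-complexity sequence dominates pileup errors.
`baq_adjust()` runs a glocal three-state (match/insert/delete) pair HMM
of the aligned read segment against the reference window (alignment ± 7
bp): gap open 0.001, gap extension 0.1, match emission from the base
quality, insertions emitting uniformly, uniform entry over window
columns. Forward–backward gives, per base, the posterior probability that
it aligns at its original column as a match; the Phred of one minus that
posterior caps the base quality. BAQ therefore never raises a quality,
reads identical to non-repetitive reference keep their qualities, and an
indel inside a homopolymer collapses the flanking qualities — all of
which are tested, along with forward/backward total-likelihood agreement
below $10^{-6}$ relative. The delete-state recurrences run within a row
of the dynamic program; they are solved in closed form with cumulative
sums, which keeps the whole pass vectorized over the window.

BAQ is opt-in (`pileup(..., baq = TRUE)`; `mpileup --baq` on the command
line): the HMM is the single most expensive step in an interpreted
implementation, and the default pipeline is sized for interactive use on
desk-scale fixtures. The calling model is unchanged either way; enabling
BAQ only caps qualities.

## Normalization and consensus

`normalize_variants()` reduces a variant to its left-aligned, minimal
representation: shared trailing bases are stripped, extending left from
the reference whenever an allele would become empty, then shared leading
bases are stripped while every allele keeps at least one base; iterated
to the fixed point. The result's REF always equals the reference
substring at its interval, and the operation is idempotent and
haplotype-preserving (applying either representation to the reference
yields the same sequence) — both properties are fuzz-tested on 10^4
generated representations against an apply-to-reference oracle.

`consensus_apply()` splices selected alleles into the reference with
coordinates tracked through prior length changes. Overlapping edits are a
hard error naming both sites (silent last-wins behaviour hides upstream
data errors); heterozygous SNPs can be emitted as IUPAC ambiguity codes;
records without genotypes apply their first alternate.

Site identity for `isec()`, `merge_variant_files()` and `gtcheck()`
compares chromosome, position, REF and the alt-allele set (after
normalization when a reference is available); a position-only mode is
available. Merge resolves QUAL as the maximum, FILTER as PASS iff all
PASS, sums INFO fields declared `Number=1 Integer` (depth-like), and
drops other INFO fields with a warning — there is no general merge rule
for arbitrary annotations. Splitting a multiallelic record slices
`Number=A/R/G` fields via the genotype index formula; joining its own
output restores everything recoverable, with the caveat that biallelic
slices contain no cross-alternate genotype cells, so those PL entries
come back missing.

## The ROH HMM

Two states per site: autozygous (AZ; haplotypes identical by descent, so
genotypes are hom-ref or hom-alt with probabilities $1-f$ and $f$) and
non-autozygous (HW; genotypes at Hardy–Weinberg). Emissions combine the
per-genotype likelihoods (from PL, or 1/0 from hard GT calls) with those
weights. Transition probabilities decay with physical distance $d$ as
$1 - e^{-\rho d}$, with default rates $\rho_{HW\to AZ} = 6.7\times10^{-8}$
and $\rho_{AZ\to HW} = 5\times10^{-9}$ per bp. Viterbi defines segment
boundaries; forward–backward posteriors (computed in log space, with
forward and backward totals agreeing to numerical precision) provide the
per-segment confidence, reported as the Phred of one minus the mean AZ
posterior. Allele frequencies come from `INFO/AF` when present, else from
panel genotypes, else a configurable default (0.4) with a warning; sites
with missing genotypes are skipped but their physical distance still
drives the transition decay. Both the Viterbi path and the posteriors are
tested against exhaustive enumeration over all state sequences on
instances of up to 12 sites.

Two honest caveats, found while testing. The Viterbi boundary of a true
segment absorbs any immediately flanking run of homozygous sites — this
is correct behaviour, and it means individual boundary errors follow the
flank's homozygosity run-length distribution; the accuracy check
therefore bounds the *mean* boundary error (≤ 5 sites at 200-site planted
segments), not every single boundary. And the intuition that raising
$\rho_{HW\to AZ}$ can only grow the AZ call set holds on genotype-shaped
emissions over a mostly-HW genome (the test fixture), but is false for
arbitrary emissions: the all-AZ path contains no $HW\to AZ$ edge, so it
gains nothing from the rate increase and mixed paths can overtake it.

## Simulators: what they emulate and what they do not

The generators define the study conditions used throughout the tests: a
100 kb pseudo-random reference (GC 0.5, with embedded homopolymer tracts
for the BAQ and normalization paths), one diploid sample, SNPs at
$10^{-3}$/bp and 1–4 bp indels at $10^{-4}$/bp with two thirds of
variants heterozygous, and 30x paired-end coverage in 100 bp reads
(insert 300 ± 30) with substitution errors at $10^{-3}$ and base
qualities reflecting that true rate (Q30). Each generator draws from its
own stream derived from the master seed and a fixed label, so adding a
generator never perturbs another, and every output is byte-stable for a
fixed seed.

Truth genotypes are phased, haplotypes are built by splicing, and reads
carry exact CIGARs through the planted indels plus truth tags, so
cross-module round trips (consensus of truth equals the haplotype;
error-free reads are exact haplotype substrings; simulated mate fields
are a fixmate fixed point) close exactly. Indel placements exclude the
flanking-base patterns that would allow left-shifting, so the truth VCF
is minimal and left-aligned by construction — verified by the independent
normalizer, not by construction alone.

What the simulator does not emulate: instrument-specific error profiles
(qualities are flat, errors independent), mapping ambiguity (every read
is placed at its true origin with MAPQ 60; there are no mismapped or
chimeric reads), PCR duplicates, or structural variants. Passing the
end-to-end targets (genotype concordance ≥ 0.99, SNP recall ≥ 0.95,
false-site rate ≤ 2%) therefore demonstrates the correctness of the
likelihood machinery and callers under the stated model, not performance
on real libraries, where alignment artefacts dominate.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at the sizes
above: 10^4-record format round-trip corpora, 1000 randomized region
queries, 100 random pileup fixtures, 100 EM panels against a $10^{-4}$
grid, 10^4 fuzzed indel representations, 100 consensus sequence pairs, 20
planted-ROH replicates of 800 sites, and one full 100 kb end-to-end
calling run — sizes chosen so the whole suite completes in minutes on one
core while every check retains statistical teeth.

Numerical conventions: likelihood work in log10 (HMMs in natural log with
per-row scaling), QUAL capped at 9999 and GQ at 99, PLs rounded to
integers with minimum 0, ties in allele ranking broken alphabetically,
duplicate-key ties in `markdup()` broken toward the first record, and the
depth cap in `pileup()` (250 per sample) applied deterministically in
input order — no randomness anywhere outside the seeded simulators.

## Known limitations

Binary BAM/BCF and CRAM encodings are out of scope (records travel as
SAM/VCF text over the BGZF layer, so "compressed SAM" here is not a BAM
file); the linear index is not BAI/CSI/TBI-compatible; ploidy is diploid
throughout (the callers have no haploid mode yet); symbolic and breakend
alleles are carried opaquely and rejected by `normalize_variants()` and
`consensus_apply()`; the filter language has no arithmetic between fields
or aggregate functions; and `markdup()` does not sub-classify optical
duplicates.
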