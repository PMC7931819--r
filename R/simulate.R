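# Deterministic synthetic-data generators.
#
# Every generator draws from its own pseudo-random stream derived from the
# master seed and a fixed label, so adding a generator never perturbs the
# draws of another.  Defaults describe the standard desk-scale study
# fixture: a 100 kb reference, one diploid sample, 30x paired-end Q30
# coverage, SNPs at 1e-3/bp and short indels at 1e-4/bp with two thirds of
# variants heterozygous.

.stream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483647)
}

#' Simulate a reference sequence
#'
#' Pseudo-random bases at the configured GC fraction, with embedded
#' homopolymer tracts (useful for exercising BAQ and indel normalization).
#' Byte-identical for a fixed seed.
#'
#' @param length sequence length in bp.
#' @param seed master seed.
#' @param chrom sequence name.
#' @param gc GC fraction.
#' @param n_homopolymers,homopolymer_len number and length of embedded
#'   single-base tracts.
#' @return named character vector of length 1.
#' @export
simulate_reference <- function(length = 100000L, seed = 1L, chrom = "chr1",
                               gc = 0.5, n_homopolymers = 20L,
                               homopolymer_len = 10L) {
  set.seed(.stream_seed(seed, paste0("reference:", chrom)))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(p), length, replace = TRUE, prob = p)
  if (n_homopolymers > 0L && length > 10L * homopolymer_len) {
    starts <- sample(seq_len(length - homopolymer_len), n_homopolymers)
    for (s in starts)
      bases[s:(s + homopolymer_len - 1L)] <- sample(c("A", "C", "G", "T"), 1L)
  }
  stats::setNames(paste(bases, collapse = ""), chrom)
}

# sample variant sites with minimum spacing
.spaced_sites <- function(n_total, rate, min_spacing) {
  n <- stats::rbinom(1L, n_total, rate)
  if (n == 0L) return(integer(0))
  pos <- sort(sample(seq_len(n_total - min_spacing), n))
  keep <- c(TRUE, diff(pos) >= min_spacing)
  pos[keep]
}

#' Simulate diploid individuals with planted variants
#'
#' Plants SNPs and short (1-4 bp) indels on the reference; indel
#' representations are minimal and left-aligned by construction (the base
#' flanking conditions that would allow shifting are excluded at
#' generation).  With one sample, each variant is heterozygous with
#' probability `het_fraction` (else hom-alt); with several, genotypes are
#' drawn from Hardy-Weinberg at a per-site frequency uniform on
#' (0.1, 0.9).  Truth genotypes are phased, so each haplotype is exactly
#' the consensus of the reference and its allele column.
#'
#' @param reference named character vector from [simulate_reference()].
#' @param n_samples number of diploid samples.
#' @param snp_rate,indel_rate per-bp variant densities.
#' @param het_fraction single-sample heterozygous fraction.
#' @param seed master seed.
#' @param min_spacing minimum distance between planted variants.
#' @return list of class `truth_set`: `vcf` (truth calls, phased GT),
#'   `haplotypes` (per sample, per haplotype named character vectors) and
#'   `maps` (per sample/haplotype/chrom alignment segment tables used by
#'   the read simulator).
#' @export
simulate_individuals <- function(reference, n_samples = 1L,
                                 snp_rate = 1e-3, indel_rate = 1e-4,
                                 het_fraction = 2 / 3, seed = 1L,
                                 min_spacing = 10L) {
  samples <- sprintf("S%d", seq_len(n_samples))
  recs <- list()
  for (chrom in names(reference)) {
    set.seed(.stream_seed(seed, paste0("individuals:", chrom)))
    refseq <- reference[[chrom]]
    len <- nchar(refseq)
    rb <- strsplit(refseq, "")[[1L]]
    snp_pos <- .spaced_sites(len, snp_rate, min_spacing)
    indel_pos <- .spaced_sites(len, indel_rate, min_spacing)
    # keep indels away from SNPs and from each other
    allpos <- sort(c(snp_pos, indel_pos))
    ok <- !(indel_pos %in% snp_pos)
    for (ip in indel_pos[ok])
      if (any(abs(setdiff(allpos, ip) - ip) < min_spacing))
        ok[indel_pos == ip] <- FALSE
    indel_pos <- indel_pos[ok]
    snp_pos <- setdiff(snp_pos, indel_pos)
    sites <- list()
    for (p in snp_pos) {     # p is 1-based
      refb <- rb[p]
      if (!(refb %in% c("A", "C", "G", "T"))) next
      alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
      sites[[length(sites) + 1L]] <- list(pos = p - 1, ref = refb, alt = alt)
    }
    for (p in indel_pos) {   # p = 1-based anchor
      if (p >= len - 6L) next
      anchor <- rb[p]
      if (!(anchor %in% c("A", "C", "G", "T"))) next
      k <- sample(1:4, 1L)
      if (stats::runif(1) < 0.5) {
        # insertion: last inserted base must differ from the anchor so the
        # representation cannot shift
        s <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
        if (s[k] == anchor)
          s[k] <- sample(setdiff(c("A", "C", "G", "T"), anchor), 1L)
        sites[[length(sites) + 1L]] <- list(pos = p - 1, ref = anchor,
                                            alt = paste0(anchor,
                                                         paste(s, collapse = "")))
      } else {
        # deletion of k bases after the anchor; last deleted base must
        # differ from the anchor
        if (p + k > len) next
        if (rb[p + k] == anchor) next
        sites[[length(sites) + 1L]] <- list(
          pos = p - 1, ref = paste(rb[p:(p + k)], collapse = ""),
          alt = anchor)
      }
    }
    if (!length(sites)) next
    ord <- order(vapply(sites, `[[`, 0, "pos"))
    sites <- sites[ord]
    # genotypes
    gts <- matrix("0|0", length(sites), n_samples,
                  dimnames = list(NULL, samples))
    for (i in seq_along(sites)) {
      if (n_samples == 1L) {
        if (stats::runif(1) < het_fraction) {
          gts[i, 1L] <- if (stats::runif(1) < 0.5) "0|1" else "1|0"
        } else gts[i, 1L] <- "1|1"
      } else {
        f <- stats::runif(1, 0.1, 0.9)
        for (s in seq_len(n_samples)) {
          a1 <- stats::rbinom(1L, 1L, f); a2 <- stats::rbinom(1L, 1L, f)
          gts[i, s] <- paste0(a1, "|", a2)
        }
      }
    }
    carried <- rowSums(matrix(gts != "0|0", nrow = length(sites))) > 0L
    sites <- sites[carried]; gts <- gts[carried, , drop = FALSE]
    if (!length(sites)) next
    d <- data.frame(chrom = chrom,
                    pos = vapply(sites, `[[`, 0, "pos"),
                    id = ".",
                    ref = vapply(sites, `[[`, "", "ref"),
                    alt = vapply(sites, `[[`, "", "alt"),
                    qual = NA_real_, filter = "PASS", info = ".",
                    format = "GT", stringsAsFactors = FALSE)
    for (s in samples) d[[s]] <- gts[, s]
    recs[[chrom]] <- d
  }
  header <- vcf_header(
    contigs = data.frame(name = names(reference),
                         length = nchar(unname(reference))),
    format = data.frame(id = "GT", number = "1", type = "String",
                        description = "Genotype"),
    samples = samples)
  records <- if (length(recs)) do.call(rbind, recs) else
    .empty_vcf_records(samples)
  rownames(records) <- NULL
  truth_vcf <- structure(list(header = header, records = records),
                         class = "vcf")
  # haplotypes + alignment maps
  haplotypes <- list(); maps <- list()
  for (s in samples) {
    haplotypes[[s]] <- list(); maps[[s]] <- list()
    for (hap in 1:2) {
      hs <- character(0); hm <- list()
      for (chrom in names(reference)) {
        refseq <- reference[[chrom]]
        rr <- records[records$chrom == chrom, , drop = FALSE]
        gt <- parse_genotypes(rr[[s]])
        al <- if (hap == 1L) gt$a1 else gt$a2
        use <- which(!is.na(al) & al > 0L)
        segs <- list(); pieces <- character(0)
        cursor <- 0; hcursor <- 0
        for (i in use) {
          pos <- rr$pos[i]; ref <- rr$ref[i]; alt <- rr$alt[i]
          mlen <- pos - cursor
          if (nchar(ref) == 1L && nchar(alt) == 1L) {
            # SNP: extend the match segment through the substituted base
            pieces <- c(pieces, substr(refseq, cursor + 1, pos), alt)
            segs[[length(segs) + 1L]] <- data.frame(
              type = "M", hstart = hcursor, rstart = cursor, len = mlen + 1)
            cursor <- pos + 1; hcursor <- hcursor + mlen + 1
          } else {
            # indel: shared leading anchor base is part of the match
            pieces <- c(pieces, substr(refseq, cursor + 1, pos), alt)
            segs[[length(segs) + 1L]] <- data.frame(
              type = "M", hstart = hcursor, rstart = cursor, len = mlen + 1)
            hcursor <- hcursor + mlen + 1
            cursor <- pos + 1
            if (nchar(alt) > nchar(ref)) {
              ilen <- nchar(alt) - 1
              segs[[length(segs) + 1L]] <- data.frame(
                type = "I", hstart = hcursor, rstart = cursor, len = ilen)
              hcursor <- hcursor + ilen
            } else {
              dlen <- nchar(ref) - 1
              segs[[length(segs) + 1L]] <- data.frame(
                type = "D", hstart = hcursor, rstart = cursor, len = dlen)
              cursor <- cursor + dlen
            }
          }
        }
        pieces <- c(pieces, substr(refseq, cursor + 1, nchar(refseq)))
        segs[[length(segs) + 1L]] <- data.frame(
          type = "M", hstart = hcursor, rstart = cursor,
          len = nchar(refseq) - cursor)
        hs[chrom] <- paste(pieces, collapse = "")
        hm[[chrom]] <- do.call(rbind, segs)
      }
      haplotypes[[s]][[hap]] <- hs
      maps[[s]][[hap]] <- hm
    }
  }
  structure(list(vcf = truth_vcf, haplotypes = haplotypes, maps = maps,
                 reference = reference),
            class = "truth_set")
}

# map a haplotype interval [hs, he) (0-based) to (ref pos, cigar) via the
# segment table; returns NULL when no aligned base falls in the interval
.map_read <- function(segs, hs, he) {
  ops <- character(0); lens <- numeric(0); rstart <- NA_real_
  for (i in seq_len(nrow(segs))) {
    st <- segs$type[i]
    if (st == "D") {
      if (!is.na(rstart) && segs$hstart[i] > hs && segs$hstart[i] < he &&
          length(ops))
        { ops <- c(ops, "D"); lens <- c(lens, segs$len[i]) }
      next
    }
    h0 <- segs$hstart[i]; h1 <- segs$hstart[i] + segs$len[i]
    o0 <- max(h0, hs); o1 <- min(h1, he)
    if (o0 >= o1) next
    if (st == "M") {
      if (is.na(rstart)) rstart <- segs$rstart[i] + (o0 - h0)
      ops <- c(ops, "M"); lens <- c(lens, o1 - o0)
    } else {   # I
      ops <- c(ops, "I"); lens <- c(lens, o1 - o0)
    }
  }
  if (!any(ops == "M")) return(NULL)
  # leading/trailing insertions become soft clips; drop dangling deletions
  while (length(ops) && ops[1L] != "M") {
    if (ops[1L] == "I") ops[1L] <- "S" else { ops <- ops[-1L]; lens <- lens[-1L] }
    if (length(ops) && ops[1L] == "S") break
  }
  while (length(ops) && ops[length(ops)] %in% c("D")) {
    ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
  }
  if (length(ops) && ops[length(ops)] == "I") ops[length(ops)] <- "S"
  # merge adjacent identical ops
  keep_ops <- character(0); keep_lens <- numeric(0)
  for (i in seq_along(ops)) {
    if (length(keep_ops) && keep_ops[length(keep_ops)] == ops[i])
      keep_lens[length(keep_lens)] <- keep_lens[length(keep_lens)] + lens[i]
    else { keep_ops <- c(keep_ops, ops[i]); keep_lens <- c(keep_lens, lens[i]) }
  }
  list(pos = rstart,
       cigar = paste0(format(keep_lens, scientific = FALSE, trim = TRUE),
                      keep_ops, collapse = ""))
}

#' Simulate reads from a truth set
#'
#' Fragments are drawn uniformly from each haplotype; substitution errors
#' are injected at `error_rate` with base qualities reflecting that true
#' error probability.  Records carry correct flags, CIGARs through the
#' planted indels, consistent mate fields (the fixmate invariant holds on
#' output), an RG tag per sample, and truth tags `XH` (haplotype) and
#' `XF` (fragment id).  Fragments are always oriented read1-forward,
#' read2-reverse.
#'
#' @param truth a `truth_set`.
#' @param depth mean per-sample coverage.
#' @param read_len read length in bp.
#' @param paired paired-end (else single-end reads).
#' @param insert_mean,insert_sd fragment length distribution.
#' @param error_rate per-base substitution error rate.
#' @param seed master seed.
#' @return list(header, records): coordinate-sorted alignments.
#' @export
simulate_reads <- function(truth, depth = 30, read_len = 100L,
                           paired = TRUE, insert_mean = 300, insert_sd = 30,
                           error_rate = 1e-3, seed = 1L) {
  reference <- truth$reference
  samples <- truth$vcf$header$samples
  qchar <- rawToChar(as.raw(33L + min(
    if (error_rate > 0) as.integer(round(-10 * log10(error_rate))) else 60L,
    60L)))
  header <- sam_header(
    refs = data.frame(name = names(reference),
                      length = nchar(unname(reference))),
    sort_order = "coordinate",
    read_groups = data.frame(id = paste0("rg_", samples), sample = samples,
                             library = paste0("lib_", samples)))
  recs <- list()
  for (s in samples) {
    set.seed(.stream_seed(seed, paste0("reads:", s)))
    for (chrom in names(reference)) {
      for (hap in 1:2) {
        hseq <- truth$haplotypes[[s]][[hap]][[chrom]]
        segs <- truth$maps[[s]][[hap]][[chrom]]
        hlen <- nchar(hseq)
        # per-haplotype coverage = depth / 2
        nbases <- depth / 2 * hlen
        nfrag <- max(1L, as.integer(round(
          nbases / (read_len * if (paired) 2L else 1L))))
        isize <- if (paired)
          pmax(read_len + 10L,
               as.integer(round(stats::rnorm(nfrag, insert_mean, insert_sd))))
        else rep(read_len, nfrag)
        isize <- pmin(isize, hlen)
        fstart <- vapply(isize, function(il)
          sample.int(hlen - il + 1L, 1L) - 1L, 0L)  # 0-based
        for (k in seq_len(nfrag)) {
          qname <- sprintf("frag_%s_%s_h%d_%d", s, chrom, hap, k)
          ends <- if (paired) list(
            c(fstart[k], fstart[k] + read_len, 0L),
            c(fstart[k] + isize[k] - read_len, fstart[k] + isize[k], 1L))
          else list(c(fstart[k], fstart[k] + read_len, 0L))
          mapped <- lapply(ends, function(e)
            .map_read(segs, e[1L], e[2L]))
          if (any(vapply(mapped, is.null, TRUE))) next
          seqs <- vapply(ends, function(e)
            substr(hseq, e[1L] + 1, e[2L]), "")
          # inject errors
          for (j in seq_along(seqs)) {
            nb <- nchar(seqs[j])
            nerr <- stats::rbinom(1L, nb, error_rate)
            if (nerr > 0L) {
              at <- sample.int(nb, nerr)
              ch <- strsplit(seqs[j], "")[[1L]]
              for (a in at)
                ch[a] <- sample(setdiff(c("A", "C", "G", "T"), ch[a]), 1L)
              seqs[j] <- paste(ch, collapse = "")
            }
          }
          qual <- strrep(qchar, read_len)
          rl <- lapply(seq_along(ends), function(j) {
            is_r2 <- ends[[j]][3L] == 1L
            flag <- if (!paired) 0L else
              FLAG_PAIRED + FLAG_PROPER +
              (if (is_r2) FLAG_REVERSE + FLAG_READ2 else
                 FLAG_MREVERSE + FLAG_READ1)
            other <- if (paired) mapped[[3L - j]] else NULL
            p1 <- mapped[[j]]$pos
            end1 <- p1 + cigar_reference_length(mapped[[j]]$cigar)
            tlen <- 0
            if (paired) {
              lo <- min(p1, other$pos)
              hi <- max(end1, other$pos +
                          cigar_reference_length(other$cigar))
              tlen <- if (p1 <= other$pos &&
                            !(p1 == other$pos && is_r2)) hi - lo else lo - hi
            }
            data.frame(
              qname = qname, flag = flag, rname = chrom, pos = p1,
              mapq = 60L, cigar = mapped[[j]]$cigar,
              rnext = if (paired) "=" else "*",
              pnext = if (paired) other$pos else -1,
              tlen = tlen,
              seq = seqs[j],   # SAM stores reference-forward orientation
              qual = qual,
              tags = sprintf("RG:Z:rg_%s\tXH:i:%d\tXF:i:%d", s, hap, k),
              stringsAsFactors = FALSE)
          })
          recs[[length(recs) + 1L]] <- do.call(rbind, rl)
        }
      }
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else .empty_sam_records()
  sort_records(records, "coordinate", header)
}

#' Simulate a complete study fixture
#'
#' Convenience wrapper chaining [simulate_reference()],
#' [simulate_individuals()] and [simulate_reads()] with shared defaults.
#'
#' @param seed master seed.
#' @param length reference length.
#' @param n_samples samples.
#' @param depth coverage.
#' @param error_rate substitution error rate (base qualities follow).
#' @param ... forwarded to the individual generators.
#' @return list with `reference`, `truth` (a `truth_set`) and
#'   `alignments` (list(header, records)).
#' @export
simulate_dataset <- function(seed = 1L, length = 100000L, n_samples = 1L,
                             depth = 30, error_rate = 1e-3, ...) {
  reference <- simulate_reference(length = length, seed = seed)
  truth <- simulate_individuals(reference, n_samples = n_samples,
                                seed = seed, ...)
  aln <- simulate_reads(truth, depth = depth, error_rate = error_rate,
                        seed = seed)
  list(reference = reference, truth = truth, alignments = aln)
}
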