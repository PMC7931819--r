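# Shared fixture builders: everything is generated in code, no stored data.

fix_header <- function(refs = data.frame(name = "chr1", length = 100000)) {
  sam_header(refs = refs)
}

# one alignment record from compact arguments (1-based pos like SAM text)
mk_rec <- function(qname, flag, pos1, cigar, seq, qual = NULL, mapq = 60L,
                   rname = "chr1", rnext = "*", pnext1 = 0L, tlen = 0L,
                   tags = "", header = fix_header()) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  line <- paste(qname, flag, if (bitwAnd(flag, 4L) > 0L) "*" else rname,
                pos1, mapq, cigar, rnext, pnext1, tlen, seq, qual, sep = "\t")
  if (nzchar(tags)) line <- paste(line, tags, sep = "\t")
  parse_sam_records(line, header)
}

# a random mapped record at a random position (M-only CIGAR)
random_records <- function(n, refs = c(chr1 = 50000, chr2 = 30000),
                           read_len = 50L) {
  hdr <- sam_header(refs = data.frame(name = names(refs),
                                      length = unname(refs)))
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    rname <- sample(names(refs), 1L)
    pos1 <- sample.int(refs[[rname]] - read_len, 1L)
    flag <- sample(c(0L, 16L), 1L)
    mk_rec(sprintf("r%04d", i), flag, pos1, sprintf("%dM", read_len),
           paste(sample(c("A", "C", "G", "T"), read_len, TRUE),
                 collapse = ""),
           rname = rname, header = hdr)
  }))
  list(header = hdr, records = recs)
}

random_sorted_sam <- function(n, ...) {
  s <- random_records(n, ...)
  sort_records(s$records, "coordinate", s$header)
}

# a small VCF header with every declared Number/Type combination used by
# the fuzzers
fuzz_vcf_header <- function(samples = c("S1", "S2")) {
  vcf_header(
    contigs = data.frame(name = c("chr1", "chr2"), length = c(1e5, 5e4)),
    info = data.frame(
      id = c("DP", "AF", "AD", "PLX", "VALID", "NOTE", "CH"),
      number = c("1", "A", "R", "G", "0", ".", "1"),
      type = c("Integer", "Float", "Integer", "Integer", "Flag", "String",
               "Character"),
      description = rep("fuzz", 7)),
    format = data.frame(
      id = c("GT", "PL", "DP", "GQ", "ADF", "FS"),
      number = c("1", "G", "1", "1", "R", "."),
      type = c("String", "Integer", "Integer", "Integer", "Integer",
               "String"),
      description = rep("fuzz", 6)),
    filter = data.frame(id = c("q10"), description = "low quality"),
    samples = samples)
}

random_vcf_lines <- function(n, header = fuzz_vcf_header()) {
  vapply(seq_len(n), function(i) {
    chrom <- sample(header$contigs$name, 1L)
    pos1 <- sample.int(1e4, 1L)
    nalt <- sample(0:3, 1L, prob = c(0.1, 0.6, 0.2, 0.1))
    ref <- paste(sample(c("A", "C", "G", "T"),
                        sample(1:3, 1L), TRUE), collapse = "")
    alts <- if (nalt == 0L) "." else paste(vapply(seq_len(nalt), function(k)
      paste(sample(c("A", "C", "G", "T"), sample(1:3, 1L), TRUE),
            collapse = ""), ""), collapse = ",")
    ng <- (nalt + 1L) * (nalt + 2L) / 2L
    info <- paste(c(
      sprintf("DP=%d", sample.int(100, 1L)),
      if (nalt > 0L) sprintf("AF=%s", paste(
        round(stats::runif(nalt), 3), collapse = ",")),
      sprintf("AD=%s", paste(sample.int(50, nalt + 1L, TRUE) - 1L,
                             collapse = ",")),
      if (nalt > 0L) sprintf("PLX=%s", paste(sample.int(99, ng, TRUE),
                                             collapse = ",")),
      if (stats::runif(1) < 0.3) "VALID",
      sprintf("NOTE=%s", paste(sample(letters, 4L), collapse = ""))),
      collapse = ";")
    qual <- if (stats::runif(1) < 0.2) "." else
      format(round(stats::runif(1, 0, 99), 2), trim = TRUE)
    filt <- sample(c("PASS", "q10", "."), 1L)
    gts <- vapply(header$samples, function(s) {
      if (stats::runif(1) < 0.1) return("./.:.:.:.:.:.")
      a1 <- sample(0:nalt, 1L); a2 <- sample(0:nalt, 1L)
      sep <- sample(c("/", "|"), 1L)
      sprintf("%d%s%d:%s:%d:%d:%s:%s", a1, sep, a2,
              paste(sample.int(99, ng, TRUE), collapse = ","),
              sample.int(99, 1L), sample.int(99, 1L),
              paste(sample.int(30, nalt + 1L, TRUE), collapse = ","),
              paste(sample(letters, 2L), collapse = ""))
    }, "")
    paste(c(chrom, pos1, ".", ref, alts, qual, filt, info,
            "GT:PL:DP:GQ:ADF:FS", gts), collapse = "\t")
  }, "")
}

# pileup entry table builder for likelihood tests
mk_entries <- function(bases, quals = 30L, mapq = 60L, sample = "S",
                       indel = 0L, indel_seq = "") {
  n <- length(bases)
  data.frame(sample = rep_len(sample, n), base = bases,
             qual = rep_len(quals, n), mapq = rep_len(mapq, n),
             is_del = rep_len(FALSE, n), indel = rep_len(indel, n),
             indel_seq = rep_len(indel_seq, n))
}

# brute-force site-set keys for isec-style comparisons
site_keys <- function(records) {
  vapply(seq_len(nrow(records)), function(i) paste(
    records$chrom[i], records$pos[i], records$ref[i],
    paste(sort(strsplit(records$alt[i], ",", fixed = TRUE)[[1L]]),
          collapse = ","), sep = "\r"), "")
}

# build a small vcf object from record lines
mk_vcf <- function(lines, header = fuzz_vcf_header()) {
  rec <- parse_vcf_records(lines, header)
  attr(rec, "header") <- NULL
  structure(list(header = header, records = rec), class = "vcf")
}

# exhaustive-enumeration oracle over all 2^n state sequences
roh_enumerate <- function(pos, emissions, params, init = c(0.5, 0.5)) {
  n <- length(pos)
  tr <- htslite:::.roh_trans(diff(pos), params)
  trmat <- function(k) matrix(c(exp(tr$az_az[k]), exp(tr$az_hw[k]),
                                exp(tr$hw_az[k]), exp(tr$hw_hw[k])),
                              2L, 2L, byrow = TRUE)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  probs <- apply(paths, 1L, function(st) {
    p <- init[st[1L]] * emissions[1L, st[1L]]
    for (k in seq2(2L, n))
      p <- p * trmat(k - 1L)[st[k - 1L], st[k]] * emissions[k, st[k]]
    p
  })
  list(best = paths[which.max(probs), ],
       best_prob = max(probs),
       total = sum(probs),
       post_az = vapply(seq_len(n), function(i)
         sum(probs[paths[, i] == 1L]) / sum(probs), 0))
}
seq2 <- function(a, b) if (b < a) integer(0) else seq.int(a, b)
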