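# Alignment-side toolbox.

test_that("view_filter equals a brute-force predicate scan", {
  set.seed(17)
  sam <- random_records(150)
  # plant some flag variety
  sam$records$flag <- sample(c(0L, 4L, 16L, 1024L, 512L, 256L), 150, TRUE)
  sam$records$rname[has_flag(sam$records$flag, FLAG_UNMAPPED)] <- "*"
  sam$records$mapq <- sample(0:60, 150, TRUE)
  for (i in 1:10) {
    req <- sample(c(0L, 16L), 1L)
    forb <- sample(c(0L, 4L, 1024L), 1L)
    mq <- sample(0:40, 1L)
    got <- view_filter(sam$records, req, forb, mq)
    want <- sam$records[
      bitwAnd(sam$records$flag, req) == req &
        bitwAnd(sam$records$flag, forb) == 0L &
        sam$records$mapq >= mq, , drop = FALSE]
    expect_equal(got, want)
  }
  expect_equal(view_filter(sam$records), sam$records)   # identity
  mapped_only <- view_filter(sam$records, forbidden_flags = FLAG_UNMAPPED)
  expect_false(any(has_flag(mapped_only$flag, FLAG_UNMAPPED)))
  expect_error(view_filter(sam$records, region = "chr1:x-y",
                           header = sam$header), "malformed region")
})

test_that("queryname sort uses natural alphanumeric order", {
  r <- rbind(mk_rec("r10", 0L, 5L, "4M", "ACGT"),
             mk_rec("r2", 0L, 1L, "4M", "ACGT"),
             mk_rec("r2a", 0L, 2L, "4M", "ACGT"),
             mk_rec("R2", 0L, 3L, "4M", "ACGT"))
  s <- sort_records(r, "queryname")
  expect_equal(s$qname, c("R2", "r2", "r2a", "r10"))
  # ties broken by first/last-of-pair flag
  p <- rbind(mk_rec("p", 1L + 128L, 5L, "4M", "ACGT"),
             mk_rec("p", 1L + 64L, 1L, "4M", "ACGT"))
  expect_equal(sort_records(p, "queryname")$flag, c(65L, 129L))
})

test_that("coordinate sort is stable, idempotent and verified pairwise", {
  set.seed(23)
  sam <- random_records(120)
  s1 <- sort_records(sam$records, "coordinate", sam$header)
  expect_equal(s1$header$sort_order, "coordinate")
  s2 <- sort_records(s1$records, "coordinate", s1$header)
  expect_identical(s2$records, s1$records)      # idempotent / stable
  rid <- match(s1$records$rname, sam$header$refs$name)
  key <- rid * 1e9 + s1$records$pos
  expect_true(all(diff(key) >= 0))
  # unmapped records go last
  u <- rbind(mk_rec("u", 4L, 0L, "*", "AC"), mk_rec("m", 0L, 10L, "2M", "AC"))
  expect_equal(sort_records(u, "coordinate")$qname, c("m", "u"))
})

test_that("merge of sorted streams equals sort of the concatenation", {
  set.seed(29)
  sam <- random_sorted_sam(90)
  cut <- sort(sample.int(89, 2L))
  parts <- list(
    list(header = sam$header, records = sam$records[1:cut[1L], ]),
    list(header = sam$header,
         records = sam$records[(cut[1L] + 1):cut[2L], ]),
    list(header = sam$header, records = sam$records[(cut[2L] + 1):90, ]))
  # each part must itself be sorted: they are slices of a sorted file
  m <- merge_sorted(parts)
  expect_equal(m$records, sam$records)
  # merge with an empty stream is the identity
  empty <- list(header = sam$header, records = sam$records[0, ])
  m2 <- merge_sorted(list(list(header = sam$header, records = sam$records),
                          empty))
  expect_equal(m2$records, sam$records)
  # conflicting reference lengths are fatal
  h2 <- sam_header(refs = data.frame(name = "chr1", length = 999))
  expect_error(merge_sorted(list(sam, list(header = h2,
                                           records = sam$records[0, ]))),
               "header conflict")
})

test_that("flagstat matches a brute-force tally and its invariants", {
  expect_true(all(flagstat(mk_rec("x", 0L, 1L, "4M", "ACGT")[0, ])$pass == 0))
  set.seed(31)
  sam <- random_records(200)
  sam$records$flag <- sample(c(0L, 4L, 16L, 99L, 147L, 1024L, 512L, 256L,
                               2048L, 83L, 163L), 200, TRUE)
  fs <- flagstat(sam$records)
  g <- function(cat, col = "pass") fs[[col]][fs$category == cat]
  f <- sam$records$flag
  fail <- has_flag(f, FLAG_QCFAIL)
  primary <- !has_flag(f, FLAG_SECONDARY) & !has_flag(f, FLAG_SUPPLEMENTARY)
  expect_equal(g("total"), sum(!fail))
  expect_equal(g("mapped"), sum(!has_flag(f, FLAG_UNMAPPED) & !fail))
  expect_equal(g("paired"), sum(has_flag(f, FLAG_PAIRED) & primary & !fail))
  expect_equal(g("read1") + g("read2"), g("paired"))
  expect_lte(g("mapped"), g("total"))
  # constructed: 10 mapped, 2 unmapped primaries
  rr <- do.call(rbind, c(
    lapply(1:10, function(i) mk_rec(paste0("m", i), 0L, i, "4M", "ACGT")),
    lapply(1:2, function(i) mk_rec(paste0("u", i), 4L, 0L, "*", "ACGT"))))
  fs2 <- flagstat(rr)
  expect_equal(fs2$pass[fs2$category == "total"], 12)
  expect_equal(fs2$pass[fs2$category == "mapped"], 10)
})

test_that("idxstats counts per reference in header order", {
  set.seed(37)
  sam <- random_records(80)
  ix <- idxstats(sam$records, sam$header)
  expect_equal(ix$name, c(sam$header$refs$name, "*"))
  for (nm in sam$header$refs$name)
    expect_equal(ix$mapped[ix$name == nm],
                 sum(sam$records$rname == nm &
                       !has_flag(sam$records$flag, FLAG_UNMAPPED)))
  expect_equal(sum(ix$mapped) + sum(ix$unmapped), nrow(sam$records))
})

test_that("stats_basic arithmetic", {
  r1 <- mk_rec("a", 0L, 1L, "100M", strrep("A", 100), tags = "NM:i:0")
  s1 <- stats_basic(r1)
  expect_equal(s1$error_rate, 0)
  expect_equal(s1$average_length, 100)
  r2 <- rbind(mk_rec("a", 0L, 1L, "100M", strrep("A", 100), tags = "NM:i:1"),
              mk_rec("b", 0L, 200L, "100M", strrep("C", 100), tags = "NM:i:1"))
  s2 <- stats_basic(r2)
  expect_equal(s2$error_rate, 2 / 200)
  expect_equal(s2$bases_mapped, 200)
  # insert sizes use the positive-tlen side of proper pairs
  p <- rbind(mk_rec("p", 99L, 100L, "50M", strrep("A", 50), tlen = 150L),
             mk_rec("p", 147L, 200L, "50M", strrep("A", 50), tlen = -150L))
  expect_equal(stats_basic(p)$insert_size_average, 150)
})

test_that("depth counts M bases only and matches pileup column sizes", {
  r <- mk_rec("a", 0L, 1L, "10M", strrep("A", 10))
  d <- depth(r)
  expect_equal(d$pos, 0:9)
  expect_true(all(d$depth == 1L))
  rd <- mk_rec("b", 0L, 1L, "5M2D5M", strrep("A", 10))
  dd <- depth(rd)
  expect_false(any(dd$pos %in% c(5, 6)))     # deletion not counted
  set.seed(41)
  sam <- random_sorted_sam(120)
  d2 <- depth(sam$records)
  p <- pileup(sam$records, sam$header)
  expect_equal(d2, pileup_depths(p))
})

test_that("bedcov sums per-base depth over intervals", {
  r <- mk_rec("a", 0L, 11L, "10M", strrep("A", 10))
  bed0 <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0))
  expect_equal(nrow(bedcov(r, bed0)), 0L)
  bed <- data.frame(chrom = "chr1", start = 0, end = 50)
  expect_equal(bedcov(r, bed)$bases, 10)
  set.seed(43)
  sam <- random_sorted_sam(60)
  bed2 <- data.frame(chrom = sample(sam$header$refs$name, 8L, TRUE),
                     start = sample.int(40000, 8L))
  bed2$end <- bed2$start + sample.int(3000, 8L)
  b <- bedcov(sam$records, bed2)
  d <- depth(sam$records)
  for (i in 1:8)
    expect_equal(b$bases[i],
                 sum(d$depth[d$rname == bed2$chrom[i] &
                               d$pos >= bed2$start[i] &
                               d$pos < bed2$end[i]]))
})

test_that("fixmate sets mutually consistent mate fields and TLEN", {
  p <- rbind(mk_rec("p1", 1L + 64L, 100L, "50M", strrep("A", 50)),
             mk_rec("p1", 1L + 128L + 16L, 200L, "50M", strrep("G", 50)))
  fx <- fixmate(p)
  expect_equal(fx$tlen, c(150, -150))
  expect_equal(fx$rnext, c("=", "="))
  expect_equal(fx$pnext, c(199, 99))
  expect_true(has_flag(fx$flag[1L], FLAG_MREVERSE))
  # mate unmapped: fields copied from the mapped read, tlen 0
  mu <- rbind(mk_rec("q", 1L + 64L, 100L, "50M", strrep("A", 50)),
              mk_rec("q", 1L + 128L + 4L, 0L, "*", strrep("G", 50)))
  fu <- fixmate(mu)
  expect_equal(fu$tlen, c(0, 0))
  expect_true(has_flag(fu$flag[1L], FLAG_MUNMAPPED))
  expect_equal(fu$pos[2L], fu$pos[1L])
  # singleton: flagged mate-unmapped
  s <- mk_rec("solo", 1L + 64L, 10L, "4M", "ACGT")
  fs <- fixmate(s)
  expect_true(has_flag(fs$flag, FLAG_MUNMAPPED))
  expect_error(fixmate(rbind(mk_rec("a", 1L, 1L, "4M", "ACGT"),
                             mk_rec("b", 1L, 2L, "4M", "ACGT"),
                             mk_rec("a", 1L, 3L, "4M", "ACGT"))),
               "not grouped")
})

test_that("markdup flags all but the best record per duplicate key", {
  dd <- rbind(mk_rec("d1", 0L, 100L, "10M", strrep("A", 10), strrep("I", 10)),
              mk_rec("d2", 0L, 100L, "10M", strrep("A", 10), strrep("5", 10)),
              mk_rec("d3", 0L, 100L, "10M", strrep("A", 10), strrep("+", 10)))
  md <- markdup(dd)
  expect_equal(has_flag(md$flag, FLAG_DUP), c(FALSE, TRUE, TRUE))
  # opposite strands are distinct keys
  os <- rbind(mk_rec("s1", 0L, 100L, "10M", strrep("A", 10)),
              mk_rec("s2", 16L, 100L, "10M", strrep("A", 10)))
  expect_false(any(has_flag(markdup(os)$flag, FLAG_DUP)))
  # clip arithmetic: 2S8M at 12 and 10M at 10 share the unclipped start
  cl <- rbind(mk_rec("c1", 0L, 10L, "10M", strrep("A", 10), strrep("I", 10)),
              mk_rec("c2", 0L, 12L, "2S8M", strrep("A", 10), strrep("5", 10)))
  mc <- markdup(cl)
  expect_equal(has_flag(mc$flag, FLAG_DUP), c(FALSE, TRUE))
  expect_error(markdup(rbind(mk_rec("a", 0L, 50L, "4M", "ACGT"),
                             mk_rec("b", 0L, 10L, "4M", "ACGT"))),
               "not coordinate-sorted")
})

test_that("markdup flags exactly group-size minus one per key", {
  set.seed(47)
  recs <- list()
  truth_dups <- 0L
  pos_used <- sample.int(10000, 12L)
  for (g in 1:12) {
    k <- sample(1:4, 1L)
    truth_dups <- truth_dups + (k - 1L)
    for (j in 1:k)
      recs[[length(recs) + 1L]] <- mk_rec(
        sprintf("g%dr%d", g, j), 0L, pos_used[g], "20M",
        paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""),
        rawToChar(as.raw(33L + sample(20:40, 20, TRUE))))
  }
  rr <- do.call(rbind, recs)
  rr <- sort_records(rr, "coordinate")
  md <- markdup(rr)
  expect_equal(sum(has_flag(md$flag, FLAG_DUP)), truth_dups)
})

test_that("calmd writes standard MD/NM and the reference is recoverable", {
  set.seed(53)
  refseq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  ref <- c(chr1 = refseq)
  # spec-style example: one mismatch in 8M
  sub8 <- substr(refseq, 101, 108)
  mut <- paste0(substr(sub8, 1, 3),
                setdiff(c("A", "C", "G", "T"), substr(sub8, 4, 4))[1L],
                substr(sub8, 5, 8))
  r <- calmd(mk_rec("m", 0L, 101L, "8M", mut), ref)
  expect_equal(sam_tag_get(r, "NM"), 1)
  expect_match(sam_tag_get(r, "MD"), "^3[ACGT]4$")
  # perfect match -> MD "n", NM 0
  rp <- calmd(mk_rec("p", 0L, 51L, "20M", substr(refseq, 51, 70)), ref)
  expect_equal(sam_tag_get(rp, "NM"), 0)
  expect_equal(sam_tag_get(rp, "MD"), "20")
  # deletion: 4M2D4M
  dseq <- paste0(substr(refseq, 201, 204), substr(refseq, 207, 210))
  rd <- calmd(mk_rec("d", 0L, 201L, "4M2D4M", dseq), ref)
  expect_equal(sam_tag_get(rd, "NM"), 2)
  expect_equal(sam_tag_get(rd, "MD"),
               paste0("4^", substr(refseq, 205, 206), "4"))
  # property: reconstructing the reference from SEQ+MD matches the truth
  reconstruct <- function(rec) {
    md <- sam_tag_get(rec, "MD")
    toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1L]]
    qs <- strsplit(rec$seq, "")[[1L]]
    qi <- 1L; out <- character(0)
    for (t in toks) {
      if (grepl("^[0-9]+$", t)) {
        n <- as.integer(t)
        if (n > 0L) { out <- c(out, qs[qi:(qi + n - 1L)]); qi <- qi + n }
      } else if (startsWith(t, "^")) {
        out <- c(out, strsplit(substr(t, 2, nchar(t)), "")[[1L]])
      } else { out <- c(out, t); qi <- qi + 1L }
    }
    paste(out, collapse = "")
  }
  for (rec in list(r, rp, rd)) {
    span <- cigar_reference_length(rec$cigar)
    expect_identical(reconstruct(rec),
                     substr(refseq, rec$pos + 1, rec$pos + span))
  }
})

test_that("to_fastq restores read orientation", {
  fwd <- mk_rec("f", 0L, 1L, "4M", "AACC", "ABCD")
  expect_equal(to_fastq(fwd), c("@f", "AACC", "+", "ABCD"))
  rev <- mk_rec("r", 16L, 1L, "4M", "AACC", "ABCD")
  expect_equal(to_fastq(rev), c("@r", "GGTT", "+", "DCBA"))
  # secondary records are excluded
  sec <- mk_rec("s", 256L, 1L, "4M", "AACC")
  expect_length(to_fastq(sec), 0L)
  # pair routing
  pp <- rbind(mk_rec("p", 1L + 64L, 1L, "4M", "AACC"),
              mk_rec("p", 1L + 128L, 10L, "4M", "GGTT"))
  sp <- to_fastq(pp, split_pairs = TRUE)
  expect_equal(sp$read1[2L], "AACC")
  expect_equal(sp$read2[2L], "GGTT")
})
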