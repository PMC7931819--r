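# Variant-side toolbox.

test_that("normalization left-aligns through repeats", {
  ref <- c(chr1 = "GGGCACACACAGGG")
  hdr <- vcf_header(contigs = data.frame(name = "chr1", length = 14))
  r <- parse_vcf_records("chr1\t9\t.\tACA\tA\t.\t.\t.", hdr)
  n <- normalize_variants(r, ref)
  expect_equal(n$pos + 1, 3)
  expect_equal(n$ref, "GCA")
  expect_equal(n$alt, "G")
  # already-minimal SNP unchanged
  s <- parse_vcf_records("chr1\t5\t.\tA\tT\t.\t.\t.", hdr)
  expect_equal(normalize_variants(s, ref), s)
  # REF must match the reference
  bad <- parse_vcf_records("chr1\t5\t.\tG\tT\t.\t.\t.", hdr)
  expect_error(normalize_variants(bad, ref), "REF mismatch")
})

test_that("normalization is idempotent and preserves the haplotype", {
  set.seed(101)
  refseq <- paste(sample(c("A", "C", "G", "T"), 500, TRUE,
                         prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
  ref <- c(chr1 = refseq)
  hdr <- vcf_header(contigs = data.frame(name = "chr1", length = 500))
  apply_one <- function(pos0, refal, alt)
    paste0(substr(refseq, 1, pos0), alt,
           substr(refseq, pos0 + nchar(refal) + 1, 500))
  for (i in 1:200) {
    # a denormalized representation: pick an interval and pad both alleles
    p <- sample.int(400, 1L) + 20L
    k <- sample(0:4, 1L)
    core_ref <- substr(refseq, p + 1, p + 1 + k)
    core_alt <- if (k > 0L && stats::runif(1) < 0.5)
      substr(core_ref, 1, 1) else
        paste0(core_ref, paste(sample(c("A", "C", "G", "T"),
                                      sample(1:3, 1L), TRUE), collapse = ""))
    pad <- sample(0:3, 1L)
    refal <- paste0(core_ref, substr(refseq, p + 2 + k, p + 1 + k + pad))
    alt <- paste0(core_alt, substr(refseq, p + 2 + k, p + 1 + k + pad))
    if (identical(refal, alt)) next
    r <- parse_vcf_records(sprintf("chr1\t%d\t.\t%s\t%s\t.\t.\t.",
                                   p + 1, refal, alt), hdr)
    n <- normalize_variants(r, ref)
    n2 <- normalize_variants(n, ref)
    expect_identical(n, n2)    # idempotent
    # haplotype equivalence: applying either representation is identical
    expect_identical(apply_one(r$pos, r$ref, r$alt),
                     apply_one(n$pos, n$ref, n$alt))
    # REF invariant
    expect_identical(toupper(substr(refseq, n$pos + 1, n$pos + nchar(n$ref))),
                     n$ref)
  }
})

test_that("split/join multiallelic slice and rebuild fields", {
  hdr <- fuzz_vcf_header(samples = "S1")
  tri <- parse_vcf_records(
    "chr1\t100\t.\tA\tT,G\t50\tPASS\tDP=20;AF=0.3,0.2\tGT:PL\t1/2:60,40,30,20,10,0",
    hdr)
  sp <- split_multiallelic(tri, hdr)
  expect_equal(nrow(sp), 2L)
  expect_equal(sp$alt, c("T", "G"))
  expect_match(sp$info[1L], "AF=0.3")
  expect_match(sp$info[2L], "AF=0.2")
  # G-number slices select via the genotype index formula
  expect_match(sp$S1[1L], ":60,40,30$")
  expect_match(sp$S1[2L], ":60,20,0$")
  expect_equal(substr(sp$S1, 1, 3), c("1/.", "./1"))
  jn <- join_multiallelic(sp, hdr)
  expect_equal(jn$alt, "T,G")
  expect_equal(substr(jn$S1, 1, 3), "1/2")
  # all recoverable PL entries restored; the cross-alt cell is missing
  expect_equal(jn$S1, "1/2:60,40,30,20,.,0")
  # biallelic records pass through split unchanged
  bi <- parse_vcf_records("chr1\t5\t.\tA\tG\t9\tPASS\tDP=1\tGT:PL\t0/1:9,0,9",
                          hdr)
  expect_equal(split_multiallelic(bi, hdr), bi)
})

test_that("merge unifies sites across files with disjoint samples", {
  mkh <- function(s) vcf_header(
    contigs = data.frame(name = "chr1", length = 1000),
    info = data.frame(id = "DP", number = "1", type = "Integer",
                      description = ""),
    format = data.frame(id = c("GT", "DP"), number = c("1", "1"),
                        type = c("String", "Integer"),
                        description = c("", "")),
    samples = s)
  va <- structure(list(header = mkh("A"), records = parse_vcf_records(
    c("chr1\t100\t.\tA\tT\t50\tPASS\tDP=5\tGT:DP\t0/1:5",
      "chr1\t300\t.\tG\tC\t20\tPASS\tDP=9\tGT:DP\t1/1:9"),
    mkh("A"))), class = "vcf")
  vb <- structure(list(header = mkh("B"), records = parse_vcf_records(
    c("chr1\t100\t.\tA\tG\t60\tPASS\tDP=7\tGT:DP\t1/1:7",
      "chr1\t200\t.\tC\tT\t30\tPASS\tDP=4\tGT:DP\t0/1:4"),
    mkh("B"))), class = "vcf")
  m <- merge_variant_files(list(va, vb))
  expect_equal(m$header$samples, c("A", "B"))
  expect_equal(m$records$pos, c(99, 199, 299))
  at100 <- m$records[m$records$pos == 99, ]
  expect_equal(at100$alt, "T,G")
  gt <- vcf_format_get(at100, "GT", m$header)
  expect_equal(unname(gt[1L, ]), c("0/1", "2/2"))   # B's alt remapped
  expect_equal(vcf_info_get(at100, "DP", m$header), 12)  # summed
  expect_equal(at100$qual, 60)                      # max
  # absent samples filled with missing
  at200 <- m$records[m$records$pos == 199, ]
  expect_match(at200$A, "^\\./\\.")
  # interleaving by position and max-QUAL behaviour verified above;
  # merge(x, empty) keeps x's records
  vempty <- structure(list(header = mkh("C"),
                           records = va$records[0, ]), class = "vcf")
  m2 <- merge_variant_files(list(va, vempty))
  expect_equal(nrow(m2$records), 2L)
})

test_that("concat requires identical samples and preserves order", {
  hdr <- fuzz_vcf_header()
  x1 <- mk_vcf("chr1\t10\t.\tA\tT\t5\tPASS\tDP=1\tGT\t0/1\t0/0", hdr)
  x2 <- mk_vcf("chr2\t20\t.\tC\tG\t5\tPASS\tDP=1\tGT\t0/0\t0/1", hdr)
  cc <- concat_variant_files(list(x1, x2))
  expect_equal(nrow(cc$records), 2L)
  expect_equal(cc$records$chrom, c("chr1", "chr2"))
  expect_equal(concat_variant_files(list(x1))$records, x1$records)
  bad <- mk_vcf("chr1\t5\t.\tA\tT\t5\tPASS\tDP=1\tGT\t0/1",
                fuzz_vcf_header(samples = "S1"))
  expect_error(concat_variant_files(list(x1, bad)), "sample lists differ")
})

test_that("isec matches brute-force set algebra on random site sets", {
  set.seed(103)
  hdr <- fuzz_vcf_header(samples = "S1")
  mk_sites <- function(positions) mk_vcf(sprintf(
    "chr1\t%d\t.\tA\tT\t5\tPASS\tDP=1\tGT\t0/1", positions),
    fuzz_vcf_header(samples = "S1"))
  for (rep in 1:10) {
    p1 <- sort(sample.int(500, 30L))
    p2 <- sort(sample.int(500, 30L))
    p3 <- sort(sample.int(500, 30L))
    vs <- lapply(list(p1, p2, p3), mk_sites)
    res <- isec(vs, rule = "shared")
    expect_equal(res$subsets[[1L]]$pos + 1, intersect(intersect(p1, p2), p3))
    priv <- isec(vs, rule = "private")
    expect_equal(priv$subsets[[1L]]$pos + 1, setdiff(p1, union(p2, p3)))
    atleast2 <- isec(vs, rule = 2L)
    want <- sort(unique(c(intersect(p1, p2), intersect(p1, p3))))
    expect_equal(atleast2$subsets[[1L]]$pos + 1, intersect(p1, want))
  }
  # self-intersection: everything shared
  x <- mk_sites(c(5L, 10L))
  expect_equal(nrow(isec(list(x, x), rule = "shared")$subsets[[1L]]), 2L)
})

test_that("annotate transfers values by site key and removes wildcards", {
  hdr <- fuzz_vcf_header(samples = "S1")
  x <- mk_vcf(c("chr1\t10\t.\tA\tT\t5\tPASS\tDP=4\tGT\t0/1",
                "chr1\t20\t.\tC\tG\t5\tPASS\tDP=6\tGT\t0/0"),
              fuzz_vcf_header(samples = "S1"))
  # remove everything, body otherwise intact
  x0 <- annotate_variants(x, remove = "INFO/*")
  expect_true(all(x0$records$info == "."))
  expect_equal(x0$records$pos, x$records$pos)
  # annotate from the file itself is idempotent
  x1 <- annotate_variants(x, source = x)
  expect_equal(x1$records$info, x$records$info)
  # random annotation table: values transferred iff keys match
  set.seed(107)
  tab <- data.frame(chrom = "chr1", pos = c(9, 15), ref = c("A", "C"),
                    alt = c("T", "G"), SCORE = c("7.5", "1.1"))
  x2 <- annotate_variants(x, source = tab, columns = "SCORE")
  expect_equal(vcf_info_get(x2$records, "SCORE", x2$header), c("7.5", NA))
  expect_true("SCORE" %in% x2$header$info$id)
})

test_that("consensus applies alleles with coordinate tracking", {
  ref <- c(s = "ACGT")
  hdr <- vcf_header(contigs = data.frame(name = "s", length = 4),
                    format = data.frame(id = "GT", number = "1",
                                        type = "String", description = ""),
                    samples = "S1")
  mkx <- function(lines) mk_vcf(lines, hdr)
  expect_equal(consensus_apply(ref, mkx("s\t2\t.\tC\tG\t.\t.\t.\tGT\t1/1"),
                               sample = "S1")[["s"]], "AGGT")
  expect_equal(consensus_apply(ref, mkx("s\t2\t.\tCG\tC\t.\t.\t.\tGT\t1/1"),
                               sample = "S1")[["s"]], "ACT")
  # hom-ref and missing leave the reference; IUPAC encodes het SNPs
  expect_equal(consensus_apply(ref, mkx("s\t2\t.\tC\tG\t.\t.\t.\tGT\t0/0"),
                               sample = "S1")[["s"]], "ACGT")
  iu <- consensus_apply(ref, mkx("s\t2\t.\tC\tG\t.\t.\t.\tGT\t0/1"),
                        sample = "S1", haplotype = "iupac")
  expect_equal(iu[["s"]], "ASGT")
  # overlapping edits are an error naming both sites
  ov <- mkx(c("s\t1\t.\tACG\tA\t.\t.\t.\tGT\t1/1",
              "s\t2\t.\tC\tG\t.\t.\t.\tGT\t1/1"))
  expect_error(consensus_apply(ref, ov, sample = "S1"), "overlapping")
})

test_that("diff-derived variants applied to the source give the target", {
  set.seed(109)
  for (i in 1:25) {
    ref <- simulate_reference(2000, seed = 1000 + i)
    truth <- simulate_individuals(ref, seed = 1000 + i, snp_rate = 3e-3,
                                  indel_rate = 5e-4)
    if (!nrow(truth$vcf$records)) next
    for (hap in 1:2) {
      got <- consensus_apply(ref, truth$vcf, sample = "S1",
                             haplotype = hap)
      expect_identical(got[[1L]], truth$haplotypes$S1[[hap]][[1L]])
    }
  }
})

test_that("query formatting projects fields and iterates samples", {
  hdr <- fuzz_vcf_header()
  r <- parse_vcf_records(
    "chr1\t100\trs1\tA\tT\t50.5\tPASS\tDP=7\tGT:DP\t0|1:4\t1/1:6", hdr)
  expect_equal(query_format(r, hdr, "%CHROM\\t%POS\\n"), "chr1\t100")
  expect_equal(query_format(r, hdr, "[%GT,]\\n"), "0|1,1/1,")
  expect_equal(query_format(r, hdr, "%INFO/DP;%QUAL\\n"), "7;50.5")
  expect_equal(query_format(r, hdr, "[%SAMPLE=%DP ]\\n"), "S1=4 S2=6 ")
  # projection equals the model fields
  out <- query_format(r, hdr, "%CHROM\\t%POS\\t%REF\\t%ALT\\n")
  expect_equal(out, paste("chr1", 100, "A", "T", sep = "\t"))
})

test_that("filter expressions evaluate totally, missing compares false", {
  hdr <- fuzz_vcf_header()
  r <- parse_vcf_records(
    "chr1\t100\t.\tA\tT\t50\tPASS\tDP=5\tGT:DP\t0/1:3\t0/0:60", hdr)
  expect_true(eval_filter(r, "QUAL>30", hdr))
  expect_false(eval_filter(r, "QUAL>30", hdr, mode = "exclude"))
  expect_false(eval_filter(r, "INFO/DP<10 && QUAL>30", hdr) &&
                 eval_filter(r, "INFO/DP>=10", hdr))
  expect_true(eval_filter(r, "INFO/DP<10 && QUAL>30", hdr))
  expect_true(eval_filter(r, "FILTER=\"PASS\"", hdr))
  expect_true(eval_filter(r, "FORMAT/DP>50", hdr))    # any-sample
  expect_false(eval_filter(r, "!(QUAL>30)", hdr))
  # missing field: comparison false, negation true
  expect_false(eval_filter(r, "INFO/AF>0", hdr))
  expect_true(eval_filter(r, "!(INFO/AF>0)", hdr))
  expect_true(eval_filter(r, "INFO/DP=5", hdr))
  expect_error(parse_filter_expression("QUAL >>> 3"), "tokenize|field|constant")
  expect_error(parse_filter_expression("(QUAL>3"), "missing ')'")
})

test_that("random filter expressions match direct evaluation", {
  set.seed(113)
  hdr <- fuzz_vcf_header(samples = "S1")
  recs <- parse_vcf_records(sprintf(
    "chr1\t%d\t.\tA\tT\t%d\t%s\tDP=%d\tGT:DP\t0/1:%d",
    1:40, sample(0:99, 40, TRUE), sample(c("PASS", "q10"), 40, TRUE),
    sample(0:50, 40, TRUE), sample(0:80, 40, TRUE)), hdr)
  attr(recs, "header") <- NULL
  qual <- recs$qual
  dp <- vcf_info_get(recs, "DP", hdr)
  filt <- recs$filter
  cases <- list(
    list(e = "QUAL>50", w = qual > 50),
    list(e = "INFO/DP<=25", w = dp <= 25),
    list(e = "QUAL>50 && INFO/DP<=25", w = qual > 50 & dp <= 25),
    list(e = "QUAL>50 || INFO/DP<=25", w = qual > 50 | dp <= 25),
    list(e = "!(QUAL>50) && FILTER=\"PASS\"", w = !(qual > 50) & filt == "PASS"),
    list(e = "(QUAL>20 || INFO/DP>40) && FILTER!=\"q10\"",
         w = (qual > 20 | dp > 40) & filt != "q10"))
  for (cs in cases)
    expect_equal(eval_filter(recs, cs$e, hdr), cs$w, info = cs$e)
})

test_that("vcf_stats counts sites and per-sample genotypes", {
  hdr <- fuzz_vcf_header()
  x <- mk_vcf(c(
    "chr1\t10\t.\tA\tG\t50\tPASS\tDP=1\tGT\t0/1\t0/0",   # ts
    "chr1\t20\t.\tC\tT\t50\tPASS\tDP=1\tGT\t1/1\t0/0",   # ts
    "chr1\t30\t.\tG\tT\t50\tPASS\tDP=1\tGT\t0/1\t0/1",   # tv
    "chr1\t40\t.\tG\tGA\t50\tPASS\tDP=1\tGT\t0/1\t./.",  # indel
    "chr1\t50\t.\tT\tA,C\t50\tPASS\tDP=1\tGT\t1/2\t0/0"), hdr)
  st <- vcf_stats(x)
  expect_equal(st$ts, 2L)
  expect_equal(st$tv, 1L)
  expect_equal(st$ts_tv, 2)
  expect_equal(st$ts + st$tv, 3L)     # = biallelic SNP count
  expect_equal(st$n_indels, 1L)
  expect_equal(st$n_multiallelic, 1L)
  expect_equal(st$n_singletons, 4L)   # sites where exactly one sample has alt
  ps <- st$per_sample
  expect_equal(ps$nHet[ps$sample == "S1"], 4L)
  expect_equal(ps$nNonRefHom[ps$sample == "S1"], 1L)
  expect_equal(ps$nMissing[ps$sample == "S2"], 1L)
  # empty file
  st0 <- vcf_stats(mk_vcf(character(0), hdr))
  expect_equal(st0$n_records, 0L)
  expect_true(is.na(st0$ts_tv))
})

test_that("gtcheck: identity, complementary homs, random panels", {
  hdr <- fuzz_vcf_header()
  x <- mk_vcf(c("chr1\t10\t.\tA\tG\t50\tPASS\tDP=1\tGT\t0/1\t1/1",
                "chr1\t20\t.\tC\tT\t50\tPASS\tDP=1\tGT\t0/0\t0/1"), hdr)
  self <- gtcheck(x, x)
  expect_true(all(self$n_discordant == 0L))
  expect_true(all(self$n_sites == 2L))
  y <- mk_vcf(c("chr1\t10\t.\tA\tG\t50\tPASS\tDP=1\tGT\t1/1\t0/0",
                "chr1\t20\t.\tC\tT\t50\tPASS\tDP=1\tGT\t1/1\t1/0"), hdr)
  gc <- gtcheck(x, y)
  expect_equal(gc$n_discordant[gc$sample_a == "S1"], 2L)
  # unordered comparison: 0/1 vs 1/0 concordant, 1/1 vs 0/0 discordant
  expect_equal(gc$n_discordant[gc$sample_a == "S2"], 1L)
  set.seed(127)
  gts <- function() sprintf("%d/%d", sample(0:1, 30, TRUE),
                            sample(0:1, 30, TRUE))
  lines_a <- sprintf("chr1\t%d\t.\tA\tG\t5\tPASS\tDP=1\tGT\t%s\t%s",
                     1:30, gts(), gts())
  lines_b <- sprintf("chr1\t%d\t.\tA\tG\t5\tPASS\tDP=1\tGT\t%s\t%s",
                     1:30, gts(), gts())
  a <- mk_vcf(lines_a, hdr); b <- mk_vcf(lines_b, hdr)
  gc2 <- gtcheck(a, b)
  for (s in c("S1", "S2")) {
    ga <- parse_genotypes(vcf_format_get(a$records, "GT", hdr)[, s])
    gb <- parse_genotypes(vcf_format_get(b$records, "GT", hdr)[, s])
    want <- sum(pmin(ga$a1, ga$a2) != pmin(gb$a1, gb$a2) |
                  pmax(ga$a1, ga$a2) != pmax(gb$a1, gb$a2))
    expect_equal(gc2$n_discordant[gc2$sample_a == s], want)
  }
})
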