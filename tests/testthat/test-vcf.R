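# VCF model, text I/O, typed access, header handling, indexing.

test_that("parse and format are mutually inverse on a fuzz corpus", {
  set.seed(83)
  hdr <- fuzz_vcf_header()
  lines <- random_vcf_lines(300, hdr)
  rec <- parse_vcf_records(lines, hdr)
  attr(rec, "header") <- NULL
  expect_identical(format_vcf_records(rec, hdr), lines)
  rt <- parse_vcf_records(format_vcf_records(rec, hdr), hdr)
  attr(rt, "header") <- NULL
  expect_identical(rt, rec)
})

test_that("coordinates, typing and genotype parsing", {
  hdr <- fuzz_vcf_header()
  line <- "chr1\t100\t.\tA\tT\t50\tPASS\tDP=7\tGT:PL\t0|1:30,0,40\t1/1:90,9,0"
  r <- parse_vcf_records(line, hdr)
  expect_equal(r$pos, 99)
  expect_equal(vcf_info_get(r, "DP", hdr), 7)
  expect_true(is.na(parse_vcf_records(
    "chr1\t100\t.\tA\tT\t.\tPASS\tDP=7\tGT\t0/0\t0/0", hdr)$qual))
  gt <- parse_genotypes(vcf_format_get(r, "GT", hdr))
  expect_true(gt$phased[1L, "S1"])
  expect_false(gt$phased[1L, "S2"])
  expect_equal(unname(gt$a1[1L, "S2"]), 1L)
  # Flag typing
  rf <- parse_vcf_records("chr1\t5\t.\tC\tG\t1\tPASS\tVALID;DP=3\tGT\t0/0\t0/1",
                          hdr)
  expect_true(vcf_info_get(rf, "VALID", hdr))
  expect_false(vcf_info_get(r, "VALID", hdr))
})

test_that("strict mode validates arity, lenient auto-declares", {
  hdr <- fuzz_vcf_header()
  # PL for 2 alts needs 6 values
  bad <- "chr1\t10\t.\tA\tT,G\t5\tPASS\tDP=1\tGT:PL\t0/1:30,0\t0/0:1,2,3,4,5,6"
  expect_error(parse_vcf_records(bad, hdr, strict = TRUE), "expected 6")
  # Number=A INFO with wrong arity
  bad2 <- "chr1\t10\t.\tA\tT,G\t5\tPASS\tAF=0.5\tGT\t0/1\t0/0"
  expect_error(parse_vcf_records(bad2, hdr, strict = TRUE),
               "1 values, expected 2")
  expect_error(parse_vcf_records(
    "chr1\t10\t.\tA\tT\t5\tPASS\tZZ=1\tGT\t0/1\t0/0", hdr, strict = TRUE),
    "undeclared")
  expect_warning(out <- parse_vcf_records(
    "chr1\t10\t.\tA\tT\t5\tPASS\tZZ=1\tGT\t0/1\t0/0", hdr),
    "auto-declaring")
  expect_true("ZZ" %in% attr(out, "header")$info$id)
  expect_error(parse_vcf_records("chr1\t10\t.\tA\tT\t5\tPASS",
                                 vcf_header()), "fields")
  expect_error(parse_vcf_records(
    "chr1\txx\t.\tA\tT\t5\tPASS\tDP=1\tGT\t0/1\t0/0", hdr), "POS")
})

test_that("header text round trips", {
  hdr <- fuzz_vcf_header()
  txt <- format_vcf_header(hdr)
  rt <- parse_vcf_header(txt)
  expect_identical(format_vcf_header(rt), txt)
  expect_equal(rt$samples, hdr$samples)
  expect_equal(rt$info$number, hdr$info$number)
})

test_that("header merging unions definitions and renames duplicates", {
  h1 <- fuzz_vcf_header(samples = c("A", "B"))
  h2 <- fuzz_vcf_header(samples = c("B", "C"))
  m <- merge_vcf_headers(list(h1, h2))
  expect_equal(m$header$samples, c("A", "B", "B_2", "C"))
  expect_equal(m$sample_names[[2L]], c("B_2", "C"))
  # disjoint INFO sets union
  h3 <- vcf_header(info = data.frame(id = "XY", number = "1",
                                     type = "Float", description = ""))
  m2 <- merge_vcf_headers(list(h1, h3))
  expect_true(all(c("DP", "XY") %in% m2$header$info$id))
  # conflicting types are fatal; conflicting Numbers resolve to '.'
  h4 <- vcf_header(info = data.frame(id = "DP", number = "1",
                                     type = "Float", description = ""))
  expect_error(merge_vcf_headers(list(h1, h4)), "declared both")
  h5 <- vcf_header(info = data.frame(id = "DP", number = "A",
                                     type = "Integer", description = ""))
  expect_equal(merge_vcf_headers(list(h1, h5))$header$info$number[
    merge_vcf_headers(list(h1, h5))$header$info$id == "DP"], ".")
})

test_that("plain and BGZF VCF round trip through files", {
  set.seed(89)
  hdr <- fuzz_vcf_header()
  x <- mk_vcf(random_vcf_lines(50, hdr), hdr)
  plain <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(x, plain)
  rt <- read_vcf(plain)
  expect_equal(rt$records, x$records)
  gz <- withr::local_tempfile(fileext = ".vcf.gz")
  write_vcf(x, gz)
  rt2 <- read_vcf(gz)
  expect_equal(rt2$records, x$records)
})

test_that("indexed region queries equal full-scan filtering", {
  set.seed(97)
  hdr <- fuzz_vcf_header()
  lines <- random_vcf_lines(200, hdr)
  rec <- parse_vcf_records(lines, hdr)
  attr(rec, "header") <- NULL
  rec <- rec[order(match(rec$chrom, hdr$contigs$name), rec$pos), ]
  rownames(rec) <- NULL
  x <- structure(list(header = hdr, records = rec), class = "vcf")
  gz <- withr::local_tempfile(fileext = ".vcf.gz")
  write_vcf(x, gz, index = TRUE)
  for (i in 1:20) {
    chrom <- sample(hdr$contigs$name, 1L)
    a <- sample.int(9000, 1L); b <- a + sample.int(2000, 1L)
    got <- vcf_query_region(gz, sprintf("%s:%d-%d", chrom, a, b))$records
    want <- rec[rec$chrom == chrom & rec$pos < b &
                  rec$pos + nchar(rec$ref) > a - 1, , drop = FALSE]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("info set/remove keeps other fields intact", {
  hdr <- fuzz_vcf_header()
  r <- parse_vcf_records("chr1\t9\t.\tA\tG\t5\tPASS\tDP=4;NOTE=abc\tGT\t0/0\t0/1",
                         hdr)
  r2 <- vcf_info_set(r, "DP", "9")
  expect_equal(vcf_info_get(r2, "DP", hdr), 9)
  expect_equal(vcf_info_get(r2, "NOTE", hdr), "abc")
  r3 <- vcf_info_set(r2, "DP", NA_character_)
  expect_true(is.na(vcf_info_get(r3, "DP", hdr)))
})
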