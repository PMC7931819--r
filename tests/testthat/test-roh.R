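# Runs-of-homozygosity HMM.

test_that("emission formulas: HWE mixture and AZ two-genotype mixture", {
  # flat likelihoods: HW emission is the HWE normalization, AZ is (1-f)+f
  flat <- c(1, 1, 1)
  em <- roh_emissions(flat, 0.5)
  expect_equal(unname(em["hw"]), 1)
  expect_equal(unname(em["az"]), 1)
  # a certain het is impossible under autozygosity
  het <- c(0, 1, 0)
  expect_equal(unname(roh_emissions(het, 0.3)["az"]), 0)
  # certain hom-alt at f = 0.1: AZ/HW = 0.1 / 0.01 = 10
  hom <- c(0, 0, 1)
  e <- roh_emissions(hom, 0.1)
  expect_equal(unname(e["az"] / e["hw"]), 10)
  expect_error(roh_emissions(flat, 0), "frequency")
  expect_error(roh_emissions(flat, 1), "frequency")
})

test_that("Viterbi and posteriors equal exhaustive enumeration", {
  set.seed(131)
  params <- roh_params(rate_hw_to_az = 1e-4, rate_az_to_hw = 5e-5)
  for (rep in 1:6) {
    n <- sample(6:12, 1L)
    pos <- cumsum(sample.int(2000, n))
    em <- matrix(stats::runif(2 * n, 0.01, 1), n, 2L,
                 dimnames = list(NULL, c("az", "hw")))
    path <- roh_viterbi(pos, em, params)
    post <- roh_posterior(pos, em, params)
    oracle <- roh_enumerate(pos, em, params)
    # the Viterbi path's probability equals the enumerated maximum
    score_path <- function(st) {
      tr <- htslite:::.roh_trans(diff(pos), params)
      lp <- log(0.5) + log(unname(em[1L, st[1L]]))
      for (k in seq2(2L, n)) {
        tt <- matrix(c(tr$az_az[k - 1L], tr$az_hw[k - 1L],
                       tr$hw_az[k - 1L], tr$hw_hw[k - 1L]), 2L, 2L,
                     byrow = TRUE)
        lp <- lp + tt[st[k - 1L], st[k]] + log(unname(em[k, st[k]]))
      }
      lp
    }
    expect_equal(score_path(path), log(oracle$best_prob), tolerance = 1e-9)
    expect_equal(post$posterior, oracle$post_az, tolerance = 1e-9)
    expect_equal(post$loglik_fwd, log(oracle$total), tolerance = 1e-9)
    expect_lt(abs(post$loglik_fwd - post$loglik_bwd) /
                abs(post$loglik_fwd), 1e-6)
  }
})

test_that("symmetric emissions and transitions give posterior one half", {
  params <- roh_params(rate_hw_to_az = 1e-4, rate_az_to_hw = 1e-4)
  pos <- c(100, 200, 300, 400)
  em <- matrix(0.4, 4L, 2L)
  post <- roh_posterior(pos, em, params)
  expect_equal(post$posterior, rep(0.5, 4L))
  # AZ and HW posteriors are complementary by construction
  expect_true(all(post$posterior >= 0 & post$posterior <= 1))
})

test_that("strongly heterozygous data yield no segments", {
  hdr <- vcf_header(
    contigs = data.frame(name = "chr1", length = 1e6),
    info = data.frame(id = "AF", number = "A", type = "Float",
                      description = ""),
    format = data.frame(id = c("GT", "PL"), number = c("1", "G"),
                        type = c("String", "Integer"),
                        description = c("", "")),
    samples = "S1")
  lines <- sprintf("chr1\t%d\t.\tA\tT\t50\tPASS\tAF=0.5\tGT:PL\t0/1:90,0,90",
                   seq(1000, 50000, by = 1000))
  x <- mk_vcf(lines, hdr)
  segs <- roh(x)
  expect_equal(nrow(segs), 0L)
})

test_that("a planted autozygous run is recovered with tight boundaries", {
  set.seed(137)
  hdr <- vcf_header(
    contigs = data.frame(name = "chr1", length = 1e8),
    info = data.frame(id = "AF", number = "A", type = "Float",
                      description = ""),
    format = data.frame(id = c("GT", "PL"), number = c("1", "G"),
                        type = c("String", "Integer"),
                        description = c("", "")),
    samples = "S1")
  n_runs <- 20L
  hits <- 0L; bound_errs <- numeric(0)
  for (rep in seq_len(n_runs)) {
    # 300 HWE sites, then 200 AZ sites, then 300 HWE sites, 1 kb apart,
    # PLs from 20x coverage at Q30, mean allele frequency 0.3
    f <- 0.3
    gt_hw <- function(n) stats::rbinom(n, 1L, f) + stats::rbinom(n, 1L, f)
    gt_az <- function(n) 2L * stats::rbinom(n, 1L, f)
    gts <- c(gt_hw(300), gt_az(200), gt_hw(300))
    pls <- vapply(gts, function(g) {
      nreads <- stats::rpois(1L, 20); if (nreads == 0L) nreads <- 1L
      nalt <- stats::rbinom(1L, nreads, c(1e-3, 0.5, 1 - 1e-3)[g + 1L])
      ll <- c(stats::dbinom(nalt, nreads, 1e-3, log = TRUE),
              stats::dbinom(nalt, nreads, 0.5, log = TRUE),
              stats::dbinom(nalt, nreads, 1 - 1e-3, log = TRUE))
      pl <- round(-10 * (ll - max(ll)) / log(10))
      paste(as.integer(pl - min(pl)), collapse = ",")
    }, "")
    lines <- sprintf("chr1\t%d\t.\tA\tT\t50\tPASS\tAF=%g\tGT:PL\t%s:%s",
                     seq_len(800) * 1000L, f,
                     c("0/0", "0/1", "1/1")[gts + 1L], pls)
    x <- mk_vcf(lines, hdr)
    segs <- roh(x, params = roh_params(rate_hw_to_az = 1e-6,
                                       rate_az_to_hw = 1e-7))
    # the planted run spans sites 301..500 (positions 301000..500000)
    overlap <- segs[segs$end > 301000 & segs$start < 500000, , drop = FALSE]
    if (nrow(overlap)) {
      hits <- hits + 1L
      seg <- overlap[which.max(overlap$n_sites), ]
      bound_errs <- c(bound_errs, abs(seg$start - 301000) / 1000,
                      abs(seg$end - 500000) / 1000)
    }
  }
  expect_gte(hits / n_runs, 0.95)
  # flanking homozygous sites are absorbed, so individual boundaries can
  # slip by a few sites; on average the error stays within five sites
  expect_lte(mean(bound_errs), 5)
})

test_that("raising the HW-to-AZ rate never shrinks the AZ call set", {
  # on genotype-shaped emissions over a mostly-Hardy-Weinberg genome
  set.seed(140)
  f <- 0.3
  gts <- c(stats::rbinom(100, 1, f) + stats::rbinom(100, 1, f),
           2L * stats::rbinom(50, 1, f),
           stats::rbinom(100, 1, f) + stats::rbinom(100, 1, f))
  em <- t(vapply(gts, function(g) {
    l <- c(0, 0, 0); l[g + 1L] <- 1
    roh_emissions(l, f)
  }, c(az = 0, hw = 0)))
  pos <- seq_along(gts) * 1000
  prev <- -1L
  for (rate in c(1e-8, 1e-7, 1e-6, 1e-5)) {
    p <- roh_params(rate_hw_to_az = rate, rate_az_to_hw = 5e-9)
    naz <- sum(roh_viterbi(pos, em, p) == 1L)
    expect_gte(naz, prev)
    prev <- naz
  }
})

test_that("AF fallback hierarchy and site skipping are reported", {
  hdr <- vcf_header(
    contigs = data.frame(name = "chr1", length = 1e6),
    format = data.frame(id = "GT", number = "1", type = "String",
                        description = ""),
    samples = "S1")
  lines <- sprintf("chr1\t%d\t.\tA\tT\t50\tPASS\t.\tGT\t%s",
                   c(1000, 2000, 3000), c("1/1", "./.", "1/1"))
  x <- mk_vcf(lines, hdr)
  expect_warning(segs <- roh(x, params = roh_params(gts_only = TRUE)),
                 "default")
  expect_equal(attr(segs, "n_skipped"), 1L)   # the missing genotype
})
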