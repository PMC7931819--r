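# Genotype likelihoods, the callers, EM allele frequencies, gVCF blocks.

test_that("single-read closed form matches independent arithmetic", {
  # 1 ref read at q20: eps = 0.01 -> likelihoods (0.99, 0.49667, 0.00333)
  gl <- site_likelihoods(mk_entries("A", quals = 20L), "A")
  eps <- 0.01
  lik <- c(1 - eps, 0.5 * (1 - eps) + 0.5 * eps / 3, eps / 3)
  pl_expected <- round(-10 * (log10(lik) - max(log10(lik))))
  expect_identical(gl$samples$S$pl, as.integer(pl_expected))
  expect_identical(gl$samples$S$pl, c(0L, 3L, 25L))
  expect_equal(min(gl$samples$S$pl), 0L)
})

test_that("no reads give flat likelihoods; alt evidence drives hom-alt", {
  gl0 <- site_likelihoods(mk_entries(character(0)), "A", samples = "S")
  expect_identical(gl0$samples$S$pl, c(0L, 0L, 0L))
  gl10 <- site_likelihoods(mk_entries(rep("T", 10), quals = 30L), "A")
  expect_equal(which.min(gl10$samples$S$pl), 3L)   # argmin = hom-alt
  # hom-ref term from the eps/3 mismatch model, recomputed independently
  eps <- 1e-3; eg <- 1e-3
  rr <- -10 * 10 * (log10(eps / 3) + log10(1 - eg))
  aa <- -10 * 10 * (log10(1 - eps) + log10(1 - eg))
  expect_equal(gl10$samples$S$pl[1L], as.integer(round(rr - aa)))
  expect_identical(gl10$samples$S$pl[1L], 348L)
})

test_that("quality sums rank alleles and depth is counted per sample", {
  ent <- rbind(mk_entries(c("A", "A", "T"), quals = c(30L, 20L, 25L)),
               mk_entries("G", quals = 35L, sample = "S2"))
  gl <- site_likelihoods(ent, "A")
  expect_equal(unname(gl$samples$S$qs["A"]), 50)
  expect_equal(unname(gl$samples$S$qs["T"]), 25)
  expect_equal(unname(gl$samples$S2$qs["G"]), 35)
  expect_equal(gl$samples$S$dp, 3L)
  expect_equal(gl$samples$S2$dp, 1L)
})

test_that("consensus caller: prior dominates flat data, data dominates prior", {
  glf <- site_likelihoods(mk_entries(character(0)), "A", samples = "S")
  expect_equal(call_consensus(glf)$genotypes$S$gt, "0/0")
  glh <- site_likelihoods(mk_entries(rep(c("A", "T"), 15)), "A")
  cc <- call_consensus(glh)
  expect_equal(cc$genotypes$S$gt, "0/1")
  expect_gte(cc$genotypes$S$gq, 30L)
  expect_gt(cc$qual, 100)
})

test_that("EM fixed points: certain panels", {
  expect_equal(estimate_af_em(list(c(0L, 300L, 600L), c(0L, 300L, 600L)), 2)[1L],
               1, tolerance = 1e-6)
  f <- estimate_af_em(list(c(300L, 0L, 300L)), 2)
  expect_equal(f, c(0.5, 0.5), tolerance = 1e-6)
})

test_that("EM matches grid maximization of the HWE likelihood", {
  set.seed(71)
  grid <- seq(0, 1, by = 1e-4)
  for (panel in 1:100) {
    ns <- sample(3:12, 1L)
    gls <- lapply(seq_len(ns), function(i) {
      pl <- sample.int(120, 3L) - 1L
      as.integer(pl - min(pl))
    })
    fhat <- estimate_af_em(gls, 2)[2L]
    ll <- numeric(length(grid))
    for (g in gls) {
      lik <- 10^(-g / 10); lik <- lik / sum(lik)
      ll <- ll + log((1 - grid)^2 * lik[1L] +
                       2 * grid * (1 - grid) * lik[2L] + grid^2 * lik[3L])
    }
    fgrid <- grid[which.max(ll)]
    expect_lt(abs(fhat - fgrid), 1e-4 + 5e-5)
  }
})

test_that("multiallelic caller keeps both alts of a triallelic toy", {
  ent <- rbind(mk_entries(rep(c("A", "C"), 10), quals = 40L, sample = "S1"),
               mk_entries(rep(c("A", "G"), 10), quals = 40L, sample = "S2"))
  gl <- site_likelihoods(ent, "A")
  cm <- call_multiallelic(gl)
  expect_length(cm$alleles, 3L)
  expect_equal(cm$af[1L], 0.5, tolerance = 0.05)
  expect_equal(sort(cm$af[-1L]), c(0.25, 0.25), tolerance = 0.05)
  gts <- vapply(cm$genotypes, `[[`, "", "gt")
  expect_setequal(unname(gts), c("0/1", "0/2"))
})

test_that("an all-hom-ref panel is suppressed (QUAL near zero)", {
  ent <- mk_entries(rep("A", 25), quals = 35L)
  cm <- call_multiallelic(site_likelihoods(ent, "A"))
  expect_true(cm$alt_is_placeholder)
  expect_lt(cm$qual, 1)
})

test_that("single-alt multiallelic agrees with consensus at matched priors", {
  # consensus priors (P(het), P(hom-alt)) = (1e-3, 5e-4) equal the HWE
  # prior at f = 1/2 scaled by theta = P(hom-alt)/P(hom-ref)
  set.seed(73)
  for (i in 1:10) {
    nref <- sample(5:20, 1L); nalt <- sample(0:20, 1L)
    ent <- mk_entries(c(rep("A", nref), rep("T", nalt)), quals = 30L)
    gl <- site_likelihoods(ent, "A")
    cc <- call_consensus(gl)
    cm <- call_multiallelic(gl, af = c(0.5, 0.5),
                            theta = 5e-4 / (1 - 1.5e-3))
    expect_equal(cm$genotypes$S$gt, cc$genotypes$S$gt)
  }
})

test_that("callers are deterministic", {
  ent <- mk_entries(rep(c("A", "T", "T"), 8), quals = 28L)
  gl <- site_likelihoods(ent, "A")
  c1 <- call_multiallelic(gl); c2 <- call_multiallelic(gl)
  expect_identical(c1, c2)
})

test_that("indel alleles are called from the column's indel evidence", {
  # het deletion: half the reads carry a 2 bp deletion after the column
  ent <- rbind(mk_entries(rep("A", 10), quals = 30L),
               mk_entries(rep("A", 10), quals = 30L, indel = -2L,
                          indel_seq = "CA"))
  gl <- site_likelihoods(ent, "A")
  expect_true("-CA" %in% gl$alleles)
  cm <- call_multiallelic(gl)
  expect_equal(cm$genotypes$S$gt, "0/1")
  # hom insertion
  ent2 <- mk_entries(rep("A", 12), quals = 30L, indel = 2L, indel_seq = "TT")
  cm2 <- call_multiallelic(site_likelihoods(ent2, "A"))
  expect_equal(cm2$genotypes$S$gt, "1/1")
  expect_equal(cm2$alleles[2L], "+TT")
})

test_that("parameter recovery on simulated HWE panels", {
  # 100 samples, 20x coverage at Q30, known allele frequencies
  set.seed(79)
  fs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  n_samples <- 100L
  conc_num <- 0L; conc_den <- 0L
  for (f in fs) {
    gts <- stats::rbinom(n_samples, 1L, f) + stats::rbinom(n_samples, 1L, f)
    ents <- list()
    for (s in seq_len(n_samples)) {
      n <- stats::rpois(1L, 20)
      if (n == 0L) n <- 1L
      p_alt <- c(1e-3, 0.5, 1 - 1e-3)[gts[s] + 1L]
      nalt <- stats::rbinom(1L, n, p_alt)
      ents[[s]] <- mk_entries(c(rep("A", n - nalt), rep("T", nalt)),
                              quals = 30L, sample = sprintf("P%03d", s))
    }
    gl <- site_likelihoods(do.call(rbind, ents), "A")
    pls <- lapply(gl$samples, function(x) .subset2(x, "pl"))
    fhat <- estimate_af_em(unname(pls), length(gl$alleles))
    expect_lt(abs(fhat[2L] - f), 0.05)
    cm <- call_multiallelic(gl)
    called <- vapply(cm$genotypes, `[[`, "", "gt")[sprintf("P%03d",
                                                           seq_len(n_samples))]
    dosage <- vapply(strsplit(called, "/"), function(g)
      sum(as.integer(g) > 0L), 0L)
    conc_num <- conc_num + sum(dosage == gts)
    conc_den <- conc_den + n_samples
  }
  expect_gte(conc_num / conc_den, 0.99)
})

test_that("gVCF blocks merge, split at bin edges and at interruptions", {
  pl <- lapply(1:5, function(i) c(0L, 30L + i, 60L))
  calls <- data.frame(chrom = "chr1", pos = 0:4,
                      gq = c(30, 30, 30, 70, 70), dp = c(10, 9, 11, 12, 10))
  calls$pl <- I(pl)
  blk <- gvcf_blocks(calls, bounds = c(1, 20, 60))
  expect_equal(nrow(blk), 2L)
  expect_equal(blk$end[1L], 2)
  expect_equal(blk$min_dp, c(9, 10))
  expect_equal(blk$pl[[1L]], c(0L, 31L, 60L))   # elementwise minimum
  # same bin throughout -> one block spanning all five sites
  calls2 <- calls; calls2$gq <- rep(30, 5)
  expect_equal(nrow(gvcf_blocks(calls2)), 1L)
  expect_equal(gvcf_blocks(calls2)$n_sites, 5L)
  # a gap (interrupting variant site removed) closes the block
  calls3 <- calls2[-3L, ]
  blk3 <- gvcf_blocks(calls3)
  expect_equal(nrow(blk3), 2L)
  expect_equal(blk3$end[1L], 1)
  # expanding blocks recovers per-site coverage exactly
  expect_equal(sum(blk3$end - blk3$start + 1), nrow(calls3))
})

test_that("PL index formula bijects with ordered genotype pairs", {
  for (n in 1:6) {
    seen <- integer(0)
    for (k in 0:(n - 1)) for (j in 0:k) {
      gi <- genotype_index(j, k)
      expect_equal(genotype_unindex(gi), c(j, k))
      seen <- c(seen, gi)
    }
    expect_equal(sort(seen), 0:(n * (n + 1) / 2 - 1))
  }
  expect_error(genotype_index(2, 1), "j <= k")
})

test_that("gVCF pipeline output covers hom-ref ground with blocks", {
  ref <- simulate_reference(4000, seed = 47)
  truth <- simulate_individuals(ref, seed = 47)
  aln <- simulate_reads(truth, depth = 15, seed = 47)
  v <- call_variants(aln$records, aln$header, ref, gvcf = TRUE)
  blocks <- v$records[v$records$alt == ".", , drop = FALSE]
  variants <- v$records[v$records$alt != ".", , drop = FALSE]
  expect_gt(nrow(blocks), 0L)
  ends <- vcf_info_get(blocks, "END", v$header)
  expect_true(all(ends >= blocks$pos + 1))
  # blocks are non-overlapping, ordered, and do not cross variant sites
  expect_true(all(blocks$pos[-1L] > ends[-length(ends)] - 1))
  for (vp in variants$pos)
    expect_false(any(blocks$pos <= vp & ends - 1 >= vp))
  # expanding blocks plus variant sites tiles the covered genome
  covered <- sum(ends - blocks$pos) + nrow(variants)
  d <- depth(aln$records)
  expect_equal(covered, nrow(d))
})
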