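# Genotype likelihoods and the two callers.
#
# Per column, each read contributes an error probability
# eps = 10^(-q/10) with q = min(base quality after BAQ, mapping quality).
# P(base | hom allele a) is 1-eps when the base equals a and eps/3
# otherwise; heterozygous genotypes average the two allele channels.
# Per-sample log-likelihoods over all diploid genotypes are scaled to
# Phred PLs (minimum 0) ordered by the standard index k(k+1)/2+j for
# genotype (j,k), j <= k.  Candidate indel alleles observed in the
# column's indel fields are scored with a flat per-read gap quality.

#' Per-sample genotype likelihoods for one pileup column
#'
#' @param entries data.frame of the column's pileup entries (one or more
#'   samples); deletion placeholder entries carry no base evidence and are
#'   ignored (the deletion itself is scored at its anchor column).
#' @param ref_base the reference base at the column.
#' @param samples sample names to report (defaults to those present);
#'   samples without data get flat likelihoods.
#' @param gap_qual flat Phred gap quality for indel allele support.
#' @return object of class `genotype_likelihoods`: list with `alleles`
#'   (REF first; `"<X>"` is the placeholder for an unobserved alternate,
#'   used when no non-reference evidence exists), and per sample `pl`
#'   (integer Phred-scaled likelihoods, min 0), `qs` (per-allele quality
#'   sums) and `dp`.
#' @export
site_likelihoods <- function(entries, ref_base, samples = NULL,
                             gap_qual = 30) {
  ref_base <- toupper(ref_base)
  b <- entries[!entries$is_del & !is.na(entries$base), , drop = FALSE]
  bases <- toupper(b$base)
  q <- pmin(b$qual, b$mapq)
  # a quality-0 base (e.g. the zeroed member of an overlapping mate pair)
  # carries no information: cap eps so every base probability is 1/4
  eps <- pmin(10^(-q / 10), 0.75)
  ind_allele <- ifelse(b$indel > 0, paste0("+", b$indel_seq),
                       ifelse(b$indel < 0, paste0("-", b$indel_seq), ""))
  alt_bases <- sort(setdiff(unique(bases[bases %in% c("A", "C", "G", "T")]),
                            ref_base))
  alt_indels <- sort(unique(ind_allele[ind_allele != ""]))
  alleles <- c(ref_base, alt_bases, alt_indels)
  if (length(alleles) == 1L) alleles <- c(alleles, "<X>")
  na <- length(alleles)
  eg <- 10^(-gap_qual / 10)
  # per-read, per-allele probability: base channel times gap channel.
  # Under a base allele, a read carrying an indel is a gap error (factor
  # eg); under an indel allele the anchor base is compared with REF and
  # the gap channel scores whether the read's indel matches.
  has_gap <- ind_allele != ""
  gap_none <- ifelse(has_gap, eg, 1 - eg)
  p_base_ref <- ifelse(bases == ref_base, 1 - eps, eps / 3)
  P <- matrix(0, nrow = nrow(b), ncol = na)
  for (a in seq_len(na)) {
    al <- alleles[a]
    P[, a] <- if (al == "<X>") eps / 3 * gap_none
    else if (al %in% c("A", "C", "G", "T"))
      ifelse(bases == al, 1 - eps, eps / 3) * gap_none
    else p_base_ref * ifelse(ind_allele == al, 1 - eg, eg)
  }
  if (is.null(samples)) samples <- sort(unique(entries$sample))
  if (!length(samples)) samples <- "SAMPLE"
  ng <- na * (na + 1) / 2
  out <- list()
  for (s in samples) {
    rows <- which(b$sample == s)
    ll <- numeric(ng)
    for (k in 0:(na - 1)) for (j in 0:k) {
      g <- genotype_index(j, k) + 1L
      ll[g] <- if (length(rows))
        sum(log10(0.5 * P[rows, j + 1L] + 0.5 * P[rows, k + 1L])) else 0
    }
    pl <- round(-10 * (ll - max(ll)))
    qs <- vapply(seq_len(na), function(a) {
      al <- alleles[a]
      supp <- if (al == "<X>") rep(FALSE, length(rows))
      else if (al %in% c("A", "C", "G", "T")) bases[rows] == al
      else ind_allele[rows] == al
      sum(q[rows][supp])
    }, 0)
    names(qs) <- alleles
    out[[s]] <- list(pl = as.integer(pl), qs = qs, dp = length(rows))
  }
  structure(list(alleles = alleles, ref = ref_base, samples = out),
            class = "genotype_likelihoods")
}

# linear-scale normalized genotype likelihoods from a PL vector
.pl_to_lik <- function(pl) {
  l <- 10^(-pl / 10)
  l / sum(l)
}

# HWE genotype prior over n alleles at frequencies f, in PL order
.hwe_prior <- function(f) {
  na <- length(f)
  pr <- numeric(na * (na + 1) / 2)
  for (k in 0:(na - 1)) for (j in 0:k)
    pr[genotype_index(j, k) + 1L] <-
      if (j == k) f[j + 1L]^2 else 2 * f[j + 1L] * f[k + 1L]
  pr
}

# subset a PL vector to the retained alleles (old 0-based indices `ord`)
.pl_subset <- function(pl, ord) {
  na <- length(ord)
  out <- integer(na * (na + 1) / 2)
  for (k in 0:(na - 1)) for (j in 0:k) {
    o <- sort(c(ord[j + 1L], ord[k + 1L]))
    out[genotype_index(j, k) + 1L] <- pl[genotype_index(o[1L], o[2L]) + 1L]
  }
  as.integer(out - min(out))
}

.phred_cap <- function(p, cap) {
  x <- -10 * log10(pmax(p, 10^(-(cap + 1) / 10)))
  pmin(round(x, 4), cap)
}

#' Biallelic consensus caller
#'
#' Considers at most one alternate allele (the non-reference allele with
#' the highest total quality sum) and a fixed genotype prior.  Per sample
#' the posterior over (hom-ref, het, hom-alt) is likelihood times prior;
#' GT is the argmax and GQ the Phred of one minus its posterior.  Site
#' QUAL is the Phred of the posterior probability that every sample is
#' hom-ref.
#'
#' @param gl a `genotype_likelihoods`.
#' @param prior_het,prior_hom_alt prior probabilities of the het and
#'   hom-alt genotypes.
#' @return object of class `site_call`: list with `alleles` (REF then any
#'   ALT), `qual`, and per-sample list `genotypes` with `gt`, `gq`, `dp`,
#'   `pl`.
#' @export
call_consensus <- function(gl, prior_het = 1e-3, prior_hom_alt = 5e-4) {
  alleles <- gl$alleles
  alts <- setdiff(alleles, c(gl$ref))
  qs_tot <- Reduce(`+`, lapply(gl$samples, `[[`, "qs"))
  real <- setdiff(alts, "<X>")
  alt <- if (length(real)) {
    o <- order(-qs_tot[real], real)
    real[o[1L]]
  } else "<X>"
  ai <- match(alt, alleles) - 1L
  prior <- c(1 - prior_het - prior_hom_alt, prior_het, prior_hom_alt)
  p_rr_all <- 1
  genos <- list()
  for (s in names(gl$samples)) {
    pl <- .pl_subset(gl$samples[[s]]$pl, c(0L, ai))
    lik <- .pl_to_lik(pl)
    post <- lik * prior
    post <- post / sum(post)
    gt_i <- which.max(post)
    genos[[s]] <- list(
      gt = c("0/0", "0/1", "1/1")[gt_i],
      gq = as.integer(min(99, round(-10 * log10(max(1 - post[gt_i], 1e-10))))),
      dp = gl$samples[[s]]$dp,
      pl = pl)
    p_rr_all <- p_rr_all * post[1L]
  }
  structure(list(alleles = c(gl$ref, if (alt != "<X>") alt),
                 alt_is_placeholder = alt == "<X>",
                 qual = .phred_cap(p_rr_all, 9999),
                 genotypes = genos),
            class = "site_call")
}

#' EM estimate of allele frequencies under Hardy-Weinberg equilibrium
#'
#' Maximizes the HWE likelihood sum_g GL(g) * HWE(g | f) over samples by
#' expectation-maximization on expected allele dosages.  The HWE
#' log-likelihood is non-decreasing across iterations (asserted).
#'
#' @param gls list of per-sample PL integer vectors (same allele set).
#' @param n_alleles number of alleles.
#' @param tol convergence tolerance on max |delta f|.
#' @param max_iter iteration cap; EM converges linearly and needs many
#'   iterations when the maximizer sits near a frequency boundary, so the
#'   cap is generous (each iteration is a handful of flops per sample).
#' @return numeric frequency vector (sums to 1, REF first).
#' @export
estimate_af_em <- function(gls, n_alleles, tol = 1e-10, max_iter = 2000L) {
  liks <- lapply(gls, .pl_to_lik)
  n <- length(liks)
  na <- n_alleles
  # allele dosage matrix: genotype x allele
  ng <- na * (na + 1) / 2
  dos <- matrix(0, ng, na)
  for (k in 0:(na - 1)) for (j in 0:k) {
    g <- genotype_index(j, k) + 1L
    dos[g, j + 1L] <- dos[g, j + 1L] + 1
    dos[g, k + 1L] <- dos[g, k + 1L] + 1
  }
  f <- rep(1 / na, na)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    pr <- .hwe_prior(f)
    ll <- 0
    acc <- numeric(na)
    for (i in seq_len(n)) {
      w <- liks[[i]] * pr
      tw <- sum(w)
      if (tw <= 0) next
      ll <- ll + log(tw)
      resp <- w / tw
      acc <- acc + as.numeric(crossprod(resp, dos))
    }
    if (ll < ll_old - 1e-9)
      stop("estimate_af_em: HWE log-likelihood decreased (internal error)")
    ll_old <- ll
    f_new <- acc / (2 * n)
    if (sum(f_new) <= 0) f_new <- rep(1 / na, na)
    f_new <- f_new / sum(f_new)
    done <- max(abs(f_new - f)) < tol
    f <- f_new
    if (done) break
  }
  f
}

#' Multiallelic caller with EM allele frequencies
#'
#' Alleles are ranked by total quality sum and at most `max_alts`
#' alternates retained; allele frequencies come from
#' [estimate_af_em()] unless supplied; per-sample posteriors over all
#' diploid genotypes are likelihood times the HWE prior at those
#' frequencies.  Alternate alleles with zero estimated frequency and no
#' supporting called genotype are dropped and PLs reordered to the final
#' allele list.  Site QUAL is the Phred of the posterior probability that
#' every sample is hom-ref.
#'
#' @param gl a `genotype_likelihoods`.
#' @param af optional user-supplied allele frequency vector (REF first,
#'   over the retained alleles); replaces the EM estimate entirely.
#' @param max_alts maximum number of alternate alleles retained.
#' @param theta prior probability that the site is variant: the prior of
#'   any genotype carrying an alternate allele is scaled by this factor,
#'   which keeps isolated sequencing errors from being called in small
#'   panels where the EM frequencies are fit to the same reads.
#' @return a `site_call` with an `af` element (frequencies of the emitted
#'   alleles).
#' @export
call_multiallelic <- function(gl, af = NULL, max_alts = 3L, theta = 1.1e-3) {
  alleles <- gl$alleles
  qs_tot <- Reduce(`+`, lapply(gl$samples, `[[`, "qs"))
  real <- setdiff(alleles, c(gl$ref, "<X>"))
  real <- real[order(-qs_tot[real], real)]
  alts <- utils::head(real, max_alts)
  placeholder <- !length(alts)
  if (placeholder) alts <- intersect("<X>", alleles)
  ord <- match(c(gl$ref, alts), alleles) - 1L
  na <- length(ord)
  pls <- lapply(gl$samples, function(s) .pl_subset(s$pl, ord))
  f <- if (!is.null(af)) {
    if (length(af) != na) stop("user allele frequencies: wrong length")
    af / sum(af)
  } else estimate_af_em(pls, na)
  pr <- .hwe_prior(f)
  for (k in 0:(na - 1)) for (j in 0:k) if (k > 0L)
    pr[genotype_index(j, k) + 1L] <- pr[genotype_index(j, k) + 1L] * theta
  p_rr_all <- 1
  genos <- list()
  gt_support <- rep(FALSE, na)
  for (s in names(gl$samples)) {
    lik <- .pl_to_lik(pls[[s]])
    post <- lik * pr
    post <- post / sum(post)
    gt_i <- which.max(post) - 1L
    jk <- genotype_unindex(gt_i)
    gt_support[jk + 1L] <- TRUE
    genos[[s]] <- list(jk = jk, post = post[gt_i + 1L], pl = pls[[s]],
                       dp = gl$samples[[s]]$dp)
    p_rr_all <- p_rr_all * post[1L]
  }
  # drop unsupported zero-frequency alts (placeholder always drops)
  keep <- c(TRUE, vapply(seq2(2L, na), function(a)
    !placeholder && (f[a] > 1e-9 || gt_support[a]), TRUE))
  kept_idx <- which(keep) - 1L
  remap <- match(seq_len(na) - 1L, kept_idx) - 1L   # old allele -> new index
  final_alleles <- c(gl$ref, alts[keep[-1L]])
  genotypes <- list()
  for (s in names(genos)) {
    jk <- genos[[s]]$jk
    nj <- remap[jk + 1L]
    gt <- if (anyNA(nj)) "./." else paste0(nj[1L], "/", nj[2L])
    genotypes[[s]] <- list(
      gt = gt,
      gq = as.integer(min(99, round(-10 * log10(max(1 - genos[[s]]$post,
                                                    1e-10))))),
      dp = genos[[s]]$dp,
      pl = if (length(kept_idx) == na) genos[[s]]$pl else
        .pl_subset(genos[[s]]$pl, kept_idx))
  }
  structure(list(alleles = final_alleles,
                 alt_is_placeholder = placeholder,
                 qual = .phred_cap(p_rr_all, 9999),
                 af = (f[keep] / sum(f[keep])),
                 genotypes = genotypes),
            class = "site_call")
}

#' Merge consecutive hom-ref calls into gVCF blocks
#'
#' Consecutive (position-adjacent, same chromosome) non-variant sites whose
#' GQ falls in the same bin merge into one block carrying END (last
#' position), MIN_DP, and a representative PL chosen elementwise as the
#' minimum across the block's sites -- the least confident choice, so a
#' block never overstates the evidence for any site it covers.
#'
#' @param calls data.frame of hom-ref per-site calls, coordinate-ordered,
#'   with columns `chrom`, `pos` (0-based), `gq`, `dp` and a list column
#'   `pl` of integer vectors.
#' @param bounds increasing GQ bin lower bounds; bins are
#'   `[0, b1), [b1, b2), ...` with the last bin open-ended.
#' @return data.frame with `chrom`, `start`, `end` (0-based inclusive),
#'   `n_sites`, `min_dp`, `gq_bin` (bin lower bound) and list column `pl`.
#' @export
gvcf_blocks <- function(calls, bounds = c(1, 20, 60)) {
  if (!nrow(calls))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_sites = integer(0),
                      min_dp = numeric(0), gq_bin = numeric(0)))
  if (any(diff(calls$pos[calls$chrom == calls$chrom[1L]]) <= 0) &&
      length(unique(calls$chrom)) == 1L)
    stop("gvcf_blocks: calls are not coordinate-ordered")
  binof <- function(gq) {
    b <- findInterval(gq, c(0, bounds))
    c(0, bounds)[b]
  }
  bins <- binof(calls$gq)
  newblk <- c(TRUE, calls$chrom[-1L] != calls$chrom[-nrow(calls)] |
                calls$pos[-1L] != calls$pos[-nrow(calls)] + 1 |
                bins[-1L] != bins[-nrow(calls)])
  grp <- cumsum(newblk)
  out <- lapply(split(seq_len(nrow(calls)), grp), function(ix) {
    pls <- calls$pl[ix]
    reppl <- if (length(pls) && !is.null(pls[[1L]]))
      as.integer(Reduce(pmin, pls)) else NULL
    if (!is.null(reppl)) reppl <- reppl - min(reppl)
    data.frame(chrom = calls$chrom[ix[1L]], start = calls$pos[ix[1L]],
               end = calls$pos[ix[length(ix)]], n_sites = length(ix),
               min_dp = min(calls$dp[ix]), gq_bin = bins[ix[1L]],
               pl = I(list(reppl)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
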