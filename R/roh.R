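# Runs-of-homozygosity HMM.
#
# Two hidden states per site: AZ (autozygous: both haplotypes identical by
# descent, so only hom-ref or hom-alt genotypes are possible, with
# probabilities (1-f) and f) and HW (non-autozygous: genotypes follow
# Hardy-Weinberg at the site's allele frequency f).  Transition
# probabilities decay with the physical distance d between consecutive
# sites as 1 - exp(-rate * d), so sparse evidence relaxes toward the
# stationary behaviour.

#' ROH HMM parameters
#'
#' @param rate_hw_to_az,rate_az_to_hw per-bp switch rates (> 0).
#' @param default_af allele frequency used for sites lacking one.
#' @param gts_only use hard genotype calls (1/0 likelihoods) instead of PL.
#' @return list of class `roh_params`.
#' @export
roh_params <- function(rate_hw_to_az = 6.7e-8, rate_az_to_hw = 5e-9,
                       default_af = 0.4, gts_only = FALSE) {
  stopifnot(rate_hw_to_az > 0, rate_az_to_hw > 0)
  structure(list(rate_hw_to_az = rate_hw_to_az, rate_az_to_hw = rate_az_to_hw,
                 default_af = default_af, gts_only = gts_only),
            class = "roh_params")
}

#' Per-site ROH emission probabilities
#'
#' @param lik length-3 numeric: genotype likelihoods (RR, RA, AA), linear
#'   scale (from PL, or 1/0 indicators from a hard GT).
#' @param f alternate allele frequency, in (0, 1).
#' @return c(az = P(data | AZ), hw = P(data | HW)).
#' @export
roh_emissions <- function(lik, f) {
  if (is.na(f) || f <= 0 || f >= 1)
    stop("roh_emissions: allele frequency must be in (0,1)")
  hw <- (1 - f)^2 * lik[1L] + 2 * f * (1 - f) * lik[2L] + f^2 * lik[3L]
  az <- (1 - f) * lik[1L] + f * lik[3L]
  c(az = az, hw = hw)
}

# distance-dependent 2x2 log transition matrices for consecutive intervals
.roh_trans <- function(dists, params) {
  p_hw_az <- 1 - exp(-params$rate_hw_to_az * dists)
  p_az_hw <- 1 - exp(-params$rate_az_to_hw * dists)
  list(az_az = log(1 - p_az_hw), az_hw = log(p_az_hw),
       hw_az = log(p_hw_az), hw_hw = log(1 - p_hw_az))
}

#' Viterbi state path for the ROH HMM
#'
#' @param pos numeric vector of 1-based site positions (sorted).
#' @param emissions n x 2 matrix, columns (az, hw).
#' @param params a `roh_params`.
#' @param init initial state probabilities c(az, hw).
#' @return integer vector of states (1 = AZ, 2 = HW).
#' @export
roh_viterbi <- function(pos, emissions, params = roh_params(),
                        init = c(0.5, 0.5)) {
  n <- length(pos)
  if (n == 0L) return(integer(0))
  if (is.unsorted(pos, strictly = FALSE))
    stop("roh_viterbi: positions are not sorted")
  le <- log(pmax(emissions, 1e-300))
  tr <- .roh_trans(diff(pos), params)
  v <- matrix(-Inf, n, 2L)
  bp <- matrix(0L, n, 2L)
  v[1L, ] <- log(init) + le[1L, ]
  for (i in seq2(2L, n)) {
    k <- i - 1L
    cand_az <- c(v[k, 1L] + tr$az_az[k], v[k, 2L] + tr$hw_az[k])
    cand_hw <- c(v[k, 1L] + tr$az_hw[k], v[k, 2L] + tr$hw_hw[k])
    bp[i, 1L] <- which.max(cand_az); v[i, 1L] <- max(cand_az) + le[i, 1L]
    bp[i, 2L] <- which.max(cand_hw); v[i, 2L] <- max(cand_hw) + le[i, 2L]
  }
  path <- integer(n)
  path[n] <- which.max(v[n, ])
  for (i in rev(seq2(2L, n))) path[i - 1L] <- bp[i, path[i]]
  path
}

#' Posterior AZ probabilities (forward-backward)
#'
#' @inheritParams roh_viterbi
#' @return list with `posterior` (per-site P(AZ | data)), `loglik_fwd`,
#'   `loglik_bwd` (these agree to numerical precision).
#' @export
roh_posterior <- function(pos, emissions, params = roh_params(),
                          init = c(0.5, 0.5)) {
  n <- length(pos)
  if (n == 0L) return(list(posterior = numeric(0), loglik_fwd = NA_real_,
                           loglik_bwd = NA_real_))
  if (is.unsorted(pos)) stop("roh_posterior: positions are not sorted")
  le <- log(pmax(emissions, 1e-300))
  tr <- .roh_trans(diff(pos), params)
  lse <- function(a, b) { m <- pmax(a, b); m + log(exp(a - m) + exp(b - m)) }
  fa <- matrix(-Inf, n, 2L)
  fa[1L, ] <- log(init) + le[1L, ]
  for (i in seq2(2L, n)) {
    k <- i - 1L
    fa[i, 1L] <- lse(fa[k, 1L] + tr$az_az[k], fa[k, 2L] + tr$hw_az[k]) + le[i, 1L]
    fa[i, 2L] <- lse(fa[k, 1L] + tr$az_hw[k], fa[k, 2L] + tr$hw_hw[k]) + le[i, 2L]
  }
  loglik_fwd <- lse(fa[n, 1L], fa[n, 2L])
  bb <- matrix(0, n, 2L)
  for (i in rev(seq2(1L, n - 1L))) {
    bb[i, 1L] <- lse(tr$az_az[i] + le[i + 1L, 1L] + bb[i + 1L, 1L],
                     tr$az_hw[i] + le[i + 1L, 2L] + bb[i + 1L, 2L])
    bb[i, 2L] <- lse(tr$hw_az[i] + le[i + 1L, 1L] + bb[i + 1L, 1L],
                     tr$hw_hw[i] + le[i + 1L, 2L] + bb[i + 1L, 2L])
  }
  loglik_bwd <- lse(log(init[1L]) + le[1L, 1L] + bb[1L, 1L],
                    log(init[2L]) + le[1L, 2L] + bb[1L, 2L])
  post <- exp(fa[, 1L] + bb[, 1L] - loglik_fwd)
  list(posterior = pmin(pmax(post, 0), 1), loglik_fwd = loglik_fwd,
       loglik_bwd = loglik_bwd)
}

#' Detect runs of homozygosity in a variant file
#'
#' Emission likelihoods come from FORMAT/PL (or hard GT calls with
#' `gts_only`); the allele frequency per site comes from INFO/AF when
#' present, else from the panel's genotypes, else `default_af` (with a
#' warning).  Monomorphic or missing-genotype sites are skipped; skipped
#' distance still contributes to transition decay because transitions use
#' physical positions of the retained sites.
#'
#' @param x a `vcf` object (biallelic sites are used; multiallelic sites
#'   are skipped).
#' @param sample sample name (default: first sample).
#' @param params a `roh_params`.
#' @param af_tag INFO tag holding the allele frequency.
#' @return data.frame of segments: `chrom`, `start`, `end` (1-based
#'   inclusive), `n_sites`, `mean_az_posterior`, `qual_posterior`
#'   (Phred of 1 - mean posterior; the Viterbi path defines the segment
#'   boundaries, the posterior its confidence), plus `n_skipped` sites as
#'   an attribute.
#' @export
roh <- function(x, sample = NULL, params = roh_params(), af_tag = "AF") {
  header <- x$header
  if (is.null(sample)) sample <- header$samples[1L]
  records <- x$records
  biall <- !grepl(",", records$alt, fixed = TRUE) & records$alt != "."
  records <- records[biall, , drop = FALSE]
  af <- rep(NA_real_, nrow(records))
  if (af_tag %in% header$info$id || any(grepl(paste0(af_tag, "="),
                                              records$info, fixed = TRUE))) {
    v <- vcf_info_get(records, af_tag, header)
    if (is.list(v)) v <- vapply(v, `[[`, 0, 1L)
    af <- suppressWarnings(as.numeric(v))
  }
  need <- is.na(af)
  if (any(need) && length(header$samples) > 1L) {
    gtm <- vcf_format_get(records[need, , drop = FALSE], "GT", header)
    gs <- parse_genotypes(gtm)
    ac <- rowSums(matrix(gs$a1 > 0L, nrow = sum(need)), na.rm = TRUE) +
      rowSums(matrix(gs$a2 > 0L, nrow = sum(need)), na.rm = TRUE)
    an <- rowSums(!is.na(matrix(gs$a1, nrow = sum(need)))) +
      rowSums(!is.na(matrix(gs$a2, nrow = sum(need))))
    af[need] <- ifelse(an > 0L, ac / an, NA_real_)
  }
  if (anyNA(af)) {
    warning(sprintf("roh: %d sites lack an allele frequency; using default %g",
                    sum(is.na(af)), params$default_af))
    af[is.na(af)] <- params$default_af
  }
  # per-site genotype likelihoods
  plm <- vcf_format_get(records, "PL", header)[, sample]
  gtm <- vcf_format_get(records, "GT", header)[, sample]
  gs <- parse_genotypes(gtm)
  n_skipped <- 0L
  keep <- logical(nrow(records))
  liks <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    lik <- NULL
    if (!params$gts_only && !is.na(plm[i])) {
      pl <- suppressWarnings(as.numeric(strsplit(plm[i], ",",
                                                 fixed = TRUE)[[1L]]))
      if (length(pl) == 3L && !anyNA(pl)) lik <- 10^(-pl / 10)
    }
    if (is.null(lik)) {
      if (is.na(gs$a1[i]) || is.na(gs$a2[i])) { n_skipped <- n_skipped + 1L; next }
      g <- sum(c(gs$a1[i], gs$a2[i]) > 0L)
      lik <- c(0, 0, 0); lik[g + 1L] <- 1
    }
    if (af[i] <= 0 || af[i] >= 1) { n_skipped <- n_skipped + 1L; next }
    keep[i] <- TRUE
    liks[[i]] <- lik
  }
  records <- records[keep, , drop = FALSE]
  af <- af[keep]; liks <- liks[keep]
  segs <- list()
  for (chrom in unique(records$chrom)) {
    ci <- which(records$chrom == chrom)
    pos <- records$pos[ci] + 1
    em <- t(vapply(seq_along(ci), function(j)
      roh_emissions(liks[[ci[j]]], af[ci[j]]), c(az = 0, hw = 0)))
    path <- roh_viterbi(pos, em, params)
    post <- roh_posterior(pos, em, params)$posterior
    runs <- rle(path)
    idx <- cumsum(runs$lengths)
    start_i <- c(1L, utils::head(idx, -1L) + 1L)
    for (r in which(runs$values == 1L)) {
      sel <- start_i[r]:idx[r]
      mp <- mean(post[sel])
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chrom, start = pos[sel[1L]], end = pos[sel[length(sel)]],
        n_sites = length(sel), mean_az_posterior = mp,
        qual_posterior = .phred_cap(max(1 - mp, 1e-10), 99))
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_sites = integer(0), mean_az_posterior = numeric(0),
               qual_posterior = numeric(0))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}
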