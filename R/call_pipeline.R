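# The two-step calling pipeline: pileup -> genotype likelihoods -> caller.
#
# Columns with only reference evidence take a closed-form fast path (their
# hom-ref PLs are sums over reads); columns showing any non-reference base
# or indel get the full likelihood model and caller.

# VCF representation of a column's allele set: the site REF spans the
# anchor base plus the longest deletion among the alleles.
.alleles_to_vcf <- function(alleles, refseq, pos) {
  dels <- alleles[startsWith(alleles, "-")]
  kmax <- if (length(dels)) max(nchar(dels)) - 1L else 0L
  site_ref <- toupper(substr(refseq, pos + 1, pos + 1 + kmax))
  refbase <- substr(site_ref, 1L, 1L)
  tail <- substr(site_ref, 2L, 1L + kmax)
  conv <- vapply(alleles, function(a) {
    if (a %in% c("A", "C", "G", "T", "N")) paste0(a, tail)
    else if (startsWith(a, "+")) paste0(refbase, substr(a, 2L, nchar(a)), tail)
    else if (startsWith(a, "-")) {
      ka <- nchar(a) - 1L
      paste0(refbase, substr(tail, ka + 1L, kmax))
    } else a
  }, "", USE.NAMES = FALSE)
  list(ref = conv[1L], alt = conv[-1L])
}

.calling_vcf_header <- function(sam_hdr, samples) {
  vcf_header(
    contigs = data.frame(name = sam_hdr$refs$name,
                         length = sam_hdr$refs$length),
    info = data.frame(
      id = c("DP", "AF", "END"),
      number = c("1", "A", "1"),
      type = c("Integer", "Float", "Integer"),
      description = c("Total read depth", "Estimated alternate allele frequency",
                      "End position of a hom-ref block (1-based inclusive)")),
    format = data.frame(
      id = c("GT", "PL", "GQ", "DP", "MIN_DP"),
      number = c("1", "G", "1", "1", "1"),
      type = c("String", "Integer", "Integer", "Integer", "Integer"),
      description = c("Genotype", "Phred-scaled genotype likelihoods",
                      "Genotype quality", "Read depth",
                      "Minimum depth in a gVCF block")),
    samples = samples)
}

#' Call variants from sorted alignments
#'
#' Runs the pileup engine and the chosen caller over every covered
#' position.  In variants-only mode a site is emitted when any sample's
#' called genotype carries an alternate allele; gVCF mode additionally
#' merges the remaining hom-ref sites into blocks (see [gvcf_blocks()]).
#'
#' @param records coordinate-sorted alignment record data.frame.
#' @param header the `sam_header`.
#' @param reference named character vector of reference sequences.
#' @param method `"multiallelic"` (EM allele frequencies under HWE) or
#'   `"consensus"` (biallelic, fixed priors).
#' @param variants_only drop sites called hom-ref in every sample.
#' @param gvcf emit hom-ref block records (implies keeping non-variant
#'   information; block PLs are reported for single-sample data).
#' @param gvcf_bounds GQ bin lower bounds for blocks.
#' @param af user-supplied allele frequencies for the multiallelic caller
#'   (replaces the EM estimate).
#' @param max_alts maximum alternate alleles retained.
#' @param theta multiallelic caller's prior on site variability.
#' @param prior_het,prior_hom_alt consensus-caller genotype priors.
#' @param ... filters passed to [pileup()] (min_mapq, min_baseq, baq,
#'   max_depth, region, ...).
#' @return a `vcf` object.
#' @export
call_variants <- function(records, header, reference,
                          method = c("multiallelic", "consensus"),
                          variants_only = TRUE, gvcf = FALSE,
                          gvcf_bounds = c(1, 20, 60), af = NULL,
                          max_alts = 3L, theta = 1.1e-3,
                          prior_het = 1e-3, prior_hom_alt = 5e-4, ...) {
  method <- match.arg(method)
  p <- pileup(records, header, reference = reference, ...)
  ent <- p$entries
  samples <- p$samples
  vhdr <- .calling_vcf_header(header, samples)
  if (!nrow(ent))
    return(structure(list(header = vhdr,
                          records = .empty_vcf_records(samples)),
                     class = "vcf"))
  refchars <- lapply(reference, function(s) strsplit(toupper(s), "")[[1L]])
  ent$refb <- vapply(seq_len(nrow(ent)), function(i) "", "")
  for (chrom in unique(ent$rname)) {
    sel <- ent$rname == chrom
    ent$refb[sel] <- refchars[[chrom]][ent$pos[sel] + 1]
  }
  ent$nonref <- ent$is_del | ent$indel != 0L |
    (!is.na(ent$base) & toupper(ent$base) != ent$refb)
  agg <- ent[, list(any_nonref = any(nonref)), by = c("rname", "pos")]
  cand <- agg[agg$any_nonref]
  candkey <- paste(cand$rname, cand$pos)
  # ---- fast path: hom-ref columns ----
  homref <- NULL
  if (!variants_only || gvcf) {
    hr <- ent[!ent$is_del & !(paste(ent$rname, ent$pos) %in% candkey)]
    if (nrow(hr)) {
      e <- pmin(10^(-pmin(hr$qual, hr$mapq) / 10), 0.75)
      hr$c1 <- 10 * (log10(1 - e) - log10(0.5 * (1 - e) + 0.5 * e / 3))
      hr$c2 <- 10 * (log10(1 - e) - log10(e / 3))
      homref <- hr[, list(dp = .N, pl1 = round(sum(c1)), pl2 = round(sum(c2))),
                   by = c("rname", "pos", "sample")]
    }
  }
  # ---- full model: candidate columns ----
  variant_rows <- list()
  homref_extra <- list()   # candidate columns called hom-ref everywhere
  if (nrow(cand)) {
    entc <- ent[paste(ent$rname, ent$pos) %in% candkey]
    splits <- split(seq_len(nrow(entc)),
                    factor(paste(entc$rname, entc$pos),
                           levels = unique(paste(entc$rname, entc$pos))))
    for (ix in splits) {
      col <- entc[ix]
      chrom <- col$rname[1L]; pos <- col$pos[1L]
      gl <- site_likelihoods(as.data.frame(col), refchars[[chrom]][pos + 1],
                             samples = samples)
      call <- if (method == "multiallelic")
        call_multiallelic(gl, af = af, max_alts = max_alts, theta = theta)
      else call_consensus(gl, prior_het = prior_het,
                          prior_hom_alt = prior_hom_alt)
      has_alt <- !call$alt_is_placeholder && length(call$alleles) > 1L &&
        any(vapply(call$genotypes, function(g)
          any(suppressWarnings(as.integer(
            strsplit(g$gt, "[/|]")[[1L]])) > 0L, na.rm = TRUE), TRUE))
      if (has_alt) {
        av <- .alleles_to_vcf(call$alleles, reference[[chrom]], pos)
        dp_tot <- sum(vapply(call$genotypes, `[[`, 0L, "dp"))
        info <- sprintf("DP=%d", dp_tot)
        if (!is.null(call$af) && length(call$af) > 1L)
          info <- paste0(info, ";AF=", paste(
            format(round(call$af[-1L], 6), scientific = FALSE, trim = TRUE),
            collapse = ","))
        rec <- data.frame(chrom = chrom, pos = pos, id = ".",
                          ref = av$ref,
                          alt = paste(av$alt, collapse = ","),
                          qual = call$qual, filter = ".",
                          info = info, format = "GT:PL:GQ:DP",
                          stringsAsFactors = FALSE)
        for (s in samples) {
          g <- call$genotypes[[s]]
          rec[[s]] <- sprintf("%s:%s:%d:%d", g$gt,
                              paste(g$pl, collapse = ","), g$gq, g$dp)
        }
        variant_rows[[length(variant_rows) + 1L]] <- rec
      } else if (!variants_only || gvcf) {
        for (s in samples) {
          g <- gl$samples[[s]]
          pl <- .pl_subset(g$pl, c(0L, match(
            if (length(gl$alleles) > 1L) gl$alleles[2L] else "<X>",
            gl$alleles) - 1L))
          homref_extra[[length(homref_extra) + 1L]] <- data.frame(
            rname = chrom, pos = pos, sample = s, dp = g$dp,
            pl1 = pl[2L], pl2 = pl[3L])
        }
      }
    }
  }
  out <- if (length(variant_rows)) do.call(rbind, variant_rows) else
    .empty_vcf_records(samples)
  # ---- gVCF blocks over the hom-ref sites ----
  if (gvcf) {
    hrall <- data.table::rbindlist(c(
      if (!is.null(homref)) list(homref) else NULL, homref_extra),
      use.names = TRUE)
    if (nrow(hrall)) {
      # per-site summaries (across samples): min GQ bins the block
      site <- hrall[, list(dp = sum(dp), gq = min(pmin(pl1, 99L)),
                           pl1 = min(pl1), pl2 = min(pl2)),
                    by = c("rname", "pos")]
      data.table::setorderv(site, c("rname", "pos"))
      calls <- data.frame(chrom = site$rname, pos = site$pos,
                          gq = site$gq, dp = site$dp)
      calls$pl <- lapply(seq_len(nrow(site)), function(i)
        c(0L, as.integer(site$pl1[i]), as.integer(site$pl2[i])))
      blocks <- gvcf_blocks(calls, bounds = gvcf_bounds)
      if (nrow(blocks)) {
        brec <- data.frame(
          chrom = blocks$chrom, pos = blocks$start, id = ".",
          ref = vapply(seq_len(nrow(blocks)), function(i)
            refchars[[blocks$chrom[i]]][blocks$start[i] + 1], ""),
          alt = ".", qual = NA_real_, filter = ".",
          info = sprintf("END=%d", as.integer(blocks$end + 1)),
          format = "GT:PL:GQ:DP:MIN_DP", stringsAsFactors = FALSE)
        for (s in samples) {
          brec[[s]] <- vapply(seq_len(nrow(blocks)), function(i) {
            pl <- blocks$pl[[i]]
            sprintf("0/0:%s:%d:%d:%d",
                    if (is.null(pl)) "." else paste(pl, collapse = ","),
                    as.integer(min(blocks$gq_bin[i] +
                                     if (blocks$gq_bin[i] >= 99) 0 else 0,
                                   99)),
                    as.integer(blocks$min_dp[i]),
                    as.integer(blocks$min_dp[i]))
          }, "")
        }
        out <- rbind(out, brec)
      }
    }
  } else if (!variants_only) {
    hrall <- data.table::rbindlist(c(
      if (!is.null(homref)) list(homref) else NULL, homref_extra),
      use.names = TRUE)
    if (nrow(hrall)) {
      site <- hrall[, list(dp = sum(dp)), by = c("rname", "pos")]
      persample <- split(as.data.frame(hrall), hrall$sample)
      srec <- data.frame(chrom = site$rname, pos = site$pos, id = ".",
                         ref = vapply(seq_len(nrow(site)), function(i)
                           refchars[[site$rname[i]]][site$pos[i] + 1], ""),
                         alt = ".", qual = NA_real_, filter = ".",
                         info = sprintf("DP=%d", site$dp),
                         format = "GT:PL:GQ:DP", stringsAsFactors = FALSE)
      key <- paste(site$rname, site$pos)
      for (s in samples) {
        ps <- persample[[s]]
        hit <- match(key, paste(ps$rname, ps$pos))
        srec[[s]] <- ifelse(is.na(hit), "./.:.:.:.",
                            sprintf("0/0:0,%d,%d:%d:%d",
                                    as.integer(ps$pl1[hit]),
                                    as.integer(ps$pl2[hit]),
                                    pmin(as.integer(ps$pl1[hit]), 99L),
                                    as.integer(ps$dp[hit])))
      }
      out <- rbind(out, srec)
    }
  }
  if (nrow(out)) {
    ord <- order(match(out$chrom, header$refs$name), out$pos)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(list(header = vhdr, records = out), class = "vcf")
}

#' Compare called variants with a truth set
#'
#' Sites are keyed by (chrom, pos, ref, alt) after biallelic decomposition
#' and (when a reference is supplied) normalization.  Recall is the
#' fraction of truth sites recovered; the false-site rate the fraction of
#' called sites absent from the truth; genotype concordance the fraction
#' of recovered truth sites whose called genotype (unordered allele
#' multiset) equals the truth genotype.
#'
#' @param called,truth `vcf` objects.
#' @param reference optional named character vector for normalization.
#' @param sample sample name present in both files (default: first truth
#'   sample).
#' @param truth_type restrict truth sites: "all", "snp", "indel".
#' @return list with `n_truth`, `n_called`, `recall`, `false_site_rate`,
#'   `concordance`, `n_compared`.
#' @export
evaluate_calls <- function(called, truth, reference = NULL, sample = NULL,
                           truth_type = "all") {
  if (is.null(sample)) sample <- truth$header$samples[1L]
  prep <- function(x) {
    r <- split_multiallelic(x$records, x$header)
    if (!is.null(reference)) r <- normalize_variants(r, reference)
    r
  }
  tr <- prep(truth)
  cr <- prep(called)
  cr <- cr[cr$alt != ".", , drop = FALSE]
  if (truth_type == "snp")
    tr <- tr[nchar(tr$ref) == 1L & nchar(tr$alt) == 1L, , drop = FALSE]
  else if (truth_type == "indel")
    tr <- tr[nchar(tr$ref) != nchar(tr$alt), , drop = FALSE]
  keyof <- function(r) paste(r$chrom, r$pos, r$ref, r$alt, sep = "\r")
  tk <- keyof(tr); ck <- keyof(cr)
  recall <- if (length(tk)) mean(tk %in% ck) else NA_real_
  false_rate <- if (length(ck)) mean(!(ck %in% tk)) else 0
  # genotype concordance at recovered truth sites, on the full (unsplit)
  # records so multiallelic genotypes compare correctly
  tfull <- truth$records; cfull <- called$records
  tkey <- paste(tfull$chrom, tfull$pos, tfull$ref, sep = "\r")
  ckey <- paste(cfull$chrom, cfull$pos, cfull$ref, sep = "\r")
  shared <- intersect(tkey, ckey)
  n_comp <- 0L; n_match <- 0L
  if (length(shared)) {
    ti <- match(shared, tkey); ci <- match(shared, ckey)
    gt_t <- vcf_format_get(tfull[ti, , drop = FALSE], "GT", truth$header)[, sample]
    gt_c <- vcf_format_get(cfull[ci, , drop = FALSE], "GT", called$header)[, sample]
    for (i in seq_along(shared)) {
      g1 <- parse_genotypes(gt_t[i]); g2 <- parse_genotypes(gt_c[i])
      if (is.na(g1$a1) || is.na(g2$a1)) next
      als <- function(rec, g) {
        a <- c(rec$ref, strsplit(rec$alt, ",", fixed = TRUE)[[1L]])
        sort(a[c(g$a1, g$a2) + 1L])
      }
      n_comp <- n_comp + 1L
      if (identical(als(tfull[ti[i], ], g1), als(cfull[ci[i], ], g2)))
        n_match <- n_match + 1L
    }
  }
  list(n_truth = length(tk), n_called = length(ck), recall = recall,
       false_site_rate = false_rate,
       concordance = if (n_comp) n_match / n_comp else NA_real_,
       n_compared = n_comp)
}
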