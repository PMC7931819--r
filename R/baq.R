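# Per-base alignment quality (BAQ).
#
# A read's base qualities describe sequencing error but not the risk that
# the base is aligned to the wrong reference column, which near indels and
# in low-complexity sequence is the dominant error mode for pileup-based
# calling.  BAQ runs a glocal profile HMM of the read against the local
# reference window (three states per column: match, insert, delete; emission
# from base quality; gap open/extension transition penalties) and converts
# the posterior probability that each base sits at its original aligned
# column into a Phred cap.  The adjusted quality is min(original, cap), so
# BAQ can only lower qualities.

# Forward-backward for one read segment against a reference window.
# y: read bases; eps: per-base error probabilities; x: window bases;
# kdiag: for each read base, its original 1-based column in the window.
# Returns per-base posterior of the original (match) column plus the
# forward and backward total log-likelihoods.
.baq_fb <- function(y, eps, x, kdiag, gap_open = 0.001, gap_ext = 0.1) {
  m <- length(y); L <- length(x)
  tMM <- 1 - 2 * gap_open; tMI <- gap_open; tMD <- gap_open
  tII <- gap_ext; tIM <- 1 - gap_ext
  tDD <- gap_ext; tDM <- 1 - gap_ext
  eI <- 0.25
  # match emission matrix rows = read index
  eM <- function(i) {
    p <- ifelse(x == "N" | y[i] == "N", 0.25,
                ifelse(x == y[i], 1 - eps[i], eps[i] / 3))
    p
  }
  powD <- tDD^(seq_len(L) - 1)   # window lengths are small; no underflow

  fM <- matrix(0, m, L); fI <- matrix(0, m, L); fD <- matrix(0, m, L)
  scale <- numeric(m)
  e1 <- eM(1L)
  fM[1L, ] <- e1 / L                       # uniform glocal entry
  fI[1L, ] <- 0
  a <- tMD * fM[1L, ]
  fD[1L, ] <- c(0, (powD[-1L] / tDD) * cumsum(a / powD)[-L])
  scale[1L] <- sum(fM[1L, ]) + sum(fI[1L, ]) + sum(fD[1L, ])
  fM[1L, ] <- fM[1L, ] / scale[1L]; fI[1L, ] <- fI[1L, ] / scale[1L]
  fD[1L, ] <- fD[1L, ] / scale[1L]
  for (i in seq2(2L, m)) {
    ei <- eM(i)
    fM[i, ] <- ei * c(0, tMM * fM[i - 1L, -L] + tIM * fI[i - 1L, -L] +
                        tDM * fD[i - 1L, -L])
    fI[i, ] <- eI * (tMI * fM[i - 1L, ] + tII * fI[i - 1L, ])
    a <- tMD * fM[i, ]
    fD[i, ] <- c(0, (powD[-1L] / tDD) * cumsum(a / powD)[-L])
    scale[i] <- sum(fM[i, ]) + sum(fI[i, ]) + sum(fD[i, ])
    fM[i, ] <- fM[i, ] / scale[i]; fI[i, ] <- fI[i, ] / scale[i]
    fD[i, ] <- fD[i, ] / scale[i]
  }
  loglik_fwd <- sum(log(scale)) + log(sum(fM[m, ]) + sum(fI[m, ]))

  bM <- matrix(0, m, L); bI <- matrix(0, m, L); bD <- matrix(0, m, L)
  bscale <- numeric(m)
  bM[m, ] <- 1; bI[m, ] <- 1
  # bD(m, k) = tDD * bD(m, k+1): no exit from D, stays 0
  bscale[m] <- 1
  for (i in rev(seq2(1L, m - 1L))) {
    en <- eM(i + 1L)
    nextM <- c(en[-1L] * bM[i + 1L, -1L], 0)   # e_M(i+1,k+1) * b_M(i+1,k+1)
    # b_D(i,k) = tDM*nextM[k] + tDD*b_D(i,k+1): reverse linear recurrence,
    # solved in closed form via a reverse cumulative sum
    g <- tDM * nextM
    bD[i, ] <- rev(cumsum(rev(g * powD))) / powD
    bI[i, ] <- tIM * nextM + tII * eI * bI[i + 1L, ]
    bM[i, ] <- tMM * nextM + tMI * eI * bI[i + 1L, ] + tMD * c(bD[i, -1L], 0)
    bscale[i] <- max(bM[i, ], bI[i, ], bD[i, ], 1e-300)
    bM[i, ] <- bM[i, ] / bscale[i]; bI[i, ] <- bI[i, ] / bscale[i]
    bD[i, ] <- bD[i, ] / bscale[i]
  }
  e1 <- eM(1L)
  loglik_bwd <- log(sum(e1 / L * bM[1L, ])) + sum(log(bscale[seq2(1L, m - 1L)]))

  # posterior that read base i is a match at its original column
  post <- numeric(m)
  logZ <- loglik_fwd
  cf <- cumsum(log(scale))
  cb <- rev(cumsum(rev(c(log(bscale[-m]), 0))))
  for (i in seq_len(m)) {
    k <- kdiag[i]
    if (k < 1L || k > L) { post[i] <- 0; next }
    lp <- log(fM[i, k]) + cf[i] + log(max(bM[i, k], 1e-300)) + cb[i] - logZ
    post[i] <- exp(min(lp, 0))
  }
  list(post = post, loglik_fwd = loglik_fwd, loglik_bwd = loglik_bwd)
}

#' Adjust base qualities with the BAQ alignment-quality HMM
#'
#' @param record one-row mapped alignment data.frame with SEQ and QUAL.
#' @param reference named character vector holding (at least) the record's
#'   reference sequence.
#' @param band window margin in bp added on both sides of the alignment;
#'   also the effective HMM band width.
#' @param gap_open,gap_ext HMM gap open/extension probabilities.
#' @return list with `qual` (integer vector of adjusted qualities, same
#'   length as the read), `cap` (the per-base Phred caps), and the forward
#'   and backward total log-likelihoods (`loglik_fwd`, `loglik_bwd`).
#' @export
baq_adjust <- function(record, reference, band = 7L, gap_open = 0.001,
                       gap_ext = 0.1) {
  if (nrow(record) != 1L) stop("baq_adjust expects a single record")
  if (has_flag(record$flag, FLAG_UNMAPPED) || record$rname == "*")
    stop("baq_adjust: record is unmapped")
  refseq <- .ref_get(reference, record$rname)
  if (is.null(refseq)) stop(sprintf("no reference sequence '%s'", record$rname))
  q0 <- .qual_ints(record$qual)
  ap <- aligned_pairs(record)
  mm <- ap[ap$op %in% c("M", "=", "X"), , drop = FALSE]
  if (!nrow(mm)) return(list(qual = q0, cap = rep(Inf, length(q0)),
                             loglik_fwd = NA_real_, loglik_bwd = NA_real_))
  rstart <- min(mm$rpos); rend <- max(mm$rpos) + 1
  wstart <- max(0, rstart - band)
  wend <- min(nchar(refseq), rend + band)
  if (wend - wstart < rend - rstart)
    stop("baq_adjust: reference window too small for the alignment band")
  x <- strsplit(toupper(substr(refseq, wstart + 1, wend)), "")[[1L]]
  # run the HMM over the aligned (non-clipped) read segment
  qidx <- ap$qpos[ap$op %in% c("M", "=", "X", "I")]
  qidx <- sort(qidx)
  y <- strsplit(toupper(record$seq), "")[[1L]][qidx + 1]
  eps <- 10^(-q0[qidx + 1] / 10)
  # original window column of each segment base (NA for inserted bases:
  # use the nearest following aligned column as the diagonal anchor)
  kmap <- rep(NA_real_, length(qidx))
  kmap[match(mm$qpos, qidx)] <- mm$rpos - wstart + 1
  for (i in rev(seq_along(kmap)))
    if (is.na(kmap[i])) kmap[i] <- if (i < length(kmap)) kmap[i + 1L] else
      length(x)
  fb <- .baq_fb(y, eps, x, as.integer(kmap), gap_open, gap_ext)
  cap <- rep(Inf, length(q0))
  p <- pmin(pmax(fb$post, 0), 1)
  capseg <- ifelse(p >= 1, Inf, -10 * log10(1 - p))
  # inserted bases have no original column: their posterior is 0 -> cap 0
  cap[qidx + 1] <- capseg
  qadj <- pmin(q0, floor(cap + 1e-9))
  list(qual = as.integer(pmax(qadj, 0L)), cap = cap,
       loglik_fwd = fb$loglik_fwd, loglik_bwd = fb$loglik_bwd)
}
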