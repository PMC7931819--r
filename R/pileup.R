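# Pileup engine: the per-position vertical slice across all reads.
#
# A pileup is represented as one long table with one row per (read, covered
# reference position) pair; a column of the pileup is the subset of rows at
# one position.  Insertions attach to the row of the preceding reference
# position (signed `indel` length plus the inserted sequence); deleted
# positions are rows with `is_del` set and no base.

#' Build a pileup from coordinate-sorted alignment records
#'
#' Each passing read contributes one entry to every reference position its
#' M/=/X and D operations cover.  Entries carry base, base quality, mapping
#' quality, strand, sample (from the read group's SM field), and the signed
#' length and sequence of any indel starting immediately after the
#' position.  The per-sample depth cap subsamples deterministically in
#' input order.
#'
#' @param records coordinate-sorted alignment record data.frame.
#' @param header `sam_header` (read groups map records to samples).
#' @param reference named character vector of reference sequences; needed
#'   for BAQ and for deletion allele sequences (otherwise deleted bases are
#'   reported as N).
#' @param min_mapq,min_baseq,exclude_flags entry filters; base entries below
#'   `min_baseq` are dropped (deletion entries are kept).
#' @param max_depth per-sample, per-position depth cap (first-come).
#' @param baq apply BAQ quality adjustment (requires `reference`).
#' @param adjust_overlaps when both mates of a pair cover a position, the
#'   lower-quality base's quality is set to 0 so the evidence is not
#'   counted twice.
#' @param default_sample sample name for records without a read group.
#' @param region optional region string restricting the pileup.
#' @return object of class `pileup`: list with `entries` (a data.table) and
#'   `samples`.
#' @export
pileup <- function(records, header, reference = NULL, min_mapq = 0L,
                   min_baseq = 0L, exclude_flags = depth_exclude_default(),
                   max_depth = 250L, baq = FALSE, adjust_overlaps = TRUE,
                   default_sample = "SAMPLE", region = NULL) {
  if (baq && is.null(reference))
    stop("BAQ requires a reference")
  if (nrow(records) > 1L) {
    blk <- cumsum(c(TRUE, records$rname[-1L] != records$rname[-nrow(records)]))
    chk <- stats::ave(records$pos, blk, FUN = function(p) c(0, diff(p)))
    if (any(chk < 0))
      stop(sprintf("pileup: input is not coordinate-sorted (record %d)",
                   which(chk < 0)[1L]))
  }
  keep <- bitwAnd(records$flag, exclude_flags) == 0L &
    records$mapq >= min_mapq & records$rname != "*" & !is.na(records$seq)
  if (!is.null(region)) {
    reg <- parse_region(region, header$refs)
    rlen <- cigar_reference_length(records$cigar)
    keep <- keep & records$rname == reg$ref & records$pos < reg$end &
      records$pos + ifelse(is.na(rlen), 1, rlen) > reg$start
  }
  rec <- records[which(keep), , drop = FALSE]
  rgmap <- header$read_groups
  rgv <- if (nrow(rgmap)) sam_tag_get(rec, "RG") else rep(NA_character_, nrow(rec))
  sample_of <- rep(default_sample, nrow(rec))
  if (nrow(rgmap)) {
    hit <- match(rgv, rgmap$id)
    sm <- rgmap$sample[hit]
    sample_of[!is.na(hit) & !is.na(sm)] <- sm[!is.na(hit) & !is.na(sm)]
  }
  pieces <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    ops <- cigar_parse(rec$cigar[i])
    if (!nrow(ops)) next
    qint <- if (!is.na(rec$qual[i])) .qual_ints(rec$qual[i]) else
      rep(30L, nchar(rec$seq[i]))
    if (baq) qint <- baq_adjust(rec[i, , drop = FALSE], reference)$qual
    bases <- strsplit(rec$seq[i], "")[[1L]]
    qp <- 0L; rp <- rec$pos[i]
    pos <- numeric(0); base <- character(0); qual <- integer(0)
    isdel <- logical(0); indel <- integer(0); iseq <- character(0)
    for (j in seq_len(nrow(ops))) {
      op <- ops$op[j]; len <- ops$len[j]
      if (op %in% c("M", "=", "X")) {
        sel <- seq_len(len)
        pos <- c(pos, rp + sel - 1); base <- c(base, bases[qp + sel])
        qual <- c(qual, qint[qp + sel]); isdel <- c(isdel, rep(FALSE, len))
        indel <- c(indel, rep(0L, len)); iseq <- c(iseq, rep("", len))
        qp <- qp + len; rp <- rp + len
      } else if (op == "I") {
        if (length(pos)) {   # attach to the preceding emitted column
          n <- length(pos)
          indel[n] <- len
          iseq[n] <- paste(bases[qp + seq_len(len)], collapse = "")
        }
        qp <- qp + len
      } else if (op == "D") {
        if (length(pos)) {
          n <- length(pos)
          indel[n] <- -len
          iseq[n] <- if (!is.null(reference) &&
                           !is.null(.ref_get(reference, rec$rname[i])))
            toupper(substr(.ref_get(reference, rec$rname[i]), rp + 1, rp + len))
          else strrep("N", len)
        }
        sel <- seq_len(len)
        pos <- c(pos, rp + sel - 1); base <- c(base, rep(NA_character_, len))
        qual <- c(qual, rep(NA_integer_, len)); isdel <- c(isdel, rep(TRUE, len))
        indel <- c(indel, rep(0L, len)); iseq <- c(iseq, rep("", len))
        rp <- rp + len
      } else if (op == "S") qp <- qp + len
      else if (op == "N") rp <- rp + len
    }
    if (!length(pos)) next
    dropb <- !isdel & qual < min_baseq
    pieces[[i]] <- data.table::data.table(
      rname = rec$rname[i], pos = pos, sample = sample_of[i],
      qname = rec$qname[i],
      strand = if (has_flag(rec$flag[i], FLAG_REVERSE)) "-" else "+",
      base = base, qual = qual, mapq = rec$mapq[i], is_del = isdel,
      indel = indel, indel_seq = iseq,
      is_start = seq_along(pos) == 1L, is_end = seq_along(pos) == length(pos)
    )[!dropb]
  }
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  ent <- if (length(pieces)) data.table::rbindlist(pieces) else
    data.table::data.table(rname = character(0), pos = numeric(0),
                           sample = character(0), qname = character(0),
                           strand = character(0), base = character(0),
                           qual = integer(0), mapq = integer(0),
                           is_del = logical(0), indel = integer(0),
                           indel_seq = character(0), is_start = logical(0),
                           is_end = logical(0))
  if (!is.null(region) && nrow(ent))
    ent <- ent[ent$pos >= reg$start & ent$pos < reg$end]
  if (nrow(ent)) {
    data.table::setorderv(ent, c("rname", "pos"))   # stable: keeps read order
    if (adjust_overlaps) {
      # both mates covering a position: zero the lower-quality base
      ent$rowid__ <- seq_len(nrow(ent))
      b <- ent[!ent$is_del]
      g <- b[, list(n = .N, r1 = rowid__[1L], r2 = rowid__[.N],
                    q1 = qual[1L], q2 = qual[.N]),
             by = c("rname", "pos", "qname")]
      g <- g[g$n == 2L]
      if (nrow(g)) {
        lose <- ifelse(g$q1 <= g$q2, g$r1, g$r2)
        ent$qual[lose] <- 0L
      }
      ent$rowid__ <- NULL
    }
    if (is.finite(max_depth)) {
      ent[, `:=`(seq__ = seq_len(.N)), by = c("rname", "pos", "sample")]
      ent <- ent[ent$seq__ <= max_depth]
      ent[, `:=`(seq__ = NULL)]
    }
  }
  structure(list(entries = ent, samples = sort(unique(c(
    sample_of, if (!nrow(rec)) default_sample)))),
    class = "pileup")
}

#' Extract one pileup column
#' @param p a `pileup`.
#' @param rname,pos reference name and 0-based position.
#' @return data.frame of the entries at that position.
#' @export
pileup_column <- function(p, rname, pos) {
  df <- as.data.frame(p$entries)
  df[df$rname == rname & df$pos == pos, , drop = FALSE]
}

#' Per-column entry counts (base entries only, the depth equivalent)
#' @param p a `pileup`.
#' @return data.frame with `rname`, `pos`, `depth`.
#' @export
pileup_depths <- function(p) {
  ent <- p$entries[!p$entries$is_del]
  if (!nrow(ent))
    return(data.frame(rname = character(0), pos = numeric(0), depth = integer(0)))
  out <- ent[, list(depth = .N), by = c("rname", "pos")]
  data.table::setorderv(out, c("rname", "pos"))
  as.data.frame(out)
}

#' Render a pileup as mpileup-style text
#'
#' One line per covered position: chrom, 1-based position, reference base
#' (N without a reference), depth (entries at the position, deletion
#' entries included), base string and quality string.  Dialect: `.`/`,`
#' match on forward/reverse strand, letters are mismatches (case by
#' strand), `*` a deleted base, `^` followed by mapq+33 marks a read start,
#' `$` a read end, and `+<n><seq>`/`-<n><seq>` an indel after the position.
#'
#' @param p a `pileup`.
#' @param reference optional named character vector.
#' @return character vector of lines.
#' @export
pileup_text <- function(p, reference = NULL) {
  ent <- p$entries
  if (!nrow(ent)) return(character(0))
  keys <- unique(ent[, c("rname", "pos")])
  lines <- character(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    e <- ent[ent$rname == keys$rname[i] & ent$pos == keys$pos[i]]
    refbase <- if (!is.null(reference) && !is.null(reference[[keys$rname[i]]]))
      toupper(substr(reference[[keys$rname[i]]], keys$pos[i] + 1,
                     keys$pos[i] + 1)) else "N"
    bs <- character(nrow(e)); qs <- character(nrow(e))
    for (j in seq_len(nrow(e))) {
      s <- if (e$is_start[j]) paste0("^", intToUtf8(pmin(e$mapq[j], 93) + 33L))
      else ""
      b <- if (e$is_del[j]) "*"
      else if (!is.null(reference) && toupper(e$base[j]) == refbase) {
        if (e$strand[j] == "+") "." else ","
      } else if (e$strand[j] == "+") toupper(e$base[j]) else tolower(e$base[j])
      ind <- if (e$indel[j] > 0L)
        paste0("+", e$indel[j], e$indel_seq[j])
      else if (e$indel[j] < 0L)
        paste0("-", -e$indel[j], e$indel_seq[j])
      else ""
      bs[j] <- paste0(s, b, ind, if (e$is_end[j]) "$" else "")
      qs[j] <- if (!e$is_del[j]) intToUtf8(pmin(e$qual[j], 93) + 33L) else "*"
    }
    lines[i] <- paste(keys$rname[i], format(keys$pos[i] + 1, scientific = FALSE),
                      refbase, nrow(e), paste(bs, collapse = ""),
                      paste(qs, collapse = ""), sep = "\t")
  }
  lines
}
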