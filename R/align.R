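# Alignment-side toolbox: filtering, sorting, merging, statistics, mate
# fixing, duplicate marking, MD/NM recalculation and FASTQ export.

.qual_ints <- function(q) utf8ToInt(q) - 33L

# M/=/X runs of one record: data.frame(rstart, qstart, len), 0-based.
.match_runs <- function(pos, cigar) {
  ops <- cigar_parse(cigar)
  qp <- 0; rp <- pos
  out <- list()
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      out[[length(out) + 1L]] <- c(rp, qp, len)
      qp <- qp + len; rp <- rp + len
    } else if (op %in% c("I", "S")) qp <- qp + len
    else if (op %in% c("D", "N")) rp <- rp + len
  }
  if (!length(out))
    return(data.frame(rstart = numeric(0), qstart = numeric(0), len = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(rstart = m[, 1L], qstart = m[, 2L], len = m[, 3L])
}

# ---- view -------------------------------------------------------------------

#' Filter alignment records
#'
#' A record is kept iff its flag contains all `required_flags` bits and none
#' of `forbidden_flags`, its MAPQ is at least `min_mapq`, it overlaps
#' `region` (when given) and its RG tag is in `read_groups` (when given).
#'
#' @param records alignment record data.frame.
#' @param required_flags,forbidden_flags integer flag masks.
#' @param min_mapq minimum mapping quality.
#' @param region region string "ref:start-end" (1-based inclusive), or NULL.
#' @param read_groups character vector of RG ids, or NULL.
#' @param header `sam_header` for region validation (optional).
#' @return the filtered data.frame.
#' @export
view_filter <- function(records, required_flags = 0L, forbidden_flags = 0L,
                        min_mapq = 0L, region = NULL, read_groups = NULL,
                        header = NULL) {
  keep <- bitwAnd(records$flag, required_flags) == required_flags &
    bitwAnd(records$flag, forbidden_flags) == 0L &
    records$mapq >= min_mapq
  if (!is.null(region)) {
    reg <- parse_region(region, if (!is.null(header)) header$refs else NULL)
    rlen <- cigar_reference_length(records$cigar)
    rlen[is.na(rlen)] <- 1
    keep <- keep & records$rname == reg$ref & records$pos < reg$end &
      records$pos + rlen > reg$start
  }
  if (!is.null(read_groups))
    keep <- keep & sam_tag_get(records, "RG") %in% read_groups
  records[which(keep), , drop = FALSE]
}

# ---- sort -------------------------------------------------------------------

# Natural (alphanumeric) queryname key: digit runs compare numerically,
# case-sensitive, shorter string first on prefix ties.  Implemented by
# zero-padding digit runs to fixed width, which makes lexicographic order
# equal natural order at any practical name length.
.natural_key <- function(x) {
  gsub("([0-9]+)", "\\1", vapply(x, function(s) {
    m <- gregexpr("[0-9]+", s)[[1L]]
    if (m[1L] == -1L) return(s)
    regmatches(s, gregexpr("[0-9]+", s)) <- lapply(
      regmatches(s, gregexpr("[0-9]+", s)),
      function(d) sprintf("%020d", as.numeric(d)))
    s
  }, ""))
}

#' Sort alignment records
#'
#' Coordinate mode orders by (reference id, position) with
#' unmapped-without-coordinate records last; queryname mode uses natural
#' alphanumeric order (digit runs compare numerically) with ties broken by
#' the first/last-of-pair flags.  Both sorts are stable.
#'
#' @param records alignment record data.frame.
#' @param mode "coordinate" or "queryname".
#' @param header optional `sam_header` providing reference order; when
#'   given, a list(header, records) with an updated sort-order field is
#'   returned, otherwise just the records.
#' @export
sort_records <- function(records, mode = c("coordinate", "queryname"),
                         header = NULL) {
  mode <- match.arg(mode)
  if (mode == "coordinate") {
    refnames <- if (!is.null(header)) header$refs$name else
      unique(records$rname[records$rname != "*"])
    rid <- match(records$rname, refnames)
    rid[is.na(rid)] <- length(refnames) + 1L   # unmapped last
    ord <- order(rid, records$pos, method = "radix")
  } else {
    key <- .natural_key(records$qname)
    pairbit <- bitwAnd(records$flag, FLAG_READ1 + FLAG_READ2)
    ord <- order(key, pairbit, method = "radix")
  }
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (is.null(header)) return(out)
  header$sort_order <- mode
  list(header = header, records = out)
}

# ---- merge ------------------------------------------------------------------

#' Merge coordinate-sorted SAM streams
#'
#' Headers are reconciled (same reference name must have the same length;
#' references keep first-appearance order), read groups are unioned with
#' duplicate ids that have conflicting sample/library renamed by appending
#' `"-<k>"` (record RG tags updated to match), and records are combined in
#' coordinate order.
#'
#' @param sams list of `list(header, records)` inputs, each
#'   coordinate-sorted.
#' @return merged `list(header, records)`.
#' @export
merge_sorted <- function(sams) {
  refs <- data.frame(name = character(0), length = numeric(0))
  rgs <- data.frame(id = character(0), sample = character(0),
                    library = character(0))
  programs <- character(0)
  recs <- list()
  for (k in seq_along(sams)) {
    h <- sams[[k]]$header
    for (i in seq_len(nrow(h$refs))) {
      j <- match(h$refs$name[i], refs$name)
      if (is.na(j)) refs <- rbind(refs, h$refs[i, ])
      else if (refs$length[j] != h$refs$length[i])
        stop(sprintf(
          "header conflict: reference '%s' has lengths %d and %d",
          h$refs$name[i], as.integer(refs$length[j]),
          as.integer(h$refs$length[i])))
    }
    r <- sams[[k]]$records
    rg <- h$read_groups
    if (nrow(rg)) for (i in seq_len(nrow(rg))) {
      j <- match(rg$id[i], rgs$id)
      if (is.na(j)) rgs <- rbind(rgs, rg[i, ])
      else if (!identical(rgs$sample[j], rg$sample[i]) ||
               !identical(rgs$library[j], rg$library[i])) {
        newid <- paste0(rg$id[i], "-", k)
        rgv <- sam_tag_get(r, "RG")
        r <- sam_tag_set(r, "RG", "Z",
                         ifelse(!is.na(rgv) & rgv == rg$id[i], newid, NA))
        rg2 <- rg[i, ]; rg2$id <- newid
        rgs <- rbind(rgs, rg2)
      }
    }
    programs <- union(programs, h$programs)
    recs[[k]] <- r
  }
  header <- sam_header(refs = refs, sort_order = "coordinate",
                       read_groups = rgs, programs = programs)
  all <- do.call(rbind, recs)
  sort_records(all, "coordinate", header)
}

# ---- flagstat / idxstats / stats -------------------------------------------

#' Flag statistics
#'
#' Counts records per category, each split into QC-pass and QC-fail by the
#' qcfail flag.  Secondary and supplementary records are counted in `total`
#' and their own categories but excluded from all pairing tallies.
#'
#' @param records alignment record data.frame.
#' @return object of class `flagstat_report`: a data.frame with columns
#'   `category`, `pass`, `fail`.
#' @export
flagstat <- function(records) {
  f <- records$flag
  fail <- has_flag(f, FLAG_QCFAIL)
  sec <- has_flag(f, FLAG_SECONDARY)
  sup <- has_flag(f, FLAG_SUPPLEMENTARY)
  primary <- !sec & !sup
  mapped <- !has_flag(f, FLAG_UNMAPPED)
  paired <- has_flag(f, FLAG_PAIRED) & primary
  tally <- function(keep) c(pass = sum(keep & !fail), fail = sum(keep & fail))
  cats <- rbind(
    total = tally(rep(TRUE, length(f))),
    secondary = tally(sec),
    supplementary = tally(sup),
    duplicates = tally(has_flag(f, FLAG_DUP)),
    mapped = tally(mapped),
    paired = tally(paired),
    read1 = tally(paired & has_flag(f, FLAG_READ1)),
    read2 = tally(paired & has_flag(f, FLAG_READ2)),
    properly_paired = tally(paired & has_flag(f, FLAG_PROPER)),
    both_mapped = tally(paired & mapped & !has_flag(f, FLAG_MUNMAPPED)),
    singletons = tally(paired & mapped & has_flag(f, FLAG_MUNMAPPED)))
  out <- data.frame(category = rownames(cats), pass = cats[, "pass"],
                    fail = cats[, "fail"], row.names = NULL)
  class(out) <- c("flagstat_report", "data.frame")
  out
}

#' @export
print.flagstat_report <- function(x, ...) {
  cat(sprintf("%d + %d %s\n", x$pass, x$fail,
              gsub("_", " ", x$category)), sep = "")
  invisible(x)
}

#' Per-reference mapped/unmapped record counts
#'
#' @param records alignment record data.frame.
#' @param header `sam_header` (references reported in header order).
#' @return data.frame with columns `name`, `length`, `mapped`, `unmapped`,
#'   ending with the unplaced (`*`) line.
#' @export
idxstats <- function(records, header) {
  mapped <- !has_flag(records$flag, FLAG_UNMAPPED) & records$rname != "*"
  out <- data.frame(name = c(header$refs$name, "*"),
                    length = c(header$refs$length, 0))
  out$mapped <- vapply(out$name, function(n)
    sum(mapped & records$rname == n), 0)
  out$mapped[out$name == "*"] <- 0
  out$unmapped <- vapply(out$name, function(n)
    sum(!mapped & records$rname == n), 0)
  rownames(out) <- NULL
  out
}

#' Basic alignment statistics
#'
#' Error rate is the NM-tag sum divided by bases mapped in M/=/X
#' operations; insert-size statistics use each proper pair once (the
#' positive-tlen side).  Secondary and supplementary records are excluded.
#'
#' @param records alignment record data.frame.
#' @return object of class `stats_report` (a list).
#' @export
stats_basic <- function(records) {
  f <- records$flag
  primary <- !has_flag(f, FLAG_SECONDARY) & !has_flag(f, FLAG_SUPPLEMENTARY)
  rec <- records[primary, , drop = FALSE]
  mapped <- !has_flag(rec$flag, FLAG_UNMAPPED)
  lens <- ifelse(is.na(rec$seq), cigar_query_length(rec$cigar), nchar(rec$seq))
  mx <- .cigar_oplen_sum(rec$cigar[mapped], "M=X")
  bases_mapped <- sum(mx, na.rm = TRUE)
  nm <- sam_tag_get(rec[mapped, , drop = FALSE], "NM")
  error_rate <- if (all(is.na(nm)) || bases_mapped == 0) NA_real_ else
    sum(nm, na.rm = TRUE) / bases_mapped
  ins <- rec$tlen[has_flag(rec$flag, FLAG_PROPER) & rec$tlen > 0]
  out <- list(raw_total_sequences = nrow(rec),
              reads_mapped = sum(mapped),
              bases_mapped = bases_mapped,
              error_rate = error_rate,
              average_length = if (length(lens)) mean(lens, na.rm = TRUE) else NA_real_,
              maximum_length = if (length(lens)) max(lens, na.rm = TRUE) else NA_real_,
              insert_size_average = if (length(ins)) mean(ins) else NA_real_,
              insert_size_sd = if (length(ins) > 1L) stats::sd(ins) else NA_real_)
  class(out) <- "stats_report"
  out
}

#' @export
print.stats_report <- function(x, ...) {
  for (n in names(x)) cat(sprintf("SN\t%s:\t%s\n", gsub("_", " ", n),
                                  format(x[[n]])))
  invisible(x)
}

# ---- depth / bedcov ---------------------------------------------------------

# default depth/pileup exclusions: unmapped | secondary | qcfail | duplicate
depth_exclude_default <- function()
  FLAG_UNMAPPED + FLAG_SECONDARY + FLAG_QCFAIL + FLAG_DUP

#' Per-position read depth
#'
#' Depth at a position counts passing reads whose aligned M/=/X bases cover
#' it; deletions and reference skips do not contribute.  Default exclusions
#' mirror common practice: unmapped, secondary, qcfail and duplicate
#' records.
#'
#' @param records coordinate-sorted alignment record data.frame.
#' @param region optional region string limiting the report.
#' @param min_mapq,min_baseq filters on mapping and base quality.
#' @param exclude_flags flag mask of records to skip.
#' @param header optional `sam_header` for region parsing.
#' @param all_positions when TRUE and a region is given, report every
#'   position of the region including zeros.
#' @return data.frame with columns `rname`, `pos` (0-based), `depth`.
#' @export
depth <- function(records, region = NULL, min_mapq = 0L, min_baseq = 0L,
                  exclude_flags = depth_exclude_default(), header = NULL,
                  all_positions = FALSE) {
  rec <- records[bitwAnd(records$flag, exclude_flags) == 0L &
                   records$mapq >= min_mapq & records$rname != "*", ,
                 drop = FALSE]
  reg <- if (!is.null(region))
    parse_region(region, if (!is.null(header)) header$refs else NULL) else NULL
  pieces <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    runs <- .match_runs(rec$pos[i], rec$cigar[i])
    if (!nrow(runs)) next
    rpos <- unlist(lapply(seq_len(nrow(runs)), function(j)
      runs$rstart[j] + seq_len(runs$len[j]) - 1))
    if (min_baseq > 0L && !is.na(rec$qual[i])) {
      qpos <- unlist(lapply(seq_len(nrow(runs)), function(j)
        runs$qstart[j] + seq_len(runs$len[j]) - 1))
      q <- .qual_ints(rec$qual[i])[qpos + 1]
      rpos <- rpos[q >= min_baseq]
    }
    if (!is.null(reg)) {
      if (rec$rname[i] != reg$ref) next
      rpos <- rpos[rpos >= reg$start & rpos < reg$end]
    }
    if (length(rpos))
      pieces[[i]] <- data.frame(rname = rec$rname[i], pos = rpos)
  }
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  tab <- if (length(pieces)) {
    dt <- data.table::rbindlist(pieces)
    agg <- dt[, list(depth = .N), by = c("rname", "pos")]
    data.table::setorderv(agg, c("rname", "pos"))
    as.data.frame(agg)
  } else data.frame(rname = character(0), pos = numeric(0), depth = integer(0))
  if (all_positions && !is.null(reg)) {
    full <- data.frame(rname = reg$ref, pos = seq2(reg$start, reg$end - 1))
    full$depth <- tab$depth[match(paste(full$rname, full$pos),
                                  paste(tab$rname, tab$pos))]
    full$depth[is.na(full$depth)] <- 0L
    return(full)
  }
  tab
}

#' Sum of per-base depth over BED intervals
#'
#' @param records coordinate-sorted alignment record data.frame.
#' @param bed data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open, the BED convention).
#' @param ... filters forwarded to [depth()].
#' @return `bed` with an added `bases` column.
#' @export
bedcov <- function(records, bed, ...) {
  if (!nrow(bed)) { bed$bases <- numeric(0); return(bed) }
  d <- depth(records, ...)
  bed$bases <- vapply(seq_len(nrow(bed)), function(i)
    sum(d$depth[d$rname == bed$chrom[i] & d$pos >= bed$start[i] &
                  d$pos < bed$end[i]]), 0)
  bed
}

# ---- fixmate ----------------------------------------------------------------

#' Synchronize mate fields within read pairs
#'
#' Input must be grouped by query name (queryname-sorted).  For each primary
#' pair the mate reference/position fields and mate-unmapped/mate-reverse
#' flags are made mutually consistent and TLEN is set to (rightmost end) -
#' (leftmost start), positive on the leftmost record, negative on the other,
#' and 0 when the mates map to different references or either is unmapped.
#'
#' @param records name-grouped alignment record data.frame.
#' @return records with mate fields rewritten.
#' @export
fixmate <- function(records) {
  if (!nrow(records)) return(records)
  grp <- cumsum(c(TRUE, records$qname[-1L] != records$qname[-nrow(records)]))
  if (anyDuplicated(records$qname[!duplicated(grp)]))
    stop("fixmate: input is not grouped by query name")
  f <- records$flag
  primary <- !has_flag(f, FLAG_SECONDARY) & !has_flag(f, FLAG_SUPPLEMENTARY) &
    has_flag(f, FLAG_PAIRED)
  for (g in split(seq_len(nrow(records)), grp)) {
    pri <- g[primary[g]]
    if (length(pri) == 1L) {   # singleton: mark mate unmapped
      i <- pri
      records$flag[i] <- bitwOr(records$flag[i], FLAG_MUNMAPPED)
      records$rnext[i] <- "*"; records$pnext[i] <- -1; records$tlen[i] <- 0
      next
    }
    if (length(pri) != 2L) next
    a <- pri[1L]; b <- pri[2L]
    for (pair in list(c(a, b), c(b, a))) {
      i <- pair[1L]; j <- pair[2L]
      jun <- has_flag(records$flag[j], FLAG_UNMAPPED)
      records$flag[i] <- bitwOr(bitwAnd(records$flag[i],
                                        bitwNot(FLAG_MUNMAPPED + FLAG_MREVERSE)),
                                (if (jun) FLAG_MUNMAPPED else 0L) +
                                  (if (has_flag(records$flag[j], FLAG_REVERSE))
                                     FLAG_MREVERSE else 0L))
      if (jun) {
        # mate fields of the mapped read point at itself; the unmapped mate
        # is placed at the mapped read's coordinate by convention
        records$rnext[i] <- "="
        records$pnext[i] <- if (!has_flag(records$flag[i], FLAG_UNMAPPED))
          records$pos[i] else records$pos[j]
      } else {
        records$rnext[i] <- if (records$rname[i] == records$rname[j] &&
                                  records$rname[i] != "*") "=" else records$rname[j]
        records$pnext[i] <- records$pos[j]
      }
    }
    aun <- has_flag(records$flag[a], FLAG_UNMAPPED)
    bun <- has_flag(records$flag[b], FLAG_UNMAPPED)
    if (!aun && !bun && records$rname[a] == records$rname[b]) {
      enda <- records$pos[a] + cigar_reference_length(records$cigar[a])
      endb <- records$pos[b] + cigar_reference_length(records$cigar[b])
      lo <- min(records$pos[a], records$pos[b])
      hi <- max(enda, endb)
      span <- hi - lo
      first_is_left <- records$pos[a] <= records$pos[b]
      records$tlen[a] <- if (first_is_left) span else -span
      records$tlen[b] <- if (first_is_left) -span else span
    } else {
      records$tlen[c(a, b)] <- 0
    }
    if (aun && !bun) records$pos[a] <- records$pos[b]
    if (bun && !aun) records$pos[b] <- records$pos[a]
  }
  records
}

# ---- markdup ----------------------------------------------------------------

#' Mark duplicate reads
#'
#' Duplicates share a key built from reference, 5'-unclipped position and
#' orientation — for pairs, the canonical (leftmost-5', orientation-pair)
#' form of both mates, so mate order never affects grouping.  Within each
#' key group the record (or pair) with the highest base-quality sum is kept
#' unflagged and all others receive the duplicate flag; secondary and
#' supplementary records inherit their primary's status.
#'
#' @param records coordinate-sorted, fixmated alignment record data.frame.
#' @return records with the duplicate flag set on duplicates.
#' @export
markdup <- function(records) {
  if (!nrow(records)) return(records)
  # order check: positions non-decreasing within each contiguous ref block
  blk <- cumsum(c(TRUE, records$rname[-1L] != records$rname[-nrow(records)]))
  chk <- stats::ave(records$pos, blk, FUN = function(p) c(0, diff(p)))
  if (any(chk < 0)) stop("markdup: input is not coordinate-sorted")
  f <- records$flag
  primary <- !has_flag(f, FLAG_SECONDARY) & !has_flag(f, FLAG_SUPPLEMENTARY)
  mapped <- !has_flag(f, FLAG_UNMAPPED)
  qsum <- ifelse(is.na(records$qual), 0,
                 vapply(records$qual, function(q)
                   if (is.na(q)) 0 else sum(.qual_ints(q)), 0, USE.NAMES = FALSE))
  u5 <- rep(NA_real_, nrow(records))
  u5[mapped] <- unclipped_5prime(records[mapped, , drop = FALSE])
  orient <- ifelse(has_flag(f, FLAG_REVERSE), "R", "F")

  idx_pri <- which(primary & mapped)
  is_pairable <- has_flag(f, FLAG_PAIRED) & !has_flag(f, FLAG_MUNMAPPED)
  dup <- logical(nrow(records))

  # paired primaries with mapped mates: group whole pairs
  pp <- idx_pri[is_pairable[idx_pri]]
  if (length(pp)) {
    byname <- split(pp, records$qname[pp])
    byname <- byname[lengths(byname) == 2L]
    if (length(byname)) {
      keys <- vapply(byname, function(ij) {
        k1 <- paste(records$rname[ij[1L]], u5[ij[1L]], orient[ij[1L]], sep = "|")
        k2 <- paste(records$rname[ij[2L]], u5[ij[2L]], orient[ij[2L]], sep = "|")
        paste(sort(c(k1, k2)), collapse = "||")
      }, "")
      scores <- vapply(byname, function(ij) sum(qsum[ij]), 0)
      for (g in split(seq_along(byname), keys)) {
        if (length(g) < 2L) next
        keep <- g[which.max(scores[g])]
        for (gi in setdiff(g, keep)) dup[byname[[gi]]] <- TRUE
      }
    }
  }

  # single-end primaries (unpaired, or mate unmapped)
  se <- idx_pri[!is_pairable[idx_pri]]
  if (length(se)) {
    keys <- paste(records$rname[se], u5[se], orient[se], sep = "|")
    for (g in split(seq_along(se), keys)) {
      if (length(g) < 2L) next
      keep <- g[which.max(qsum[se[g]])]
      for (gi in setdiff(g, keep)) dup[se[gi]] <- TRUE
    }
  }

  # secondary/supplementary inherit the status of the primary of the same
  # read (same qname and first/last-of-pair side)
  side <- bitwAnd(f, FLAG_READ1 + FLAG_READ2)
  pri_dup_key <- unique(paste(records$qname, side)[dup & primary])
  inherit <- !primary & paste(records$qname, side) %in% pri_dup_key
  dup[inherit] <- TRUE

  records$flag <- ifelse(dup, bitwOr(records$flag, FLAG_DUP), records$flag)
  records
}

# ---- calmd ------------------------------------------------------------------

#' Recompute MD and NM tags against a reference
#'
#' NM counts mismatching M/=/X bases plus inserted and deleted bases; MD
#' encodes matched-run lengths, mismatched reference bases, and
#' `^`-prefixed deleted reference runs, per the SAM optional-field standard.
#' Comparison is case-insensitive.
#'
#' @param records alignment record data.frame.
#' @param reference named character vector of reference sequences.
#' @return records with MD and NM rewritten (unmapped records untouched).
#' @export
calmd <- function(records, reference) {
  md_out <- rep(NA_character_, nrow(records))
  nm_out <- rep(NA_real_, nrow(records))
  for (i in seq_len(nrow(records))) {
    if (records$rname[i] == "*" || is.na(records$seq[i]) ||
        has_flag(records$flag[i], FLAG_UNMAPPED)) next
    refseq <- .ref_get(reference, records$rname[i])
    if (is.null(refseq)) stop(sprintf(
      "calmd: no reference sequence for '%s'", records$rname[i]))
    ops <- cigar_parse(records$cigar[i])
    qseq <- toupper(records$seq[i])
    rp <- records$pos[i]; qp <- 0
    nm <- 0; md <- character(0); run <- 0
    for (j in seq_len(nrow(ops))) {
      op <- ops$op[j]; len <- ops$len[j]
      if (op %in% c("M", "=", "X")) {
        rs <- toupper(substr(refseq, rp + 1, rp + len))
        qs <- substr(qseq, qp + 1, qp + len)
        rb <- strsplit(rs, "")[[1L]]; qb <- strsplit(qs, "")[[1L]]
        for (k in seq_len(len)) {
          if (rb[k] == qb[k]) run <- run + 1
          else {
            md <- c(md, as.character(run), rb[k]); run <- 0
            nm <- nm + 1
          }
        }
        rp <- rp + len; qp <- qp + len
      } else if (op == "I") { nm <- nm + len; qp <- qp + len }
      else if (op == "S") qp <- qp + len
      else if (op == "D") {
        md <- c(md, as.character(run),
                paste0("^", toupper(substr(refseq, rp + 1, rp + len))))
        run <- 0
        nm <- nm + len; rp <- rp + len
      } else if (op == "N") rp <- rp + len
    }
    md <- c(md, as.character(run))
    md_out[i] <- paste(md, collapse = "")
    nm_out[i] <- nm
  }
  records <- sam_tag_set(records, "NM", "i",
                         ifelse(is.na(nm_out), NA,
                                format(nm_out, scientific = FALSE, trim = TRUE)))
  sam_tag_set(records, "MD", "Z", md_out)
}

# ---- fastq ------------------------------------------------------------------

#' Export alignment records to FASTQ
#'
#' Secondary and supplementary records are excluded; reverse-flagged records
#' emit the reverse-complemented sequence with reversed qualities, restoring
#' original read orientation.
#'
#' @param records alignment record data.frame.
#' @param split_pairs when TRUE, return `list(read1, read2, other)` of FASTQ
#'   line vectors routed by the first/last-of-pair flags.
#' @return character vector of FASTQ lines (or a list, see `split_pairs`).
#' @export
to_fastq <- function(records, split_pairs = FALSE) {
  f <- records$flag
  keep <- !has_flag(f, FLAG_SECONDARY) & !has_flag(f, FLAG_SUPPLEMENTARY) &
    !is.na(records$seq)
  rec <- records[keep, , drop = FALSE]
  rev <- has_flag(rec$flag, FLAG_REVERSE)
  seqs <- ifelse(rev, revcomp(rec$seq), rec$seq)
  quals <- ifelse(is.na(rec$qual), strrep("I", nchar(seqs)), rec$qual)
  quals <- ifelse(rev, vapply(quals, function(q)
    paste(rev(strsplit(q, "")[[1L]]), collapse = ""), "", USE.NAMES = FALSE),
    quals)
  fq <- function(sel) {
    if (!any(sel)) return(character(0))
    as.vector(rbind(paste0("@", rec$qname[sel]), seqs[sel], "+", quals[sel]))
  }
  if (!split_pairs) return(fq(rep(TRUE, nrow(rec))))
  r1 <- has_flag(rec$flag, FLAG_READ1); r2 <- has_flag(rec$flag, FLAG_READ2)
  list(read1 = fq(r1), read2 = fq(r2), other = fq(!r1 & !r2))
}
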