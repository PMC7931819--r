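# SAM text alignment model and FASTA random access.
#
# Internal coordinates are 0-based half-open everywhere; conversion to the
# 1-based inclusive text conventions (SAM POS, faidx regions) happens only at
# the text boundary.  Alignment records live in a data.frame with one row per
# record; absent SEQ/QUAL are NA; tag fields are kept as their raw
# tab-joined text for lossless round trips, with typed accessors on top.

# Flag bits
FLAG_PAIRED <- 1L; FLAG_PROPER <- 2L; FLAG_UNMAPPED <- 4L
FLAG_MUNMAPPED <- 8L; FLAG_REVERSE <- 16L; FLAG_MREVERSE <- 32L
FLAG_READ1 <- 64L; FLAG_READ2 <- 128L; FLAG_SECONDARY <- 256L
FLAG_QCFAIL <- 512L; FLAG_DUP <- 1024L; FLAG_SUPPLEMENTARY <- 2048L

has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

# ---- Header -----------------------------------------------------------------

#' Construct a SAM header
#'
#' @param refs data.frame with columns `name` and `length` (bp); lengths are
#'   carried as numeric so chromosomes beyond 2 Gb are representable.
#' @param sort_order one of "unknown", "unsorted", "queryname", "coordinate".
#' @param read_groups data.frame with columns `id`, `sample`, `library`
#'   (sample/library may be NA).
#' @param programs character vector of PG line bodies (tab-joined fields
#'   after `@PG`), kept verbatim.
#' @param version SAM format version string.
#' @return an object of class `sam_header`.
#' @export
sam_header <- function(refs = data.frame(name = character(0), length = numeric(0)),
                       sort_order = "unknown",
                       read_groups = data.frame(id = character(0),
                                                sample = character(0),
                                                library = character(0)),
                       programs = character(0), version = "1.6") {
  stopifnot(sort_order %in% c("unknown", "unsorted", "queryname", "coordinate"))
  refs$name <- as.character(refs$name)
  refs$length <- as.numeric(refs$length)
  if (anyDuplicated(refs$name)) stop("duplicate reference names in header")
  if (nrow(refs) && any(refs$length < 1)) stop("reference lengths must be >= 1")
  structure(list(version = version, sort_order = sort_order, refs = refs,
                 read_groups = read_groups, programs = programs),
            class = "sam_header")
}

.hdr_field <- function(parts, tag) {
  hit <- grep(paste0("^", tag, ":"), parts, value = TRUE)
  if (length(hit)) sub(paste0("^", tag, ":"), "", hit[1L]) else NA_character_
}

#' Parse SAM header lines
#' @param lines character vector of `@`-prefixed header lines.
#' @return a `sam_header`.
#' @export
parse_sam_header <- function(lines) {
  version <- "1.6"; sort_order <- "unknown"
  refs <- list(); rgs <- list(); programs <- character(0)
  for (line in lines) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    type <- parts[1L]
    if (type == "@HD") {
      v <- .hdr_field(parts, "VN"); if (!is.na(v)) version <- v
      so <- .hdr_field(parts, "SO")
      if (!is.na(so) && so %in% c("unknown", "unsorted", "queryname", "coordinate"))
        sort_order <- so
    } else if (type == "@SQ") {
      refs[[length(refs) + 1L]] <- data.frame(
        name = .hdr_field(parts, "SN"),
        length = as.numeric(.hdr_field(parts, "LN")))
    } else if (type == "@RG") {
      rgs[[length(rgs) + 1L]] <- data.frame(
        id = .hdr_field(parts, "ID"),
        sample = .hdr_field(parts, "SM"),
        library = .hdr_field(parts, "LB"))
    } else if (type == "@PG") {
      programs <- c(programs, paste(parts[-1L], collapse = "\t"))
    }
  }
  sam_header(refs = if (length(refs)) do.call(rbind, refs) else
               data.frame(name = character(0), length = numeric(0)),
             sort_order = sort_order,
             read_groups = if (length(rgs)) do.call(rbind, rgs) else
               data.frame(id = character(0), sample = character(0),
                          library = character(0)),
             programs = programs, version = version)
}

#' Format a SAM header as text lines
#' @param header a `sam_header`.
#' @export
format_sam_header <- function(header) {
  out <- sprintf("@HD\tVN:%s\tSO:%s", header$version, header$sort_order)
  if (nrow(header$refs))
    out <- c(out, sprintf("@SQ\tSN:%s\tLN:%s", header$refs$name,
                          format(header$refs$length, scientific = FALSE,
                                 trim = TRUE)))
  if (nrow(header$read_groups)) {
    rg <- header$read_groups
    for (i in seq_len(nrow(rg))) {
      line <- sprintf("@RG\tID:%s", rg$id[i])
      if (!is.na(rg$sample[i])) line <- paste0(line, "\tSM:", rg$sample[i])
      if (!is.na(rg$library[i])) line <- paste0(line, "\tLB:", rg$library[i])
      out <- c(out, line)
    }
  }
  if (length(header$programs)) out <- c(out, paste0("@PG\t", header$programs))
  out
}

# ---- Records ----------------------------------------------------------------

.empty_sam_records <- function() {
  data.frame(qname = character(0), flag = integer(0), rname = character(0),
              pos = numeric(0), mapq = integer(0), cigar = character(0),
              rnext = character(0), pnext = numeric(0), tlen = numeric(0),
              seq = character(0), qual = character(0), tags = character(0),
              stringsAsFactors = FALSE)
}

#' Parse SAM alignment record lines
#'
#' Converts the 1-based SAM POS to the 0-based internal `pos`; `*` SEQ/QUAL
#' become NA; tag fields are preserved verbatim in `tags`.  Validation
#' enforces the field count, known reference names (when the header declares
#' any), integer flags in 0..4095, and CIGAR/SEQ length consistency; errors
#' name the offending line number.
#'
#' @param lines character vector of record lines (no header lines).
#' @param header a `sam_header` used to validate reference names.
#' @return data.frame of alignment records, one row per line.
#' @export
parse_sam_records <- function(lines, header = NULL) {
  if (!length(lines)) return(.empty_sam_records())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L))
    stop(sprintf("SAM parse error at line %d: %d fields (need >= 11)",
                 which(nf < 11L)[1L], nf[which(nf < 11L)[1L]]))
  field <- function(i) vapply(parts, `[[`, "", i)
  flag <- suppressWarnings(as.integer(field(2L)))
  bad <- which(is.na(flag) | flag < 0L | flag > 4095L)
  if (length(bad))
    stop(sprintf("SAM parse error at line %d: invalid flag '%s'",
                 bad[1L], field(2L)[bad[1L]]))
  rname <- field(3L)
  if (!is.null(header) && nrow(header$refs)) {
    unk <- which(rname != "*" & !(rname %in% header$refs$name))
    if (length(unk))
      stop(sprintf("SAM parse error at line %d: unknown reference '%s'",
                   unk[1L], rname[unk[1L]]))
  }
  seq <- field(10L); qual <- field(11L)
  seq[seq == "*"] <- NA_character_
  qual[qual == "*"] <- NA_character_
  cigar <- field(6L)
  qlen <- cigar_query_length(cigar)
  slen <- ifelse(is.na(seq), NA_real_, nchar(seq))
  bad <- which(!is.na(qlen) & !is.na(slen) & qlen != slen)
  if (length(bad))
    stop(sprintf(
      "SAM parse error at line %d: CIGAR consumes %d query bases but SEQ has %d",
      bad[1L], as.integer(qlen[bad[1L]]), as.integer(slen[bad[1L]])))
  bad <- which(!is.na(qual) & !is.na(seq) & nchar(qual) != nchar(seq))
  if (length(bad))
    stop(sprintf("SAM parse error at line %d: QUAL length differs from SEQ",
                 bad[1L]))
  tags <- vapply(parts, function(p)
    if (length(p) > 11L) paste(p[-(1:11)], collapse = "\t") else "", "")
  data.frame(qname = field(1L), flag = flag, rname = rname,
             pos = as.numeric(field(4L)) - 1, mapq = as.integer(field(5L)),
             cigar = cigar, rnext = field(7L),
             pnext = as.numeric(field(8L)) - 1,
             tlen = as.numeric(field(9L)), seq = seq, qual = qual,
             tags = tags, stringsAsFactors = FALSE)
}

#' @rdname parse_sam_records
#' @param line a single record line.
#' @export
parse_sam_record <- function(line, header = NULL) parse_sam_records(line, header)

#' Format alignment records as SAM text lines
#'
#' Inverse of [parse_sam_records()]: internal 0-based positions become
#' 1-based POS, NA SEQ/QUAL render as `*`, and tag text is appended verbatim
#' so that parse-format is the identity.
#'
#' @param records data.frame of alignment records.
#' @return character vector of SAM lines.
#' @export
format_sam_records <- function(records) {
  if (!nrow(records)) return(character(0))
  base <- paste(records$qname, records$flag, records$rname,
                format(records$pos + 1, scientific = FALSE, trim = TRUE),
                records$mapq, records$cigar, records$rnext,
                format(records$pnext + 1, scientific = FALSE, trim = TRUE),
                format(records$tlen, scientific = FALSE, trim = TRUE),
                ifelse(is.na(records$seq), "*", records$seq),
                ifelse(is.na(records$qual), "*", records$qual),
                sep = "\t")
  ifelse(records$tags == "", base, paste(base, records$tags, sep = "\t"))
}

#' @rdname format_sam_records
#' @export
format_sam_record <- function(records) format_sam_records(records)

#' Read / write a SAM file (plain text or BGZF-compressed)
#'
#' Compression is detected from the gzip magic bytes on read; on write it is
#' chosen by the `.gz` suffix or the `compress` argument.
#'
#' @param path file path.
#' @return `read_sam`: list with elements `header` (a `sam_header`) and
#'   `records` (a data.frame).
#' @export
read_sam <- function(path) {
  head2 <- readBin(path, "raw", 2L)
  lines <- if (length(head2) == 2L && head2[1L] == as.raw(0x1f) &&
               head2[2L] == as.raw(0x8b)) {
    bgzf_read_lines(path)
  } else readLines(path)
  lines <- lines[nzchar(lines)]
  is_hdr <- startsWith(lines, "@")
  list(header = parse_sam_header(lines[is_hdr]),
       records = parse_sam_records(lines[!is_hdr],
                                   parse_sam_header(lines[is_hdr])))
}

#' @rdname read_sam
#' @param sam list with `header` and `records`.
#' @param compress write BGZF-compressed output (default: path ends in .gz).
#' @param index also build and write a linear index alongside (`path.svi`);
#'   requires compressed, coordinate-sorted output.  The index is built in
#'   the same single pass that writes the file.
#' @export
write_sam <- function(sam, path, compress = grepl("\\.gz$", path),
                      index = FALSE) {
  lines <- c(format_sam_header(sam$header), format_sam_records(sam$records))
  if (compress) {
    offsets <- bgzf_write_lines(lines, path)
    if (index) {
      nh <- length(lines) - nrow(sam$records)
      rec <- sam$records
      mapped <- which(rec$rname != "*" & !has_flag(rec$flag, FLAG_UNMAPPED))
      idx <- linear_index_new(sam$header$refs$name)
      for (i in mapped) {
        rid <- match(rec$rname[i], sam$header$refs$name) - 1L
        idx <- linear_index_add(idx, rid, rec$pos[i],
                                rec$pos[i] + cigar_reference_length(rec$cigar[i]),
                                offsets[nh + i])
      }
      write_linear_index(linear_index_finish(idx), paste0(path, ".svi"))
    }
  } else {
    if (index) stop("indexing requires BGZF-compressed output")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Query a region of an indexed BGZF SAM file
#'
#' @param path BGZF SAM file written with `write_sam(..., index = TRUE)`.
#' @param region region string "ref:start-end" (1-based inclusive) or "ref".
#' @param idx optional pre-loaded `linear_index` (default: `path.svi`).
#' @return data.frame of the records overlapping the region, in file order.
#' @export
sam_query_region <- function(path, region, idx = NULL) {
  if (is.null(idx)) idx <- read_linear_index(paste0(path, ".svi"))
  reg <- parse_region(region, data.frame(name = idx$ref_names,
                                          length = Inf))
  rid <- match(reg$ref, idx$ref_names) - 1L
  extract <- function(line) {
    if (startsWith(line, "@")) return(NULL)
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (f[3L] == "*") return(NULL)
    pos <- as.numeric(f[4L]) - 1
    list(ref = match(f[3L], idx$ref_names) - 1L, start = pos,
         end = pos + cigar_reference_length(f[6L]))
  }
  lines <- bgzf_query_region(path, idx, reg$ref, reg$start, reg$end, extract)
  parse_sam_records(lines)
}

# ---- Region strings ---------------------------------------------------------

#' Parse a region string
#'
#' Accepts `"ref"`, `"ref:start-end"` or `"ref:pos"` with 1-based inclusive
#' text coordinates, returning the 0-based half-open internal interval.
#'
#' @param region region string.
#' @param refs data.frame with `name` and `length`, used for bounds and for
#'   bare-reference regions.
#' @return list with `ref`, `start`, `end` (0-based half-open).
#' @export
parse_region <- function(region, refs = NULL) {
  m <- regmatches(region,
                  regexec("^([^:]+)(:([0-9,]+)(-([0-9,]+))?)?$", region))[[1L]]
  if (!length(m)) stop(sprintf("malformed region string: '%s'", region))
  ref <- m[2L]
  if (!is.null(refs) && !(ref %in% refs$name))
    stop(sprintf("unknown reference name: %s", ref))
  if (m[3L] == "") {
    len <- if (!is.null(refs)) refs$length[match(ref, refs$name)] else Inf
    return(list(ref = ref, start = 0, end = len))
  }
  start1 <- as.numeric(gsub(",", "", m[4L], fixed = TRUE))
  end1 <- if (m[6L] != "") as.numeric(gsub(",", "", m[6L], fixed = TRUE)) else start1
  if (start1 < 1 || end1 < start1)
    stop(sprintf("malformed region string: '%s'", region))
  list(ref = ref, start = start1 - 1, end = end1)
}

# ---- Tags -------------------------------------------------------------------

#' Get an optional tag's value across records
#'
#' Tags of type `i` and `f` are returned numeric, all others as character.
#' Records lacking the tag give NA.  Unknown tag types are preserved as
#' text.
#'
#' @param records alignment record data.frame.
#' @param key two-character tag name.
#' @return vector of values, one per record.
#' @export
sam_tag_get <- function(records, key) {
  pre <- paste0(key, ":")
  entries <- strsplit(records$tags, "\t", fixed = TRUE)
  out <- vapply(entries, function(e) {
    hit <- e[startsWith(e, pre)]
    if (length(hit)) hit[1L] else NA_character_
  }, "")
  type <- substr(out, 4L, 4L)
  val <- substr(out, 6L, nchar(out))
  if (all(is.na(type) | type %in% c("i", "f"))) as.numeric(val) else val
}

#' Set (or replace) an optional tag on records
#'
#' @param records alignment record data.frame.
#' @param key two-character tag name.
#' @param type SAM tag type letter (A, i, f, Z, H, B).
#' @param values vector of values (NA leaves the record untouched).
#' @return records with updated `tags`, insertion order preserved and new
#'   tags appended.
#' @export
sam_tag_set <- function(records, key, type, values) {
  pat <- paste0("(^|\t)", key, ":[^\t]*")
  stripped <- gsub(pat, "\\1", records$tags)
  stripped <- gsub("\t+", "\t", gsub("^\t|\t$", "", stripped))
  newtag <- ifelse(is.na(values), NA_character_,
                   paste0(key, ":", type, ":", values))
  records$tags <- ifelse(is.na(newtag), records$tags,
                         ifelse(stripped == "", newtag,
                                paste(stripped, newtag, sep = "\t")))
  records
}

# ---- CIGAR ------------------------------------------------------------------

#' Parse a CIGAR string into operations
#' @param cigar CIGAR string (`"*"` gives a zero-row result).
#' @return data.frame with columns `op` (character) and `len` (numeric).
#' @export
cigar_parse <- function(cigar) {
  if (is.na(cigar) || cigar == "*")
    return(data.frame(op = character(0), len = numeric(0)))
  lens <- as.numeric(strsplit(cigar, "[MIDNSHP=X]")[[1L]])
  ops <- strsplit(gsub("[0-9]+", "", cigar), "")[[1L]]
  if (length(ops) != length(lens) || any(is.na(lens)) || any(lens < 1) ||
      !all(ops %in% c("M", "I", "D", "N", "S", "H", "P", "=", "X")))
    stop(sprintf("malformed CIGAR: '%s'", cigar))
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

# Vectorized query/reference lengths implied by CIGAR strings ("*" -> NA).
.cigar_oplen_sum <- function(cigars, opset) {
  out <- rep(NA_real_, length(cigars))
  todo <- which(!is.na(cigars) & cigars != "*")
  if (!length(todo)) return(out)
  pat <- paste0("[0-9]+[", opset, "]")
  hits <- regmatches(cigars[todo], gregexpr(pat, cigars[todo]))
  out[todo] <- vapply(hits, function(h)
    sum(as.numeric(sub(".$", "", h))), 0)
  out
}

#' Query and reference lengths consumed by CIGAR strings
#'
#' Query-consuming ops are M, I, S, =, X; reference-consuming ops are M, D,
#' N, =, X.  Vectorized; `"*"` yields NA.
#'
#' @param cigars character vector of CIGAR strings.
#' @export
cigar_query_length <- function(cigars) .cigar_oplen_sum(cigars, "MIS=X")

#' @rdname cigar_query_length
#' @export
cigar_reference_length <- function(cigars) .cigar_oplen_sum(cigars, "MDN=X")

#' Walk a record's alignment, pairing query and reference coordinates
#'
#' M/=/X operations emit both coordinates, I/S query only, D/N reference
#' only; H and P consume neither and emit nothing.  Coordinates are 0-based.
#'
#' @param record one-row alignment data.frame (mapped, with a CIGAR).
#' @return data.frame with columns `qpos` (query index or NA), `rpos`
#'   (reference position or NA) and `op`.
#' @export
aligned_pairs <- function(record) {
  if (nrow(record) != 1L) stop("aligned_pairs expects a single record")
  if (record$rname == "*" || has_flag(record$flag, FLAG_UNMAPPED))
    stop("aligned_pairs: record is unmapped")
  ops <- cigar_parse(record$cigar)
  if (!nrow(ops)) stop("aligned_pairs: record has no CIGAR")
  qp <- 0; rp <- record$pos
  qout <- rout <- numeric(0); opout <- character(0)
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      qout <- c(qout, qp + seq_len(len) - 1)
      rout <- c(rout, rp + seq_len(len) - 1)
      opout <- c(opout, rep(op, len))
      qp <- qp + len; rp <- rp + len
    } else if (op %in% c("I", "S")) {
      qout <- c(qout, qp + seq_len(len) - 1)
      rout <- c(rout, rep(NA_real_, len))
      opout <- c(opout, rep(op, len))
      qp <- qp + len
    } else if (op %in% c("D", "N")) {
      qout <- c(qout, rep(NA_real_, len))
      rout <- c(rout, rp + seq_len(len) - 1)
      opout <- c(opout, rep(op, len))
      rp <- rp + len
    }
  }
  data.frame(qpos = qout, rpos = rout, op = opout, stringsAsFactors = FALSE)
}

# 5'-unclipped start position (0-based) used by duplicate marking: for a
# forward read, pos minus leading clips; for a reverse read, the alignment
# end plus trailing clips, minus 1.
unclipped_5prime <- function(records) {
  out <- numeric(nrow(records))
  rev <- has_flag(records$flag, FLAG_REVERSE)
  lead <- suppressWarnings(as.numeric(
    sub("^([0-9]+)[SH].*$", "\\1", records$cigar)))
  lead[!grepl("^[0-9]+[SH]", records$cigar)] <- 0
  trail <- suppressWarnings(as.numeric(
    sub("^.*?([0-9]+)[SH]$", "\\1", records$cigar)))
  trail[!grepl("[0-9]+[SH]$", records$cigar)] <- 0
  rlen <- cigar_reference_length(records$cigar)
  out[!rev] <- records$pos[!rev] - lead[!rev]
  out[rev] <- records$pos[rev] + rlen[rev] - 1 + trail[rev]
  out
}

# ---- FASTA / faidx ----------------------------------------------------------

#' Read / write a FASTA file as a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("not a FASTA file: no '>' header lines")
  names_ <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    paste(lines[seq2(starts[i], ends[i])], collapse = ""), "")
  names(seqs) <- names_
  seqs
}

seq2 <- function(a, b) if (b < a) integer(0) else seq.int(a, b)

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @param width bases per line.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Build a FASTA index (faidx)
#'
#' Records, for each sequence, its length, the byte offset of its first
#' base, and the bases/bytes per body line, enabling O(1) retrieval of any
#' subsequence.  Body lines must have uniform length within a sequence
#' (except the last).
#'
#' @param path FASTA file.
#' @return data.frame (class `fasta_index`) with columns `name`, `length`,
#'   `offset`, `linebases`, `linewidth` — the standard 5-column .fai layout.
#' @export
faidx_build <- function(path) {
  data <- readBin(path, "raw", file.size(path))
  txt <- rawToChar(data)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  # byte offset of each line start (newlines are single bytes)
  lens <- nchar(lines, type = "bytes")
  offs <- c(0, cumsum(lens + 1))[seq_along(lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("not a FASTA file: no '>' header lines")
  out <- list()
  for (i in seq_along(hdr)) {
    name <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr[i]])
    body <- seq2(hdr[i] + 1L, if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines))
    body <- body[nzchar(lines[body])]
    if (!length(body)) {
      out[[i]] <- data.frame(name = name, length = 0, offset = offs[hdr[i]] +
                               lens[hdr[i]] + 1, linebases = 0, linewidth = 1)
      next
    }
    blens <- lens[body]
    if (length(body) > 1L && any(blens[-length(body)] != blens[1L])) {
      badline <- body[which(blens[-length(body)] != blens[1L])[1L]]
      stop(sprintf("ragged FASTA body in sequence '%s' at line %d",
                   name, badline))
    }
    if (length(body) > 1L && blens[length(body)] > blens[1L])
      stop(sprintf("ragged FASTA body in sequence '%s' at line %d",
                   name, body[length(body)]))
    out[[i]] <- data.frame(name = name, length = sum(blens),
                           offset = offs[body[1L]],
                           linebases = blens[1L], linewidth = blens[1L] + 1)
  }
  idx <- do.call(rbind, out)
  class(idx) <- c("fasta_index", "data.frame")
  idx
}

#' @rdname faidx_build
#' @param idx a `fasta_index`.
#' @export
write_fai <- function(idx, path) {
  writeLines(sprintf("%s\t%s\t%s\t%s\t%s", idx$name,
                     format(idx$length, scientific = FALSE, trim = TRUE),
                     format(idx$offset, scientific = FALSE, trim = TRUE),
                     format(idx$linebases, scientific = FALSE, trim = TRUE),
                     format(idx$linewidth, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' @rdname faidx_build
#' @export
read_fai <- function(path) {
  d <- utils::read.table(path, sep = "\t", col.names = c(
    "name", "length", "offset", "linebases", "linewidth"),
    colClasses = c("character", rep("numeric", 4L)))
  class(d) <- c("fasta_index", "data.frame")
  d
}

#' Fetch a subsequence from an indexed FASTA file
#'
#' @param path FASTA file.
#' @param idx its `fasta_index` (built if NULL).
#' @param region region string `"name:start-end"`, 1-based inclusive, or a
#'   bare sequence name for the whole sequence.
#' @return the sequence substring (case preserved).
#' @export
faidx_fetch <- function(path, region, idx = NULL) {
  if (is.null(idx)) idx <- faidx_build(path)
  reg <- parse_region(region, data.frame(name = idx$name, length = idx$length))
  row <- idx[match(reg$ref, idx$name), ]
  start0 <- reg$start
  end <- if (is.finite(reg$end)) reg$end else row$length
  if (start0 >= row$length || end > row$length)
    stop(sprintf("region '%s' out of range for sequence '%s' (length %d)",
                 region, reg$ref, as.integer(row$length)))
  # byte offset of base i (0-based): offset + (i %/% linebases) * linewidth
  #                                          + i %% linebases
  first <- row$offset + (start0 %/% row$linebases) * row$linewidth +
    start0 %% row$linebases
  nbases <- end - start0
  # read enough bytes to cover the bases plus interleaved newlines
  span <- ((end - 1) %/% row$linebases) * row$linewidth +
    (end - 1) %% row$linebases - ((start0 %/% row$linebases) * row$linewidth +
                                    start0 %% row$linebases) + 1
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, where = first)
  chunk <- rawToChar(readBin(con, "raw", span))
  gsub("\n", "", chunk, fixed = TRUE)
}


# safe lookup in a named character vector of sequences (NULL when absent)
.ref_get <- function(reference, name) {
  if (is.na(match(name, names(reference)))) NULL else reference[[name]]
}

#' Reverse-complement a DNA sequence
#' @param seq character vector of sequences (IUPAC letters, case preserved).
#' @export
revcomp <- function(seq) {
  chartr("ACGTUacgtuRYKMrykmBDHVbdhv",
         "TGCAAtgcaaYRMKyrmkVHDBvhdb",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "")[[1L]]), collapse = ""), "",
           USE.NAMES = FALSE))
}
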