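# BGZF block compression and the linear coordinate index.
#
# BGZF is a blockwise variant of gzip: a file is a series of standard gzip
# members, each carrying a "BC" extra subfield holding the total block size,
# terminated by a fixed 28-byte empty block (the EOF sentinel).  Because each
# block is independently decompressible, a (compressed offset, within-block
# offset) pair -- a "virtual offset" -- addresses any byte of the
# uncompressed stream, which is what makes random access possible.

BGZF_MAX_BLOCK <- 65536L
LINEAR_WINDOW_SHIFT <- 14L   # 16 kb windows, the tabix/BAI convention

# The canonical 28-byte empty-block EOF marker.
BGZF_EOF <- as.raw(c(
  0x1f, 0x8b, 0x08, 0x04, 0x00, 0x00, 0x00, 0x00, 0x00, 0xff,
  0x06, 0x00, 0x42, 0x43, 0x02, 0x00, 0x1b, 0x00, 0x03, 0x00,
  0x00, 0x00, 0x00, 0x00, 0x00, 0x00, 0x00, 0x00))

# ---- CRC32 (gzip trailer) ---------------------------------------------------

.crc32_table <- local({
  tab <- integer(256L)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L)
        bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1L))
      else
        bitwShiftR(bitwAnd(c, -2L), 1L)
    }
    tab[i + 1L] <- c
  }
  tab
})

.crc32 <- function(raw) {
  crc <- -1L
  if (length(raw)) {
    bytes <- as.integer(raw)
    tab <- .crc32_table
    for (b in bytes) {
      crc <- bitwXor(tab[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                     bitwShiftR(bitwAnd(crc, -256L), 8L))
    }
  }
  as.numeric(bitwXor(crc, -1L)) %% 2^32
}

.u16le <- function(v) as.raw(c(v %% 256, v %/% 256))
.u32le <- function(v) {
  v <- as.numeric(v) %% 2^32
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
           (v %/% 16777216) %% 256))
}
.rd_u16le <- function(r, at) as.integer(r[at]) + 256L * as.integer(r[at + 1L])
.rd_u32le <- function(r, at) {
  sum(as.numeric(r[at + 0:3]) * c(1, 256, 65536, 16777216))
}

# Raw deflate body of a payload.  memCompress(type = "gzip") emits a zlib
# stream (2-byte header, 4-byte Adler32 trailer); both are stripped here.
.deflate_raw <- function(payload) {
  z <- memCompress(payload, type = "gzip")
  z[seq.int(3L, length(z) - 4L)]
}

.bgzf_block1 <- function(payload) {
  defl <- .deflate_raw(payload)
  bsize <- 12L + 6L + length(defl) + 8L   # header + XLEN extra + body + trailer
  if (bsize > 65536L) return(NULL)        # incompressible chunk: caller splits
  c(as.raw(c(0x1f, 0x8b, 0x08, 0x04, 0x00, 0x00, 0x00, 0x00, 0x00, 0xff,
             0x06, 0x00, 0x42, 0x43, 0x02, 0x00)),
    .u16le(bsize - 1L),
    defl,
    .u32le(.crc32(payload)),
    .u32le(length(payload)))
}

# Emit one or more blocks for a chunk, halving on compressed-size overflow
# (incompressible data can deflate to more than 64 KB per member).
.bgzf_block <- function(payload) {
  blk <- .bgzf_block1(payload)
  if (!is.null(blk)) return(blk)
  half <- length(payload) %/% 2L
  c(.bgzf_block(payload[seq_len(half)]),
    .bgzf_block(payload[seq.int(half + 1L, length(payload))]))
}

#' Compress a byte payload into a BGZF stream
#'
#' Splits `payload` into chunks of at most `block_size` uncompressed bytes,
#' compresses each chunk into a standard-conformant gzip member carrying the
#' BGZF "BC" extra subfield, and appends the fixed 28-byte end-of-file
#' sentinel block.  An empty payload yields exactly the sentinel.
#'
#' @param payload raw vector to compress.
#' @param block_size maximum uncompressed bytes per block (1..65536).
#' @return raw vector holding the BGZF stream.
#' @export
bgzf_compress <- function(payload, block_size = BGZF_MAX_BLOCK) {
  stopifnot(is.raw(payload))
  if (block_size < 1L || block_size > BGZF_MAX_BLOCK)
    stop("block_size must be in 1..65536")
  n <- length(payload)
  if (n == 0L) return(BGZF_EOF)
  starts <- seq.int(1L, n, by = block_size)
  blocks <- lapply(starts, function(s)
    .bgzf_block(payload[seq.int(s, min(n, s + block_size - 1L))]))
  c(do.call(c, blocks), BGZF_EOF)
}

# Parse one gzip member header starting at byte offset `at` (1-based).
# Returns list(hdr_len, bsize or NA).  BGZF members carry BSIZE in the BC
# extra subfield; plain gzip members do not and must be rejected upstream.
.gzip_member_info <- function(data, at) {
  n <- length(data)
  if (at + 9L > n) stop(sprintf("truncated gzip header at offset %d", at - 1L))
  if (data[at] != as.raw(0x1f) || data[at + 1L] != as.raw(0x8b))
    stop(sprintf("malformed gzip member at offset %d: bad magic", at - 1L))
  flg <- as.integer(data[at + 3L])
  pos <- at + 10L
  bsize <- NA_real_
  if (bitwAnd(flg, 4L) == 4L) {  # FEXTRA
    xlen <- .rd_u16le(data, pos)
    xend <- pos + 2L + xlen
    p <- pos + 2L
    while (p < xend) {
      si <- rawToChar(data[p + 0:1])
      slen <- .rd_u16le(data, p + 2L)
      if (si == "BC" && slen == 2L) bsize <- .rd_u16le(data, p + 4L) + 1
      p <- p + 4L + slen
    }
    pos <- xend
  }
  if (bitwAnd(flg, 8L) == 8L)   # FNAME
    pos <- pos + which(data[pos:n] == as.raw(0L))[1L]
  if (bitwAnd(flg, 16L) == 16L) # FCOMMENT
    pos <- pos + which(data[pos:n] == as.raw(0L))[1L]
  if (bitwAnd(flg, 2L) == 2L)   # FHCRC
    pos <- pos + 2L
  list(hdr_len = pos - at, bsize = bsize)
}

#' Decompress a BGZF stream
#'
#' Walks the gzip members of `data`, decompresses each, and returns the
#' concatenated payload (the EOF sentinel contributes nothing).  A stream
#' that does not end with the sentinel block is decompressed as far as
#' possible and reported with a truncation warning, so partial files remain
#' inspectable.
#'
#' @param data raw vector holding a BGZF stream.
#' @return raw vector with the uncompressed payload.
#' @export
bgzf_decompress <- function(data) {
  stopifnot(is.raw(data))
  n <- length(data)
  out <- list()
  at <- 1L
  saw_eof <- FALSE
  while (at <= n) {
    info <- .gzip_member_info(data, at)
    if (is.na(info$bsize))
      stop(sprintf("gzip member at offset %d lacks the BGZF BC subfield", at - 1L))
    end <- at + info$bsize - 1L
    if (end > n) stop(sprintf("truncated BGZF block at offset %d", at - 1L))
    member <- data[at:end]
    if (info$bsize == 28 && identical(member, BGZF_EOF)) {
      saw_eof <- at + 28L > n   # sentinel only counts as EOF when final
      at <- end + 1L
      next
    }
    payload <- memDecompress(member, type = "gzip")
    isize <- .rd_u32le(data, end - 3L)
    if (length(payload) != isize)
      stop(sprintf("BGZF block at offset %d: ISIZE mismatch", at - 1L))
    out[[length(out) + 1L]] <- payload
    at <- end + 1L
  }
  if (!saw_eof)
    warning("BGZF stream is truncated: end-of-file sentinel block missing")
  if (length(out)) do.call(c, out) else raw(0)
}

# ---- Virtual offsets --------------------------------------------------------

#' Pack and unpack BGZF virtual offsets
#'
#' A virtual offset addresses one byte of the uncompressed stream as
#' `coffset * 2^16 + uoffset`, where `coffset` is the byte offset of the
#' containing block in the compressed file and `uoffset` the offset within
#' that block's payload.  Packed values sort in file order.  Values are
#' carried as doubles (exact up to 2^53, ample for any desk-scale file).
#'
#' @param coffset compressed (block start) byte offset, >= 0.
#' @param uoffset within-block payload offset, 0..65535.
#' @return `pack_virtual_offset`: numeric packed offset.
#'   `unpack_virtual_offset`: list with `coffset` and `uoffset`.
#' @export
pack_virtual_offset <- function(coffset, uoffset) {
  if (any(uoffset < 0 | uoffset >= 65536))
    stop("uoffset must be in 0..65535")
  if (any(coffset < 0)) stop("coffset must be >= 0")
  as.numeric(coffset) * 65536 + as.numeric(uoffset)
}

#' @rdname pack_virtual_offset
#' @param packed numeric packed virtual offset.
#' @export
unpack_virtual_offset <- function(packed) {
  packed <- as.numeric(packed)
  list(coffset = packed %/% 65536, uoffset = packed %% 65536)
}

# ---- Linear index -----------------------------------------------------------

# A linear index maps, per reference, each 16 kb genome window w to the
# smallest virtual offset of any record whose interval overlaps window w or
# any later window.  Because records are position-sorted and virtual offsets
# increase in file order, that smallest offset belongs to the first record in
# file order whose interval reaches window w; the array is non-decreasing.

.win <- function(pos) pos %/% bitwShiftL(1L, LINEAR_WINDOW_SHIFT)

#' Build a linear index from a position-sorted record stream
#'
#' Single pass; suitable for building the index concurrently with writing.
#' `records` is a data.frame with columns `ref` (integer id, 0-based or any
#' consistent coding), `start`, `end` (0-based half-open) and `voffset`
#' (packed virtual offset of the record's first byte), sorted by
#' (ref, start).
#'
#' @param records data.frame as described above.
#' @param ref_names character vector naming the references, in id order.
#' @return an object of class `linear_index`.
#' @export
build_linear_index <- function(records, ref_names = NULL) {
  idx <- linear_index_new(ref_names)
  if (nrow(records)) {
    for (i in seq_len(nrow(records)))
      idx <- linear_index_add(idx, records$ref[i], records$start[i],
                              records$end[i], records$voffset[i])
  }
  linear_index_finish(idx)
}

#' @rdname build_linear_index
#' @export
linear_index_new <- function(ref_names = NULL) {
  structure(list(windows = list(), ref_names = ref_names,
                 last_ref = -1L, last_start = -1, maxwin = -1L),
            class = "linear_index")
}

#' @rdname build_linear_index
#' @param idx a `linear_index` under construction.
#' @param ref,start,end,voffset one record's reference id, 0-based half-open
#'   interval, and packed virtual offset.
#' @export
linear_index_add <- function(idx, ref, start, end, voffset) {
  ref <- as.integer(ref)
  if (ref < idx$last_ref || (ref == idx$last_ref && start < idx$last_start))
    stop(sprintf(
      "unsorted record: ref %d pos %d after ref %d pos %d",
      ref, as.integer(start), idx$last_ref, as.integer(idx$last_start)))
  if (ref != idx$last_ref) idx$maxwin <- -1L
  key <- as.character(ref)
  if (is.null(idx$windows[[key]])) idx$windows[[key]] <- numeric(0)
  we <- .win(max(start, end - 1))
  if (we > idx$maxwin) {
    arr <- idx$windows[[key]]
    arr[(idx$maxwin + 2L):(we + 1L)] <- voffset
    idx$windows[[key]] <- arr
    idx$maxwin <- we
  }
  idx$last_ref <- ref
  idx$last_start <- start
  idx
}

#' @rdname build_linear_index
#' @export
linear_index_finish <- function(idx) {
  idx$last_ref <- idx$last_start <- idx$maxwin <- NULL
  idx
}

# First virtual offset at which a record overlapping [start, end) can occur,
# or NA when the index proves no record reaches that far.
linear_index_lookup <- function(idx, ref, start) {
  arr <- idx$windows[[as.character(as.integer(ref))]]
  w <- .win(start)
  if (is.null(arr) || w >= length(arr)) return(NA_real_)
  arr[w + 1L]
}

#' Serialize a linear index
#'
#' Flat binary layout: magic "SVLI1"; uint32 reference count; then per
#' reference a uint16 name length, the name bytes, a uint32 window count and
#' that many packed virtual offsets as little-endian uint64 (two uint32
#' words, low word first).
#'
#' @param idx a finished `linear_index`.
#' @param path file to write.
#' @export
write_linear_index <- function(idx, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("SVLI1"), con)
  keys <- names(idx$windows)
  nm <- idx$ref_names
  writeBin(.u32le(length(keys)), con)
  for (key in keys) {
    name <- if (!is.null(nm)) nm[as.integer(key) + 1L] else key
    nb <- charToRaw(name)
    writeBin(.u16le(length(nb)), con)
    writeBin(nb, con)
    arr <- idx$windows[[key]]
    writeBin(.u32le(length(arr)), con)
    for (v in arr) {
      writeBin(.u32le(v %% 2^32), con)
      writeBin(.u32le(v %/% 2^32), con)
    }
  }
  invisible(path)
}

#' @rdname write_linear_index
#' @return `read_linear_index`: the `linear_index` object.
#' @export
read_linear_index <- function(path) {
  data <- readBin(path, "raw", file.size(path))
  if (length(data) < 9L || rawToChar(data[1:5]) != "SVLI1")
    stop("not a linear index file (bad magic)")
  at <- 6L
  nref <- .rd_u32le(data, at); at <- at + 4L
  windows <- list()
  ref_names <- character(0)
  for (i in seq_len(nref)) {
    nl <- .rd_u16le(data, at); at <- at + 2L
    name <- rawToChar(data[at:(at + nl - 1L)]); at <- at + nl
    nw <- .rd_u32le(data, at); at <- at + 4L
    arr <- numeric(nw)
    for (j in seq_len(nw)) {
      lo <- .rd_u32le(data, at); hi <- .rd_u32le(data, at + 4L)
      arr[j] <- hi * 2^32 + lo
      at <- at + 8L
    }
    windows[[as.character(i - 1L)]] <- arr
    ref_names[i] <- name
  }
  structure(list(windows = windows, ref_names = ref_names),
            class = "linear_index")
}

# ---- BGZF text lines with virtual offsets ----------------------------------

#' Write text lines to a BGZF file, reporting per-line virtual offsets
#'
#' Each line is terminated with a newline.  The returned offsets are the
#' packed virtual offsets of each line's first byte, which is what a linear
#' index stores; blocks are flushed so no line's start crosses a block
#' boundary unnecessarily.
#'
#' @param lines character vector.
#' @param path output file.
#' @param block_size maximum uncompressed bytes per block.
#' @return numeric vector of packed virtual offsets, one per line, invisibly.
#' @export
bgzf_write_lines <- function(lines, path, block_size = BGZF_MAX_BLOCK) {
  con <- file(path, "wb")
  on.exit(close(con))
  coffset <- 0
  buf <- raw(0)
  offsets <- numeric(length(lines))
  flush_block <- function() {
    if (!length(buf)) return(invisible())
    blk <- .bgzf_block(buf)
    writeBin(blk, con)
    coffset <<- coffset + length(blk)
    buf <<- raw(0)
  }
  for (i in seq_along(lines)) {
    bytes <- charToRaw(paste0(lines[i], "\n"))
    if (length(buf) + length(bytes) > block_size) flush_block()
    offsets[i] <- pack_virtual_offset(coffset, length(buf))
    # a single line longer than block_size spans multiple blocks
    while (length(buf) + length(bytes) > block_size) {
      take <- block_size - length(buf)
      buf <- c(buf, bytes[seq_len(take)])
      bytes <- bytes[-seq_len(take)]
      flush_block()
    }
    buf <- c(buf, bytes)
    if (length(buf) >= block_size) flush_block()
  }
  flush_block()
  writeBin(BGZF_EOF, con)
  invisible(offsets)
}

#' Read text lines from a BGZF file, optionally starting at a virtual offset
#'
#' @param path BGZF file.
#' @param voffset packed virtual offset to start at (default: file start).
#' @return character vector of lines.
#' @export
bgzf_read_lines <- function(path, voffset = 0) {
  data <- readBin(path, "raw", file.size(path))
  vo <- unpack_virtual_offset(voffset)
  if (vo$coffset > 0) data <- data[-seq_len(vo$coffset)]
  payload <- bgzf_decompress(data)
  if (vo$uoffset > 0) payload <- payload[-seq_len(vo$uoffset)]
  if (!length(payload)) return(character(0))
  txt <- rawToChar(payload)
  strsplit(txt, "\n", fixed = TRUE)[[1L]]
}

#' Query a region of an indexed, position-sorted BGZF record file
#'
#' Generic driver shared by SAM and VCF region queries: seeks to the
#' index-provided virtual offset for the query window, then scans records,
#' keeping those whose interval overlaps `[start, end)` and stopping at the
#' first record starting at or beyond `end`.  Results are identical to a
#' full linear scan with an overlap filter.
#'
#' @param path BGZF file of newline-terminated records.
#' @param idx `linear_index` for the file.
#' @param ref reference name.
#' @param start,end 0-based half-open query interval.
#' @param extract function(line) -> list(ref = id, start =, end =) used to
#'   interpret each record line (records with NULL result are skipped).
#' @return character vector of matching record lines.
#' @export
bgzf_query_region <- function(path, idx, ref, start, end, extract) {
  rid <- match(ref, idx$ref_names) - 1L
  if (is.na(rid)) stop(sprintf("unknown reference name: %s", ref))
  v0 <- linear_index_lookup(idx, rid, start)
  if (is.na(v0)) return(character(0))
  lines <- bgzf_read_lines(path, v0)
  keep <- character(0)
  for (line in lines) {
    info <- extract(line)
    if (is.null(info)) next
    if (info$ref != rid) { if (info$ref > rid) break else next }
    if (info$start >= end) break
    if (info$end > start) keep[length(keep) + 1L] <- line
  }
  keep
}
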