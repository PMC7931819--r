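# VCF data model and text I/O.
#
# Internal positions are 0-based (converted at the text boundary); records
# live in a data.frame with the fixed columns chrom, pos, id, ref, alt,
# qual, filter, info, format followed by one character column per sample.
# INFO and per-sample fields stay as text for lossless round trips; typed
# accessors decode them against the header's declarations.

#' Construct a VCF header
#'
#' @param contigs data.frame with `name`, `length`.
#' @param info,format,filter data.frames declaring fields: columns `id`,
#'   `number` (an integer count, or "A", "R", "G", "."), `type` (Integer,
#'   Float, Flag, Character, String) and `description` (filter: `id`,
#'   `description`).
#' @param samples ordered character vector of sample names.
#' @param fileformat version string.
#' @param other verbatim extra `##` lines, kept for round trips.
#' @return object of class `vcf_header`.
#' @export
vcf_header <- function(contigs = data.frame(name = character(0),
                                            length = numeric(0)),
                       info = NULL, format = NULL, filter = NULL,
                       samples = character(0), fileformat = "VCFv4.3",
                       other = character(0)) {
  empty_def <- data.frame(id = character(0), number = character(0),
                          type = character(0), description = character(0))
  if (is.null(info)) info <- empty_def
  if (is.null(format)) format <- empty_def
  if (is.null(filter)) filter <- data.frame(id = character(0),
                                            description = character(0))
  for (d in list(info, format, filter))
    if (anyDuplicated(d$id)) stop("duplicate ids in a header section")
  structure(list(fileformat = fileformat, contigs = contigs, info = info,
                 format = format, filter = filter, samples = samples,
                 other = other),
            class = "vcf_header")
}

.vcf_meta_fields <- function(body) {
  # parse ID=..,Number=..,Type=..,Description=".." (commas inside quotes kept)
  m <- regmatches(body, gregexpr('[A-Za-z]+=("[^"]*"|[^,>]*)', body))[[1L]]
  kv <- strsplit(m, "=", fixed = FALSE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(m, function(s) sub("^[A-Za-z]+=", "", s), "", USE.NAMES = FALSE)
  vals <- gsub('^"|"$', "", vals)
  stats::setNames(vals, keys)
}

#' Parse VCF header lines
#' @param lines the `##` lines plus the final `#CHROM` line.
#' @return a `vcf_header`.
#' @export
parse_vcf_header <- function(lines) {
  fileformat <- "VCFv4.3"
  contigs <- list(); info <- list(); format <- list(); filter <- list()
  other <- character(0); samples <- character(0)
  for (line in lines) {
    if (startsWith(line, "##fileformat=")) {
      fileformat <- sub("^##fileformat=", "", line)
    } else if (startsWith(line, "##contig=<")) {
      f <- .vcf_meta_fields(sub("^##contig=<", "", sub(">$", "", line)))
      contigs[[length(contigs) + 1L]] <- data.frame(
        name = f[["ID"]],
        length = if ("length" %in% names(f)) as.numeric(f[["length"]]) else NA_real_)
    } else if (grepl("^##(INFO|FORMAT)=<", line)) {
      sec <- if (startsWith(line, "##INFO")) "info" else "format"
      f <- .vcf_meta_fields(sub("^##(INFO|FORMAT)=<", "", sub(">$", "", line)))
      row <- data.frame(id = f[["ID"]], number = f[["Number"]],
                        type = f[["Type"]],
                        description = if ("Description" %in% names(f))
                          f[["Description"]] else "")
      if (sec == "info") info[[length(info) + 1L]] <- row
      else format[[length(format) + 1L]] <- row
    } else if (startsWith(line, "##FILTER=<")) {
      f <- .vcf_meta_fields(sub("^##FILTER=<", "", sub(">$", "", line)))
      filter[[length(filter) + 1L]] <- data.frame(
        id = f[["ID"]], description = if ("Description" %in% names(f))
          f[["Description"]] else "")
    } else if (startsWith(line, "#CHROM")) {
      f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      if (length(f) > 9L) samples <- f[10:length(f)]
    } else if (startsWith(line, "##")) {
      other <- c(other, line)
    }
  }
  bindor <- function(x, empty) if (length(x)) do.call(rbind, x) else empty
  vcf_header(
    contigs = bindor(contigs, data.frame(name = character(0),
                                         length = numeric(0))),
    info = bindor(info, NULL), format = bindor(format, NULL),
    filter = bindor(filter, NULL),
    samples = samples, fileformat = fileformat, other = other)
}

#' Format a VCF header as text lines
#' @param header a `vcf_header`.
#' @export
format_vcf_header <- function(header) {
  out <- paste0("##fileformat=", header$fileformat)
  if (nrow(header$contigs))
    out <- c(out, ifelse(
      is.na(header$contigs$length),
      sprintf("##contig=<ID=%s>", header$contigs$name),
      sprintf("##contig=<ID=%s,length=%s>", header$contigs$name,
              format(header$contigs$length, scientific = FALSE, trim = TRUE))))
  fmtdef <- function(sec, d) sprintf(
    "##%s=<ID=%s,Number=%s,Type=%s,Description=\"%s\">",
    sec, d$id, d$number, d$type, d$description)
  if (nrow(header$filter))
    out <- c(out, sprintf("##FILTER=<ID=%s,Description=\"%s\">",
                          header$filter$id, header$filter$description))
  if (nrow(header$info)) out <- c(out, fmtdef("INFO", header$info))
  if (nrow(header$format)) out <- c(out, fmtdef("FORMAT", header$format))
  out <- c(out, header$other)
  chrom <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t")
  if (length(header$samples))
    chrom <- paste(c(chrom, "FORMAT", header$samples), collapse = "\t")
  c(out, chrom)
}

.empty_vcf_records <- function(samples = character(0)) {
  d <- data.frame(chrom = character(0), pos = numeric(0), id = character(0),
                  ref = character(0), alt = character(0), qual = numeric(0),
                  filter = character(0), info = character(0),
                  format = character(0), stringsAsFactors = FALSE)
  for (s in samples) d[[s]] <- character(0)
  d
}

#' Parse VCF record lines
#'
#' The 1-based POS becomes the 0-based internal `pos`.  In strict mode the
#' declared Number arity of every INFO and FORMAT field is validated
#' (A = one per alt, R = one per allele, G = one per diploid genotype) and
#' undeclared ids or unknown chromosomes are errors; in lenient mode
#' undeclared ids are auto-declared (Number ".", Type String) with a
#' warning.
#'
#' @param lines record lines.
#' @param header a `vcf_header` (may be updated in lenient mode; the
#'   possibly-extended header is attached to the result as attribute
#'   `"header"`).
#' @param strict logical.
#' @return data.frame of records.
#' @export
parse_vcf_records <- function(lines, header, strict = FALSE) {
  if (!length(lines)) return(.empty_vcf_records(header$samples))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  need <- 8L + if (length(header$samples)) 1L + length(header$samples) else 0L
  bad <- which(nf < need)
  if (length(bad))
    stop(sprintf("VCF parse error at line %d: %d fields (need %d)",
                 bad[1L], nf[bad[1L]], need))
  field <- function(i) vapply(parts, `[[`, "", i)
  chrom <- field(1L)
  if (nrow(header$contigs)) {
    unk <- which(!(chrom %in% header$contigs$name))
    if (length(unk)) {
      msg <- sprintf("unknown chromosome '%s' at line %d",
                     chrom[unk[1L]], unk[1L])
      if (strict) stop(paste("VCF parse error:", msg)) else warning(msg)
    }
  }
  pos1 <- suppressWarnings(as.numeric(field(2L)))
  if (anyNA(pos1))
    stop(sprintf("VCF parse error at line %d: unparseable POS",
                 which(is.na(pos1))[1L]))
  qualf <- field(6L)
  qual <- suppressWarnings(as.numeric(qualf))
  badq <- which(is.na(qual) & qualf != ".")
  if (length(badq))
    stop(sprintf("VCF parse error at line %d: unparseable QUAL '%s'",
                 badq[1L], qualf[badq[1L]]))
  d <- data.frame(chrom = chrom, pos = pos1 - 1, id = field(3L),
                  ref = field(4L), alt = field(5L), qual = qual,
                  filter = field(7L), info = field(8L),
                  format = if (length(header$samples)) field(9L) else
                    NA_character_,
                  stringsAsFactors = FALSE)
  for (si in seq_along(header$samples))
    d[[header$samples[si]]] <- field(9L + si)
  hdr2 <- .vcf_validate(d, header, strict)
  attr(d, "header") <- hdr2
  d
}

# arity/declaration validation; returns a (possibly extended) header
.vcf_validate <- function(d, header, strict) {
  n_alt <- ifelse(d$alt == ".", 0L,
                  lengths(strsplit(d$alt, ",", fixed = TRUE)))
  expect_n <- function(number, nalt) {
    switch(number,
           A = nalt, R = nalt + 1L,
           G = (nalt + 1L) * (nalt + 2L) / 2L,
           "." = NA_integer_,
           suppressWarnings(as.integer(number)))
  }
  check_typed <- function(vals, def, line, what) {
    if (def$type %in% c("Integer", "Float")) {
      v <- suppressWarnings(as.numeric(vals[vals != "."]))
      if (anyNA(v))
        stop(sprintf("VCF parse error at line %d: %s/%s is not numeric",
                     line, what, def$id))
    }
  }
  declare <- function(header, sec, id) {
    if (strict)
      stop(sprintf("VCF parse error: undeclared %s field '%s'",
                   toupper(sec), id))
    warning(sprintf("auto-declaring undeclared %s field '%s'",
                    toupper(sec), id))
    header[[sec]] <- rbind(header[[sec]],
                           data.frame(id = id, number = ".", type = "String",
                                      description = "(auto-declared)"))
    header
  }
  for (i in seq_len(nrow(d))) {
    if (d$info[i] != ".") {
      for (kv in strsplit(d$info[i], ";", fixed = TRUE)[[1L]]) {
        eq <- regexpr("=", kv, fixed = TRUE)
        key <- if (eq > 0) substr(kv, 1, eq - 1) else kv
        di <- match(key, header$info$id)
        if (is.na(di)) { header <- declare(header, "info", key); next }
        def <- header$info[di, ]
        if (def$type == "Flag") next
        vals <- strsplit(substr(kv, eq + 1, nchar(kv)), ",", fixed = TRUE)[[1L]]
        en <- expect_n(def$number, n_alt[i])
        if (strict && !is.na(en) && length(vals) != en)
          stop(sprintf(
            "VCF parse error at line %d: INFO/%s has %d values, expected %d",
            i, key, length(vals), en))
        if (strict) check_typed(vals, def, i, "INFO")
      }
    }
    if (!is.na(d$format[i]) && d$format[i] != ".") {
      keys <- strsplit(d$format[i], ":", fixed = TRUE)[[1L]]
      for (key in keys) {
        if (key == "GT") next
        di <- match(key, header$format$id)
        if (is.na(di)) { header <- declare(header, "format", key); next }
        if (strict) {
          def <- header$format[di, ]
          en <- expect_n(def$number, n_alt[i])
          ki <- match(key, keys)
          for (s in header$samples) {
            sv <- strsplit(d[[s]][i], ":", fixed = TRUE)[[1L]]
            if (ki > length(sv)) next   # trailing fields may be dropped
            if (sv[ki] == ".") next
            vals <- strsplit(sv[ki], ",", fixed = TRUE)[[1L]]
            if (!is.na(en) && length(vals) != en)
              stop(sprintf(
                "VCF parse error at line %d: FORMAT/%s for sample %s has %d values, expected %d",
                i, key, s, length(vals), en))
            check_typed(vals, def, i, "FORMAT")
          }
        }
      }
    }
  }
  header
}

#' Format VCF records as text lines
#'
#' Inverse of [parse_vcf_records()]: numbers render in their shortest
#' round-trip form, missing values as `.`.
#'
#' @param records VCF record data.frame.
#' @param header the `vcf_header` (supplies the sample order).
#' @return character vector of lines.
#' @export
format_vcf_records <- function(records, header) {
  if (!nrow(records)) return(character(0))
  qual <- ifelse(is.na(records$qual), ".",
                 vapply(records$qual, function(q)
                   if (is.na(q)) "." else format(q, scientific = FALSE,
                                                 trim = TRUE, digits = 10),
                   "", USE.NAMES = FALSE))
  base <- paste(records$chrom,
                format(records$pos + 1, scientific = FALSE, trim = TRUE),
                records$id, records$ref, records$alt, qual, records$filter,
                records$info, sep = "\t")
  if (length(header$samples)) {
    base <- paste(base, records$format, sep = "\t")
    for (s in header$samples) base <- paste(base, records[[s]], sep = "\t")
  }
  base
}

#' @rdname format_vcf_records
#' @export
format_vcf_record <- format_vcf_records

#' @rdname parse_vcf_records
#' @param line single record line.
#' @export
parse_vcf_record <- function(line, header, strict = FALSE)
  parse_vcf_records(line, header, strict)

#' Read / write a VCF file (plain text or BGZF-compressed)
#'
#' @param path file path; compression detected from the gzip magic on
#'   read, chosen by a `.gz` suffix or `compress` on write.
#' @param strict strict parsing mode (see [parse_vcf_records()]).
#' @return `read_vcf`: object of class `vcf`: list(header, records).
#' @export
read_vcf <- function(path, strict = FALSE) {
  head2 <- readBin(path, "raw", 2L)
  lines <- if (length(head2) == 2L && head2[1L] == as.raw(0x1f) &&
               head2[2L] == as.raw(0x8b)) bgzf_read_lines(path)
  else readLines(path)
  lines <- lines[nzchar(lines)]
  is_hdr <- startsWith(lines, "#")
  header <- parse_vcf_header(lines[is_hdr])
  records <- parse_vcf_records(lines[!is_hdr], header, strict)
  header <- attr(records, "header")
  attr(records, "header") <- NULL
  structure(list(header = header, records = records), class = "vcf")
}

#' @rdname read_vcf
#' @param x a `vcf` object (list with `header` and `records`).
#' @param compress write BGZF output.
#' @param index also write a linear index (`path.svi`); requires
#'   compressed, position-sorted output.
#' @export
write_vcf <- function(x, path, compress = grepl("\\.gz$", path),
                      index = FALSE) {
  lines <- c(format_vcf_header(x$header),
             format_vcf_records(x$records, x$header))
  if (compress) {
    offsets <- bgzf_write_lines(lines, path)
    if (index) {
      nh <- length(lines) - nrow(x$records)
      refnames <- if (nrow(x$header$contigs)) x$header$contigs$name else
        unique(x$records$chrom)
      idx <- linear_index_new(refnames)
      for (i in seq_len(nrow(x$records))) {
        rid <- match(x$records$chrom[i], refnames) - 1L
        idx <- linear_index_add(idx, rid, x$records$pos[i],
                                x$records$pos[i] + nchar(x$records$ref[i]),
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

#' Query a region of an indexed BGZF VCF file
#'
#' A record overlaps the region if the interval covered by its REF allele
#' does.
#'
#' @param path indexed BGZF VCF.
#' @param region region string (1-based inclusive).
#' @param idx optional pre-loaded `linear_index`.
#' @return a `vcf` object with the overlapping records.
#' @export
vcf_query_region <- function(path, region, idx = NULL) {
  if (is.null(idx)) idx <- read_linear_index(paste0(path, ".svi"))
  x <- read_vcf(path)   # header comes from the file
  reg <- parse_region(region, data.frame(name = idx$ref_names, length = Inf))
  extract <- function(line) {
    if (startsWith(line, "#")) return(NULL)
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    pos <- as.numeric(f[2L]) - 1
    list(ref = match(f[1L], idx$ref_names) - 1L, start = pos,
         end = pos + nchar(f[4L]))
  }
  lines <- bgzf_query_region(path, idx, reg$ref, reg$start, reg$end, extract)
  records <- parse_vcf_records(lines, x$header)
  attr(records, "header") <- NULL
  structure(list(header = x$header, records = records), class = "vcf")
}

# ---- typed accessors --------------------------------------------------------

#' Get a typed INFO field across records
#'
#' @param records VCF record data.frame.
#' @param key INFO id.
#' @param header the `vcf_header` (typing); Flag fields give logicals,
#'   Integer/Float numerics, multi-valued fields a list.
#' @export
vcf_info_get <- function(records, key, header = NULL) {
  def <- if (!is.null(header)) header$info[match(key, header$info$id), ] else NULL
  raw <- vapply(strsplit(records$info, ";", fixed = TRUE), function(kvs) {
    hit <- kvs[kvs == key | startsWith(kvs, paste0(key, "="))]
    if (!length(hit)) NA_character_
    else if (hit[1L] == key) "TRUE"
    else sub("^[^=]*=", "", hit[1L])
  }, "")
  if (!is.null(def) && !is.na(def$type) && def$type == "Flag")
    return(!is.na(raw))
  numeric_type <- !is.null(def) && !is.na(def$type) &&
    def$type %in% c("Integer", "Float")
  multi <- grepl(",", raw, fixed = TRUE)
  if (any(multi, na.rm = TRUE)) {
    vals <- strsplit(raw, ",", fixed = TRUE)
    if (numeric_type) lapply(vals, function(v)
      if (length(v) == 1L && is.na(v)) NA_real_ else as.numeric(v))
    else vals
  } else if (numeric_type) suppressWarnings(as.numeric(raw)) else raw
}

#' Set (or remove) an INFO field on records
#'
#' @param records VCF record data.frame.
#' @param key INFO id.
#' @param values character vector of formatted values (NA removes the
#'   field; "" sets a bare Flag).
#' @export
vcf_info_set <- function(records, key, values) {
  set1 <- function(info, v) {
    kvs <- strsplit(info, ";", fixed = TRUE)[[1L]]
    kvs <- kvs[!(kvs == key | startsWith(kvs, paste0(key, "=")))]
    kvs <- kvs[kvs != "."]
    if (!is.na(v)) kvs <- c(kvs, if (v == "") key else paste0(key, "=", v))
    if (!length(kvs)) "." else paste(kvs, collapse = ";")
  }
  records$info <- vapply(seq_len(nrow(records)), function(i)
    set1(records$info[i], values[i]), "")
  records
}

#' Get a FORMAT field as a sample-by-record character matrix
#'
#' @param records VCF record data.frame.
#' @param key FORMAT id.
#' @param header the `vcf_header` (sample list).
#' @return character matrix, rows = records, columns = samples; missing
#'   values are NA.
#' @export
vcf_format_get <- function(records, key, header) {
  out <- matrix(NA_character_, nrow(records), length(header$samples),
                dimnames = list(NULL, header$samples))
  if (!nrow(records)) return(out)
  fkeys <- strsplit(records$format, ":", fixed = TRUE)
  for (si in seq_along(header$samples)) {
    svals <- strsplit(records[[header$samples[si]]], ":", fixed = TRUE)
    out[, si] <- vapply(seq_len(nrow(records)), function(i) {
      ki <- match(key, fkeys[[i]])
      if (is.na(ki) || ki > length(svals[[i]])) NA_character_
      else svals[[i]][ki]
    }, "")
  }
  out[out == "."] <- NA_character_
  out
}

#' Parse GT strings into allele index pairs
#'
#' @param gt character vector/matrix of GT strings (`"0/1"`, `"1|0"`, `"."`).
#' @return list with `a1`, `a2` (integer allele indexes, NA for missing)
#'   and `phased` (logical), all shaped like `gt`.
#' @export
parse_genotypes <- function(gt) {
  shape <- dim(gt)
  g <- as.character(gt)
  phased <- grepl("|", g, fixed = TRUE)
  partsplit <- strsplit(g, "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(partsplit, function(p)
    if (length(p) >= 1L) p[1L] else NA_character_, "")))
  a2 <- suppressWarnings(as.integer(vapply(partsplit, function(p)
    if (length(p) >= 2L) p[2L] else NA_character_, "")))
  if (!is.null(shape)) {
    dim(a1) <- shape; dim(a2) <- shape; dim(phased) <- shape
    dn <- dimnames(gt)
    dimnames(a1) <- dimnames(a2) <- dimnames(phased) <- dn
  }
  list(a1 = a1, a2 = a2, phased = phased)
}

# ---- PL genotype ordering ---------------------------------------------------

#' Diploid genotype PL index and its inverse
#'
#' Genotype (j, k) with allele indexes j <= k sits at PL index
#' k(k+1)/2 + j; for n alleles there are n(n+1)/2 genotypes, a quadratic
#' growth that dominates multi-allelic sites with many samples.
#'
#' @param j,k 0-based allele indexes, j <= k.
#' @return `genotype_index`: the 0-based PL index.
#' @export
genotype_index <- function(j, k) {
  if (any(j > k)) stop("genotype_index requires j <= k")
  if (any(j < 0)) stop("allele indexes are non-negative")
  k * (k + 1) / 2 + j
}

#' @rdname genotype_index
#' @param idx 0-based PL index.
#' @return `genotype_unindex`: integer vector c(j, k).
#' @export
genotype_unindex <- function(idx) {
  k <- floor((sqrt(8 * idx + 1) - 1) / 2)
  j <- idx - k * (k + 1) / 2
  # guard against floating point at triangle boundaries
  bad <- j > k
  k[bad] <- k[bad] + 1
  j[bad] <- idx[bad] - k[bad] * (k[bad] + 1) / 2
  as.integer(c(j, k))
}

#' Merge VCF headers
#'
#' Definitions with the same id must have the same Type (error otherwise);
#' differing Numbers resolve to "."; contigs are unioned in first-seen
#' order; sample lists concatenate with duplicates disambiguated by a
#' `"_<k>"` suffix (k = input index).
#'
#' @param headers list of `vcf_header` objects.
#' @return list with `header` (the merged `vcf_header`) and
#'   `sample_names`: a list giving, per input, the (possibly renamed)
#'   sample names in the merged header.
#' @export
merge_vcf_headers <- function(headers) {
  contigs <- data.frame(name = character(0), length = numeric(0))
  defs <- list(info = NULL, format = NULL)
  filter <- data.frame(id = character(0), description = character(0))
  samples <- character(0)
  sample_names <- list()
  other <- character(0)
  for (k in seq_along(headers)) {
    h <- headers[[k]]
    for (i in seq_len(nrow(h$contigs))) {
      j <- match(h$contigs$name[i], contigs$name)
      if (is.na(j)) contigs <- rbind(contigs, h$contigs[i, ])
    }
    for (sec in c("info", "format")) {
      d <- h[[sec]]
      for (i in seq_len(nrow(d))) {
        cur <- defs[[sec]]
        j <- if (is.null(cur)) NA_integer_ else match(d$id[i], cur$id)
        if (is.na(j)) defs[[sec]] <- rbind(cur, d[i, ])
        else {
          if (cur$type[j] != d$type[i])
            stop(sprintf(
              "header merge error: %s/%s declared both %s and %s",
              toupper(sec), d$id[i], cur$type[j], d$type[i]))
          if (cur$number[j] != d$number[i]) defs[[sec]]$number[j] <- "."
        }
      }
    }
    for (i in seq_len(nrow(h$filter)))
      if (!(h$filter$id[i] %in% filter$id)) filter <- rbind(filter, h$filter[i, ])
    nm <- h$samples
    clash <- nm %in% samples
    nm[clash] <- paste0(nm[clash], "_", k)
    sample_names[[k]] <- nm
    samples <- c(samples, nm)
    other <- union(other, h$other)
  }
  list(header = vcf_header(contigs = contigs, info = defs$info,
                           format = defs$format, filter = filter,
                           samples = samples,
                           fileformat = headers[[1L]]$fileformat,
                           other = other),
       sample_names = sample_names)
}
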