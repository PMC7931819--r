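# Variant-side toolbox: normalization, multiallelic split/join, merge,
# concat, isec, annotate, consensus, query formatting, filter expressions,
# stats and genotype concordance checks.

.is_symbolic <- function(allele)
  grepl("[<>\\[\\]]", allele) | allele == "*"

# ---- normalize --------------------------------------------------------------

#' Normalize a variant to its left-aligned minimal representation
#'
#' Shared trailing bases are stripped (extending left from the reference
#' when an allele would empty), then shared leading bases are stripped
#' while no allele would empty; iterated to the fixed point.  The result's
#' REF always equals the reference substring at its interval, and applying
#' either representation to the reference yields the same haplotype.
#'
#' @param records VCF record data.frame (non-symbolic alleles).
#' @param reference named character vector of reference sequences.
#' @return records, normalized (positions may move left).
#' @export
normalize_variants <- function(records, reference) {
  for (i in seq_len(nrow(records))) {
    refseq <- .ref_get(reference, records$chrom[i])
    if (is.null(refseq))
      stop(sprintf("normalize: no reference sequence '%s'", records$chrom[i]))
    alts <- if (records$alt[i] == ".") character(0) else
      strsplit(records$alt[i], ",", fixed = TRUE)[[1L]]
    if (any(.is_symbolic(c(records$ref[i], alts))))
      stop(sprintf("normalize: symbolic allele at %s:%d",
                   records$chrom[i], as.integer(records$pos[i] + 1)))
    pos <- records$pos[i]
    ref <- toupper(records$ref[i])
    obs <- toupper(substr(refseq, pos + 1, pos + nchar(ref)))
    if (obs != ref)
      stop(sprintf(
        "normalize: REF mismatch at %s:%d (record %s, reference %s)",
        records$chrom[i], as.integer(pos + 1), ref, obs))
    if (!length(alts)) next
    al <- c(ref, toupper(alts))
    repeat {
      last <- substr(al, nchar(al), nchar(al))
      if (length(unique(last)) == 1L && all(nchar(al) >= 1L) &&
          nchar(al[1L]) + min(nchar(al)) > 2L) {
        # strip the shared last base, extending left first if any allele
        # would become empty
        if (any(nchar(al) == 1L)) {
          if (pos == 0) break
          prev <- toupper(substr(refseq, pos, pos))
          al <- paste0(prev, al)
          pos <- pos - 1
        }
        al <- substr(al, 1L, nchar(al) - 1L)
      } else break
    }
    while (all(nchar(al) >= 2L) &&
           length(unique(substr(al, 1L, 1L))) == 1L) {
      al <- substr(al, 2L, nchar(al))
      pos <- pos + 1
    }
    records$pos[i] <- pos
    records$ref[i] <- al[1L]
    records$alt[i] <- paste(al[-1L], collapse = ",")
  }
  records
}

# ---- multiallelic split / join ---------------------------------------------

# slice a comma-joined Number=A/R/G field value for alt index ai (1-based)
.slice_field <- function(val, number, ai) {
  if (is.na(val) || val == ".") return(val)
  v <- strsplit(val, ",", fixed = TRUE)[[1L]]
  out <- switch(number,
                A = v[ai],
                R = v[c(1L, ai + 1L)],
                G = v[c(genotype_index(0L, 0L), genotype_index(0L, ai),
                        genotype_index(ai, ai)) + 1L],
                val)
  paste(out, collapse = ",")
}

#' Split multiallelic records into biallelic ones (and rejoin)
#'
#' `split_multiallelic` emits one record per alternate allele with
#' Number=A/R/G INFO and FORMAT fields sliced accordingly (G via the PL
#' index formula); genotype indexes are remapped, with alleles other than
#' the kept one becoming missing.  `join_multiallelic` inverts the split on
#' its own output, grouping by (chrom, pos, ref).
#'
#' @param records VCF record data.frame.
#' @param header the `vcf_header` (field Number declarations).
#' @return data.frame of records.
#' @export
split_multiallelic <- function(records, header) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    alts <- if (records$alt[i] == ".") character(0) else
      strsplit(records$alt[i], ",", fixed = TRUE)[[1L]]
    if (length(alts) <= 1L) { out[[length(out) + 1L]] <- records[i, ]; next }
    for (ai in seq_along(alts)) {
      r <- records[i, ]
      r$alt <- alts[ai]
      # INFO
      if (r$info != ".") {
        kvs <- strsplit(r$info, ";", fixed = TRUE)[[1L]]
        kvs <- vapply(kvs, function(kv) {
          eq <- regexpr("=", kv, fixed = TRUE)
          if (eq < 0) return(kv)
          key <- substr(kv, 1, eq - 1)
          num <- header$info$number[match(key, header$info$id)]
          if (is.na(num) || !(num %in% c("A", "R", "G"))) return(kv)
          paste0(key, "=",
                 .slice_field(substr(kv, eq + 1, nchar(kv)), num, ai))
        }, "", USE.NAMES = FALSE)
        r$info <- paste(kvs, collapse = ";")
      }
      # FORMAT
      if (!is.na(r$format) && length(header$samples)) {
        keys <- strsplit(r$format, ":", fixed = TRUE)[[1L]]
        for (s in header$samples) {
          sv <- strsplit(r[[s]], ":", fixed = TRUE)[[1L]]
          for (ki in seq_along(keys)) {
            if (ki > length(sv)) next
            if (keys[ki] == "GT") {
              g <- parse_genotypes(sv[ki])
              remap <- function(a) ifelse(is.na(a), NA_integer_,
                                          ifelse(a == 0L, 0L,
                                                 ifelse(a == ai, 1L, NA_integer_)))
              sep <- if (isTRUE(g$phased[1L])) "|" else "/"
              fmt1 <- function(a) ifelse(is.na(a), ".", as.character(a))
              sv[ki] <- paste0(fmt1(remap(g$a1[1L])), sep, fmt1(remap(g$a2[1L])))
            } else {
              num <- header$format$number[match(keys[ki], header$format$id)]
              if (!is.na(num) && num %in% c("A", "R", "G"))
                sv[ki] <- .slice_field(sv[ki], num, ai)
            }
          }
          r[[s]] <- paste(sv, collapse = ":")
        }
      }
      out[[length(out) + 1L]] <- r
    }
  }
  res <- if (length(out)) do.call(rbind, out) else records[0, ]
  rownames(res) <- NULL
  res
}

#' @rdname split_multiallelic
#' @export
join_multiallelic <- function(records, header) {
  if (!nrow(records)) return(records)
  key <- paste(records$chrom, records$pos, records$ref, sep = "\r")
  out <- list()
  for (ix in split(seq_len(nrow(records)), factor(key, unique(key)))) {
    if (length(ix) == 1L) { out[[length(out) + 1L]] <- records[ix, ]; next }
    alts <- unlist(strsplit(records$alt[ix], ",", fixed = TRUE))
    r <- records[ix[1L], ]
    r$alt <- paste(alts, collapse = ",")
    r$qual <- suppressWarnings(max(records$qual[ix], na.rm = TRUE))
    if (!is.finite(r$qual)) r$qual <- NA_real_
    na <- length(alts) + 1L
    # INFO: rebuild A/R/G fields from the slices
    if (r$info != ".") {
      kvs0 <- strsplit(records$info[ix], ";", fixed = TRUE)
      keys <- vapply(strsplit(kvs0[[1L]], "=", fixed = TRUE), `[[`, "", 1L)
      parts <- lapply(kvs0, function(kvs)
        stats::setNames(sub("^[^=]*=?", "", kvs),
                        vapply(strsplit(kvs, "=", fixed = TRUE), `[[`, "", 1L)))
      newinfo <- vapply(keys, function(key) {
        num <- header$info$number[match(key, header$info$id)]
        vals <- vapply(parts, function(p)
          if (key %in% names(p)) p[[key]] else ".", "")
        if (is.na(num) || !(num %in% c("A", "R", "G"))) {
          if (vals[1L] == "") return(key)
          return(paste0(key, "=", vals[1L]))
        }
        joined <- switch(num,
          A = paste(vals, collapse = ","),
          R = paste(c(strsplit(vals[1L], ",", fixed = TRUE)[[1L]][1L],
                      vapply(vals, function(v)
                        strsplit(v, ",", fixed = TRUE)[[1L]][2L], "")),
                    collapse = ","),
          G = {
            gout <- rep(".", na * (na + 1L) / 2L)
            for (ai in seq_along(alts)) {
              v <- strsplit(vals[ai], ",", fixed = TRUE)[[1L]]
              gout[genotype_index(0L, 0L) + 1L] <- v[1L]
              gout[genotype_index(0L, ai) + 1L] <- v[2L]
              gout[genotype_index(ai, ai) + 1L] <- v[3L]
            }
            paste(gout, collapse = ",")
          })
        paste0(key, "=", joined)
      }, "")
      r$info <- paste(newinfo, collapse = ";")
    }
    if (!is.na(r$format) && length(header$samples)) {
      keys <- strsplit(r$format, ":", fixed = TRUE)[[1L]]
      for (s in header$samples) {
        svs <- strsplit(records[[s]][ix], ":", fixed = TRUE)
        sv <- svs[[1L]]
        for (ki in seq_along(keys)) {
          if (keys[ki] == "GT") {
            gts <- vapply(svs, `[[`, "", ki)
            gs <- parse_genotypes(gts)
            # per haplotype: the alt whose slice shows 1, else 0 if any
            # slice shows ref, else missing
            hap <- function(av) {
              if (any(!is.na(av) & av == 1L)) which(av == 1L)[1L]
              else if (any(!is.na(av) & av == 0L)) 0L
              else NA_integer_
            }
            a1 <- hap(gs$a1); a2 <- hap(gs$a2)
            f1 <- function(a) if (is.na(a)) "." else as.character(a)
            sv[ki] <- paste0(f1(a1), if (any(gs$phased)) "|" else "/", f1(a2))
          } else {
            num <- header$format$number[match(keys[ki], header$format$id)]
            if (!is.na(num) && num %in% c("A", "R", "G")) {
              vals <- vapply(svs, function(v)
                if (ki <= length(v)) v[ki] else ".", "")
              sv[ki] <- switch(num,
                A = paste(vals, collapse = ","),
                R = paste(c(strsplit(vals[1L], ",", fixed = TRUE)[[1L]][1L],
                            vapply(vals, function(v)
                              strsplit(v, ",", fixed = TRUE)[[1L]][2L], "")),
                          collapse = ","),
                G = {
                  gout <- rep(".", na * (na + 1L) / 2L)
                  for (ai in seq_along(alts)) {
                    v <- strsplit(vals[ai], ",", fixed = TRUE)[[1L]]
                    if (length(v) == 3L) {
                      gout[genotype_index(0L, 0L) + 1L] <- v[1L]
                      gout[genotype_index(0L, ai) + 1L] <- v[2L]
                      gout[genotype_index(ai, ai) + 1L] <- v[3L]
                    }
                  }
                  paste(gout, collapse = ",")
                })
            }
          }
        }
        r[[s]] <- paste(sv, collapse = ":")
      }
    }
    out[[length(out) + 1L]] <- r
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- merge / concat / isec --------------------------------------------------

#' Merge variant files with disjoint samples
#'
#' Records at the same (chrom, pos) with identical REF are unified: allele
#' lists are unioned, genotype indexes and Number=A/R/G fields remapped,
#' absent samples filled with missing values.  QUAL resolves to the
#' maximum, FILTER to PASS iff all inputs PASS; INFO fields declared
#' Number=1 Integer are summed, all others dropped with a warning.
#'
#' @param vcfs list of `vcf` objects, each position-sorted.
#' @return merged `vcf` object.
#' @export
merge_variant_files <- function(vcfs) {
  mh <- merge_vcf_headers(lapply(vcfs, `[[`, "header"))
  header <- mh$header
  allrec <- list()
  for (k in seq_along(vcfs)) {
    r <- vcfs[[k]]$records
    if (!nrow(r)) next
    oldnames <- vcfs[[k]]$header$samples
    newnames <- mh$sample_names[[k]]
    names(r)[match(oldnames, names(r))] <- newnames
    r$file__ <- k
    allrec[[k]] <- r
  }
  if (!length(allrec)) return(structure(list(header = header,
                                             records = .empty_vcf_records(header$samples)),
                                        class = "vcf"))
  # group by site key
  keys <- lapply(allrec, function(r) paste(r$chrom, r$pos, r$ref, sep = "\r"))
  ukeys <- unique(unlist(keys))
  # sort keys by (chrom order of appearance, pos)
  kparts <- strsplit(ukeys, "\r", fixed = TRUE)
  kchrom <- vapply(kparts, `[[`, "", 1L)
  kpos <- as.numeric(vapply(kparts, `[[`, "", 2L))
  ukeys <- ukeys[order(match(kchrom, unique(kchrom)), kpos)]
  int_info <- header$info$id[header$info$number == "1" &
                               header$info$type == "Integer"]
  dropped <- character(0)
  out <- vector("list", length(ukeys))
  for (ui in seq_along(ukeys)) {
    rows <- lapply(seq_along(allrec), function(k) {
      r <- allrec[[k]]
      r[keys[[k]] == ukeys[ui], , drop = FALSE]
    })
    rows <- rows[vapply(rows, nrow, 0L) > 0L]
    first <- rows[[1L]][1L, ]
    alts <- character(0)
    for (r in rows) {
      a <- if (r$alt[1L] == ".") character(0) else
        strsplit(r$alt[1L], ",", fixed = TRUE)[[1L]]
      alts <- union(alts, a)
    }
    rec <- data.frame(chrom = first$chrom, pos = first$pos, id = first$id,
                      ref = first$ref,
                      alt = if (length(alts)) paste(alts, collapse = ",") else ".",
                      qual = suppressWarnings(
                        max(unlist(lapply(rows, `[[`, "qual")), na.rm = TRUE)),
                      filter = ".", info = ".",
                      format = NA_character_, stringsAsFactors = FALSE)
    if (!is.finite(rec$qual)) rec$qual <- NA_real_
    filters <- unlist(lapply(rows, `[[`, "filter"))
    rec$filter <- if (all(filters == "PASS")) "PASS" else
      if (all(filters == ".")) "." else
        paste(sort(unique(setdiff(filters, c("PASS", ".")))), collapse = ";")
    # INFO: sum Number=1 Integer fields; drop others
    infos <- unlist(lapply(rows, `[[`, "info"))
    kvs <- unlist(strsplit(infos[infos != "."], ";", fixed = TRUE))
    ikeys <- unique(vapply(strsplit(kvs, "=", fixed = TRUE), `[[`, "", 1L))
    newinfo <- character(0)
    for (key in ikeys) {
      if (key %in% int_info) {
        vals <- suppressWarnings(as.numeric(sub("^[^=]*=", "",
                                                kvs[startsWith(kvs, paste0(key, "="))])))
        newinfo <- c(newinfo, paste0(key, "=",
                                     format(sum(vals, na.rm = TRUE),
                                            scientific = FALSE, trim = TRUE)))
      } else dropped <- union(dropped, key)
    }
    rec$info <- if (length(newinfo)) paste(newinfo, collapse = ";") else "."
    # FORMAT: carry GT (remapped) plus DP/GQ when present
    fkeys <- unique(unlist(strsplit(unlist(lapply(rows, `[[`, "format")),
                                    ":", fixed = TRUE)))
    fkeys <- fkeys[!is.na(fkeys)]
    fkeys <- c("GT", setdiff(intersect(fkeys, c("DP", "GQ")), "GT"))
    rec$format <- paste(fkeys, collapse = ":")
    for (s in header$samples) rec[[s]] <- paste(
      ifelse(fkeys == "GT", "./.", "."), collapse = ":")
    for (r in rows) {
      srcalts <- if (r$alt[1L] == ".") character(0) else
        strsplit(r$alt[1L], ",", fixed = TRUE)[[1L]]
      amap <- c(0L, match(srcalts, alts))   # old allele idx -> new
      skeys <- strsplit(r$format[1L], ":", fixed = TRUE)[[1L]]
      mysamples <- intersect(names(r), header$samples)
      for (s in mysamples) {
        sv <- strsplit(r[[s]][1L], ":", fixed = TRUE)[[1L]]
        outv <- character(length(fkeys))
        for (fi in seq_along(fkeys)) {
          ki <- match(fkeys[fi], skeys)
          if (is.na(ki) || ki > length(sv)) { outv[fi] <- "."; next }
          if (fkeys[fi] == "GT") {
            g <- parse_genotypes(sv[ki])
            f1 <- function(a) if (is.na(a)) "." else
              as.character(amap[a + 1L])
            outv[fi] <- paste0(f1(g$a1[1L]),
                               if (g$phased[1L]) "|" else "/", f1(g$a2[1L]))
          } else outv[fi] <- sv[ki]
        }
        rec[[s]] <- paste(outv, collapse = ":")
      }
    }
    out[[ui]] <- rec
  }
  if (length(dropped))
    warning(sprintf("merge: dropped INFO fields without merge rules: %s",
                    paste(dropped, collapse = ", ")))
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  structure(list(header = header, records = records), class = "vcf")
}

#' Concatenate variant files with identical samples
#'
#' @param vcfs list of `vcf` objects with identical sample lists (error
#'   otherwise); headers are merged; records concatenate in input order.
#' @return a `vcf` object.
#' @export
concat_variant_files <- function(vcfs) {
  base <- vcfs[[1L]]$header$samples
  for (v in vcfs[-1L])
    if (!identical(v$header$samples, base))
      stop("concat: sample lists differ between inputs")
  headers <- lapply(vcfs, `[[`, "header")
  mh <- merge_vcf_headers(headers[1L])
  header <- mh$header
  for (h in headers[-1L]) {
    # definitions must be compatible; samples identical so no renaming
    m2 <- merge_vcf_headers(list(header, h))
    header <- m2$header
    header$samples <- base
  }
  records <- do.call(rbind, lapply(vcfs, `[[`, "records"))
  rownames(records) <- NULL
  structure(list(header = header, records = records), class = "vcf")
}

#' Intersect / subtract variant files by site
#'
#' Sites are keyed by (chrom, pos, ref, alt-set), optionally after
#' normalization against a reference, or by position only.  Each input
#' record is routed by its presence bitmask across the inputs.
#'
#' @param vcfs list of `vcf` objects.
#' @param rule which records to keep per input: `"all"` (everything, the
#'   default), an integer n (sites present in at least n inputs),
#'   `"shared"` (present in every input) or `"private"` (present in
#'   exactly one).
#' @param reference optional named character vector; when given, keys use
#'   normalized alleles.
#' @param by_position_only match sites on (chrom, pos) alone.
#' @return list with `masks` (per input, integer vector of presence
#'   bitmask per record) and `subsets` (per input, the records matching
#'   `rule`).
#' @export
isec <- function(vcfs, rule = "all", reference = NULL,
                 by_position_only = FALSE) {
  keyof <- function(v) {
    r <- v$records
    if (!is.null(reference)) r <- normalize_variants(r, reference)
    if (by_position_only) paste(r$chrom, r$pos)
    else vapply(seq_len(nrow(r)), function(i) paste(
      r$chrom[i], r$pos[i], r$ref[i],
      paste(sort(strsplit(r$alt[i], ",", fixed = TRUE)[[1L]]), collapse = ","),
      sep = "\r"), "")
  }
  keys <- lapply(vcfs, keyof)
  n <- length(vcfs)
  masks <- lapply(seq_len(n), function(k) {
    m <- integer(length(keys[[k]]))
    for (j in seq_len(n)) m <- m + bitwShiftL(as.integer(
      keys[[k]] %in% keys[[j]]), j - 1L)
    m
  })
  nfiles <- lapply(masks, function(m)
    vapply(m, function(x) sum(bitwAnd(x, bitwShiftL(1L, 0:(n - 1L))) > 0L), 0L))
  selector <- function(nf) {
    if (identical(rule, "all")) rep(TRUE, length(nf))
    else if (identical(rule, "shared")) nf == n
    else if (identical(rule, "private")) nf == 1L
    else if (is.numeric(rule)) nf >= rule
    else stop(sprintf("unknown isec rule: %s", format(rule)))
  }
  subsets <- lapply(seq_len(n), function(k)
    vcfs[[k]]$records[selector(nfiles[[k]]), , drop = FALSE])
  list(masks = masks, subsets = subsets)
}

# ---- annotate ---------------------------------------------------------------

#' Transfer or remove annotations
#'
#' @param x target `vcf` object.
#' @param source optional source: a `vcf` object or a data.frame with
#'   columns `chrom`, `pos` (0-based), optionally `ref`, `alt`, plus one
#'   column per annotation to add.
#' @param columns INFO keys to transfer from the source (default: all its
#'   INFO declarations / extra columns).
#' @param remove character vector of removals: `"INFO/KEY"`, or `"INFO/*"`
#'   for all INFO fields.
#' @param match_alleles require ref+alt match (else position only).
#' @return the annotated `vcf` object (header updated with new
#'   definitions).
#' @export
annotate_variants <- function(x, source = NULL, columns = NULL,
                              remove = character(0), match_alleles = TRUE) {
  records <- x$records
  header <- x$header
  for (rm in remove) {
    if (rm == "INFO/*") {
      records$info <- "."
    } else if (startsWith(rm, "INFO/")) {
      key <- sub("^INFO/", "", rm)
      records <- vcf_info_set(records, key, rep(NA_character_, nrow(records)))
    } else stop(sprintf("unsupported removal target: %s", rm))
  }
  if (!is.null(source)) {
    if (inherits(source, "vcf")) {
      src <- source$records
      if (is.null(columns)) columns <- source$header$info$id
      getval <- function(key) vapply(
        seq_len(nrow(src)), function(i) {
          v <- vcf_info_get(src[i, , drop = FALSE], key, source$header)
          if (is.list(v)) v <- paste(v[[1L]], collapse = ",")
          if (is.logical(v)) { if (isTRUE(v)) "" else NA_character_ }
          else if (is.na(v)) NA_character_
          else as.character(v)
        }, "")
      defs <- source$header$info
    } else {
      src <- source
      if (is.null(columns))
        columns <- setdiff(names(src), c("chrom", "pos", "ref", "alt"))
      getval <- function(key) as.character(src[[key]])
      defs <- data.frame(id = columns, number = "1", type = "String",
                         description = "(annotation)")
    }
    skey <- if (match_alleles && all(c("ref", "alt") %in% names(src)))
      paste(src$chrom, src$pos, src$ref, src$alt, sep = "\r")
    else paste(src$chrom, src$pos, sep = "\r")
    tkey <- if (match_alleles && all(c("ref", "alt") %in% names(src)))
      paste(records$chrom, records$pos, records$ref, records$alt, sep = "\r")
    else paste(records$chrom, records$pos, sep = "\r")
    hit <- match(tkey, skey)
    for (key in columns) {
      vals <- getval(key)[hit]
      upd <- !is.na(hit) & !is.na(vals)
      if (any(upd)) {
        allvals <- rep(NA_character_, nrow(records))
        cur <- vapply(seq_len(nrow(records)), function(i) {
          v <- vcf_info_get(records[i, , drop = FALSE], key, header)
          if (is.list(v)) paste(v[[1L]], collapse = ",") else
            if (is.logical(v)) { if (isTRUE(v)) "" else NA_character_ } else
              if (is.na(v)) NA_character_ else as.character(v)
        }, "")
        allvals[!upd] <- cur[!upd]
        allvals[upd] <- vals[upd]
        records <- vcf_info_set(records, key, allvals)
      }
      if (!(key %in% header$info$id)) {
        di <- match(key, defs$id)
        header$info <- rbind(header$info, if (!is.na(di)) defs[di, ] else
          data.frame(id = key, number = "1", type = "String",
                     description = "(annotation)"))
      }
    }
  }
  structure(list(header = header, records = records), class = "vcf")
}

# ---- consensus --------------------------------------------------------------

IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Apply variants to a reference, producing a consensus sequence
#'
#' Variants must be normalized, sorted and non-overlapping after haplotype
#' selection (overlap is an error, not last-wins).  With a sample, the
#' chosen allele follows that sample's GT on the requested haplotype;
#' hom-ref or missing genotypes leave the reference; in IUPAC mode
#' heterozygous SNPs become ambiguity codes.  Records without genotypes
#' apply their first ALT.
#'
#' @param reference named character vector.
#' @param x a `vcf` object.
#' @param sample sample name (NULL: apply first ALT everywhere).
#' @param haplotype 1, 2, or "iupac".
#' @return named character vector of consensus sequences.
#' @export
consensus_apply <- function(reference, x, sample = NULL, haplotype = 1L) {
  records <- x$records
  out <- reference
  for (chrom in unique(records$chrom)) {
    refseq <- .ref_get(reference, chrom)
    if (is.null(refseq))
      stop(sprintf("consensus: no reference sequence '%s'", chrom))
    rr <- records[records$chrom == chrom, , drop = FALSE]
    rr <- rr[order(rr$pos), , drop = FALSE]
    pieces <- character(0)
    cursor <- 0   # 0-based position up to which output is built
    prev_desc <- NULL
    for (i in seq_len(nrow(rr))) {
      alts <- if (rr$alt[i] == ".") character(0) else
        strsplit(rr$alt[i], ",", fixed = TRUE)[[1L]]
      if (!length(alts)) next
      if (any(.is_symbolic(c(rr$ref[i], alts))))
        stop(sprintf("consensus: symbolic allele at %s:%d", chrom,
                     as.integer(rr$pos[i] + 1)))
      allele <- NULL
      if (!is.null(sample)) {
        gtm <- vcf_format_get(rr[i, , drop = FALSE], "GT", x$header)
        g <- parse_genotypes(gtm[, sample])
        a1 <- g$a1[1L]; a2 <- g$a2[1L]
        if (is.na(a1) && is.na(a2)) next
        if (identical(haplotype, "iupac")) {
          ai <- c(a1, a2)
          ai <- ai[!is.na(ai)]
          als <- c(rr$ref[i], alts)[ai + 1L]
          if (length(unique(als)) == 1L) allele <- als[1L]
          else if (all(nchar(als) == 1L) && nchar(rr$ref[i]) == 1L) {
            code <- IUPAC2[paste(sort(toupper(als)), collapse = "")]
            allele <- if (is.na(code)) als[1L] else code
          } else allele <- als[which(als != rr$ref[i])[1L]]
        } else {
          a <- if (haplotype == 1L) a1 else a2
          if (is.na(a)) a <- if (haplotype == 1L) a2 else a1
          if (is.na(a) || a == 0L) next
          allele <- alts[a]
        }
      } else allele <- alts[1L]
      if (is.null(allele) || identical(allele, rr$ref[i])) next
      if (rr$pos[i] < cursor) {
        stop(sprintf(
          "consensus: overlapping edits at %s:%d (previous edit %s ends at %d)",
          chrom, as.integer(rr$pos[i] + 1),
          if (is.null(prev_desc)) "?" else prev_desc, as.integer(cursor)))
      }
      pieces <- c(pieces, substr(refseq, cursor + 1, rr$pos[i]), allele)
      cursor <- rr$pos[i] + nchar(rr$ref[i])
      prev_desc <- sprintf("%s:%d %s>%s", chrom, as.integer(rr$pos[i] + 1),
                           rr$ref[i], allele)
    }
    pieces <- c(pieces, substr(refseq, cursor + 1, nchar(refseq)))
    out[[chrom]] <- paste(pieces, collapse = "")
  }
  out
}

# ---- query ------------------------------------------------------------------

#' Format records with a query template
#'
#' Placeholders `%CHROM %POS %ID %REF %ALT %QUAL %FILTER %INFO/x` expand
#' per record (POS is 1-based); a `[...]` block repeats per sample and may
#' use `%SAMPLE`, `%GT` and any FORMAT key as `%KEY`.  `\t` and `\n` are
#' the usual escapes; missing values render as `.`.
#'
#' @param records VCF record data.frame.
#' @param header the `vcf_header`.
#' @param format template string.
#' @return character vector: the output split into lines.
#' @export
query_format <- function(records, header, format) {
  fmt <- gsub("\\\\t", "\t", gsub("\\\\n", "\n", format))
  expand_simple <- function(i, txt) {
    r <- records[i, , drop = FALSE]
    repl <- function(t, key, val) gsub(key, val, t, fixed = TRUE)
    # INFO/x first (longest match)
    for (m in regmatches(txt, gregexpr("%INFO/[A-Za-z0-9_]+", txt))[[1L]]) {
      key <- sub("^%INFO/", "", m)
      v <- vcf_info_get(r, key, header)
      if (is.list(v)) v <- paste(v[[1L]], collapse = ",")
      if (is.logical(v)) v <- if (isTRUE(v)) "1" else "."
      txt <- repl(txt, m, if (is.na(v)) "." else as.character(v))
    }
    txt <- repl(txt, "%CHROM", r$chrom)
    txt <- repl(txt, "%POS", format(r$pos + 1, scientific = FALSE, trim = TRUE))
    txt <- repl(txt, "%ID", r$id)
    txt <- repl(txt, "%REF", r$ref)
    txt <- repl(txt, "%ALT", r$alt)
    txt <- repl(txt, "%QUAL", if (is.na(r$qual)) "." else
      format(r$qual, scientific = FALSE, trim = TRUE))
    txt <- repl(txt, "%FILTER", r$filter)
    txt
  }
  expand_sample_block <- function(i, txt) {
    r <- records[i, , drop = FALSE]
    paste(vapply(header$samples, function(s) {
      t2 <- txt
      for (m in rev(regmatches(t2, gregexpr("%[A-Za-z0-9_]+", t2))[[1L]])) {
        key <- sub("^%", "", m)
        v <- if (key == "SAMPLE") s
        else {
          vm <- vcf_format_get(r, key, header)
          if (is.na(vm[1L, s])) "." else vm[1L, s]
        }
        t2 <- gsub(m, v, t2, fixed = TRUE)
      }
      t2
    }, ""), collapse = "")
  }
  out <- vapply(seq_len(nrow(records)), function(i) {
    txt <- fmt
    m <- regmatches(txt, gregexpr("\\[[^]]*\\]", txt))[[1L]]
    for (blk in m) {
      inner <- substr(blk, 2L, nchar(blk) - 1L)
      txt <- sub(blk, expand_sample_block(i, inner), txt, fixed = TRUE)
    }
    expand_simple(i, txt)
  }, "")
  out <- paste(out, collapse = "")
  strsplit(out, "\n", fixed = TRUE)[[1L]]
}

# ---- filter expressions -----------------------------------------------------

#' Parse a filter expression
#'
#' Grammar: comparisons `field OP constant` with OP in
#' `= == != < <= > >=`, field references `QUAL`, `FILTER`, `INFO/x`,
#' `FORMAT/x`, flag presence by naming an INFO field alone, combined with
#' `&&`, `||`, `!` and parentheses.  String constants are quoted with
#' `"` or `'`.  Evaluation is total: missing values make a comparison
#' false.
#'
#' @param text expression text.
#' @return parse tree of class `filter_expr`.
#' @export
parse_filter_expression <- function(text) {
  pat <- paste0("\\s*(", paste(c(
    "&&", "\\|\\|", "!=", "<=", ">=", "==", "[()!<>=]",
    "\"[^\"]*\"", "'[^']*'",
    "-?[0-9]+\\.?[0-9]*([eE][-+]?[0-9]+)?",
    "(INFO|FORMAT|FMT)/[A-Za-z0-9_]+", "[A-Za-z_][A-Za-z0-9_]*"),
    collapse = "|"), ")")
  toks <- character(0)
  rest <- text
  while (grepl("\\S", rest)) {
    m <- regmatches(rest, regexpr(paste0("^", pat), rest))
    if (!length(m) || !nzchar(m))
      stop(sprintf("filter expression: cannot tokenize near '%s'", rest))
    toks <- c(toks, sub("^\\s+", "", m))
    rest <- substr(rest, nchar(m) + 1L, nchar(rest))
  }
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_or <- function() {
    left <- parse_and()
    while (peek() == "||") { take(); left <- list(op = "or", a = left,
                                                  b = parse_and()) }
    left
  }
  parse_and <- function() {
    left <- parse_not()
    while (peek() == "&&") { take(); left <- list(op = "and", a = left,
                                                  b = parse_not()) }
    left
  }
  parse_not <- function() {
    if (peek() == "!") { take(); return(list(op = "not", a = parse_not())) }
    parse_primary()
  }
  is_field <- function(t) t %in% c("QUAL", "FILTER") ||
    grepl("^(INFO|FORMAT|FMT)/", t)
  parse_primary <- function() {
    t <- peek()
    if (t == "(") {
      take()
      e <- parse_or()
      if (take() != ")") stop("filter expression: missing ')'")
      return(e)
    }
    if (!is_field(t))
      stop(sprintf("filter expression: expected a field reference, got '%s'", t))
    take()
    op <- peek()
    if (op %in% c("=", "==", "!=", "<", "<=", ">", ">=")) {
      take()
      cv <- take()
      const <- if (grepl("^[\"']", cv)) substr(cv, 2L, nchar(cv) - 1L)
      else suppressWarnings(as.numeric(cv))
      if (is.na(const) && !grepl("^[\"']", cv))
        stop(sprintf("filter expression: bad constant '%s'", cv))
      return(list(op = "cmp", field = t, cmp = if (op == "=") "==" else op,
                  const = const))
    }
    list(op = "present", field = t)
  }
  tree <- parse_or()
  if (pos <= length(toks))
    stop(sprintf("filter expression: trailing tokens from '%s'", peek()))
  structure(tree, class = "filter_expr")
}

# field values for one record: list(values, per_sample)
.filter_field <- function(record, field, header) {
  if (field == "QUAL") return(list(v = record$qual, per_sample = FALSE))
  if (field == "FILTER") return(list(v = record$filter, per_sample = FALSE))
  sec <- sub("/.*$", "", field)
  key <- sub("^[^/]*/", "", field)
  if (sec == "INFO") {
    v <- vcf_info_get(record, key, header)
    if (is.list(v)) v <- v[[1L]]
    list(v = v, per_sample = FALSE)
  } else {
    m <- vcf_format_get(record, key, header)
    v <- as.vector(m[1L, ])
    num <- suppressWarnings(as.numeric(v))
    list(v = if (all(is.na(num) == is.na(v))) num else v, per_sample = TRUE)
  }
}

#' Evaluate a filter expression on records
#'
#' @param records VCF record data.frame.
#' @param expr a `filter_expr` (or expression text).
#' @param header the `vcf_header`.
#' @param mode `"include"` keeps records where the expression is true,
#'   `"exclude"` keeps those where it is false.
#' @return logical vector: keep each record?
#' @export
eval_filter <- function(records, expr, header,
                        mode = c("include", "exclude")) {
  mode <- match.arg(mode)
  if (is.character(expr)) expr <- parse_filter_expression(expr)
  eval1 <- function(node, i) {
    r <- records[i, , drop = FALSE]
    switch(node$op,
      or = eval1(node$a, i) || eval1(node$b, i),
      and = eval1(node$a, i) && eval1(node$b, i),
      not = !eval1(node$a, i),
      present = {
        fv <- .filter_field(r, node$field, header)
        any(!is.na(fv$v)) && !identical(fv$v, FALSE)
      },
      cmp = {
        fv <- .filter_field(r, node$field, header)
        v <- fv$v
        if (is.numeric(node$const)) v <- suppressWarnings(as.numeric(v))
        else v <- as.character(v)
        res <- switch(node$cmp,
                      "==" = v == node$const, "!=" = v != node$const,
                      "<" = v < node$const, "<=" = v <= node$const,
                      ">" = v > node$const, ">=" = v >= node$const)
        any(res, na.rm = TRUE)   # missing -> false; FORMAT: any sample
      })
  }
  keep <- vapply(seq_len(nrow(records)), function(i)
    isTRUE(eval1(expr, i)), TRUE)
  if (mode == "include") keep else !keep
}

# ---- stats ------------------------------------------------------------------

#' Variant-file summary statistics
#'
#' SNPs have all alleles of length 1; transitions are A<->G and C<->T;
#' the ts/tv ratio is computed over biallelic SNPs; a singleton is a site
#' where exactly one sample carries an alternate allele.
#'
#' @param x a `vcf` object.
#' @return object of class `vcf_stats_report` (a list; per-sample counts
#'   in `$per_sample`).
#' @export
vcf_stats <- function(x) {
  records <- x$records
  header <- x$header
  if (!nrow(records)) {
    out <- list(n_records = 0L, n_snps = 0L, n_indels = 0L,
                n_multiallelic = 0L, n_singletons = 0L, ts = 0L, tv = 0L,
                ts_tv = NA_real_,
                per_sample = if (length(header$samples))
                  data.frame(sample = header$samples, nNonRefHom = 0L,
                             nHet = 0L, nMissing = 0L) else NULL)
    class(out) <- "vcf_stats_report"
    return(out)
  }
  altsplit <- strsplit(ifelse(records$alt == ".", "", records$alt), ",",
                       fixed = TRUE)
  n_alt <- lengths(altsplit)
  is_snp <- nchar(records$ref) == 1L &
    vapply(altsplit, function(a) length(a) > 0L && all(nchar(a) == 1L), TRUE)
  is_indel <- vapply(seq_len(nrow(records)), function(i)
    n_alt[i] > 0L && any(nchar(altsplit[[i]]) != nchar(records$ref[i])), TRUE)
  multiallelic <- n_alt > 1L
  ts <- tv <- 0L
  bi_snp <- which(is_snp & n_alt == 1L)
  for (i in bi_snp) {
    pair <- paste(sort(c(toupper(records$ref[i]), toupper(altsplit[[i]]))),
                  collapse = "")
    if (pair %in% c("AG", "CT")) ts <- ts + 1L else tv <- tv + 1L
  }
  per_sample <- NULL
  singletons <- 0L
  if (length(header$samples)) {
    gtm <- vcf_format_get(records, "GT", header)
    gs <- parse_genotypes(gtm)
    nonref <- (ifelse(is.na(gs$a1), 0L, (gs$a1 > 0L)) +
                 ifelse(is.na(gs$a2), 0L, (gs$a2 > 0L))) > 0L
    dim(nonref) <- dim(gtm)
    singletons <- sum(rowSums(nonref, na.rm = TRUE) == 1L)
    miss <- is.na(gs$a1) & is.na(gs$a2)
    het <- !is.na(gs$a1) & !is.na(gs$a2) & gs$a1 != gs$a2
    hom_alt <- !is.na(gs$a1) & !is.na(gs$a2) & gs$a1 == gs$a2 & gs$a1 > 0L
    per_sample <- data.frame(sample = header$samples,
                             nNonRefHom = colSums(hom_alt),
                             nHet = colSums(het),
                             nMissing = colSums(miss))
    rownames(per_sample) <- NULL
  }
  out <- list(n_records = nrow(records), n_snps = sum(is_snp),
              n_indels = sum(is_indel), n_multiallelic = sum(multiallelic),
              n_singletons = singletons, ts = ts, tv = tv,
              ts_tv = if (tv > 0L) ts / tv else NA_real_,
              per_sample = per_sample)
  class(out) <- "vcf_stats_report"
  out
}

#' @export
print.vcf_stats_report <- function(x, ...) {
  for (n in setdiff(names(x), "per_sample"))
    cat(sprintf("SN\t%s:\t%s\n", n, format(x[[n]])))
  if (!is.null(x$per_sample)) {
    cat("PSC\tsample\tnNonRefHom\tnHet\tnMissing\n")
    for (i in seq_len(nrow(x$per_sample)))
      cat(sprintf("PSC\t%s\t%d\t%d\t%d\n", x$per_sample$sample[i],
                  x$per_sample$nNonRefHom[i], x$per_sample$nHet[i],
                  x$per_sample$nMissing[i]))
  }
  invisible(x)
}

# ---- gtcheck ----------------------------------------------------------------

#' Pairwise genotype concordance between two variant files
#'
#' Genotypes are compared at shared site keys (chrom, pos, ref, alt-set)
#' where both samples are non-missing; a pair of genotypes is discordant
#' when the unordered allele multisets (as allele strings) differ.
#'
#' @param a,b `vcf` objects.
#' @param pairs data.frame with columns `sample_a`, `sample_b` (default:
#'   samples with matching names).
#' @return data.frame with `sample_a`, `sample_b`, `n_sites`,
#'   `n_discordant`, `discordance`.
#' @export
gtcheck <- function(a, b, pairs = NULL) {
  if (is.null(pairs)) {
    common <- intersect(a$header$samples, b$header$samples)
    pairs <- data.frame(sample_a = common, sample_b = common)
  }
  keyof <- function(r) vapply(seq_len(nrow(r)), function(i) paste(
    r$chrom[i], r$pos[i], r$ref[i],
    paste(sort(strsplit(r$alt[i], ",", fixed = TRUE)[[1L]]), collapse = ","),
    sep = "\r"), "")
  ka <- keyof(a$records); kb <- keyof(b$records)
  shared <- intersect(ka, kb)
  ia <- match(shared, ka); ib <- match(shared, kb)
  gta <- vcf_format_get(a$records[ia, , drop = FALSE], "GT", a$header)
  gtb <- vcf_format_get(b$records[ib, , drop = FALSE], "GT", b$header)
  allele_strings <- function(r, g1, g2) {
    als <- c(r$ref, strsplit(r$alt, ",", fixed = TRUE)[[1L]])
    paste(sort(als[c(g1, g2) + 1L]), collapse = "/")
  }
  out <- pairs
  out$n_sites <- 0L; out$n_discordant <- 0L
  for (p in seq_len(nrow(pairs))) {
    ns <- 0L; nd <- 0L
    for (i in seq_along(shared)) {
      ga <- parse_genotypes(gta[i, pairs$sample_a[p]])
      gb <- parse_genotypes(gtb[i, pairs$sample_b[p]])
      if (is.na(ga$a1) || is.na(ga$a2) || is.na(gb$a1) || is.na(gb$a2)) next
      ns <- ns + 1L
      sa <- allele_strings(a$records[ia[i], , drop = FALSE], ga$a1, ga$a2)
      sb <- allele_strings(b$records[ib[i], , drop = FALSE], gb$a1, gb$a2)
      if (sa != sb) nd <- nd + 1L
    }
    out$n_sites[p] <- ns; out$n_discordant[p] <- nd
  }
  out$discordance <- ifelse(out$n_sites > 0L,
                            out$n_discordant / out$n_sites, NA_real_)
  out
}
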