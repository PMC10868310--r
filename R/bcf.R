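# BCF2.2 binary codec: typed values, the string dictionary, and record
# blocks.
#
# A BCF file is a BGZF stream whose payload starts with the magic
# "BCF\2\2", a length-prefixed copy of the VCF header text, then one
# binary block per record.  All ids (FILTER/INFO/FORMAT) and contigs are
# replaced by integer indices into dictionaries derived from the header.
#
# Typed values: a descriptor byte packs (count << 4 | type-code), with
# count 15 escaping to a following typed integer.  Type codes: 1 = int8,
# 2 = int16, 3 = int32, 5 = float32, 7 = char; 0 encodes "no value"
# (used for flags and empty vectors).  Integers reserve the two lowest
# values of each width for the missing and end-of-vector sentinels;
# float32 uses two quiet-NaN bit patterns.

.BCF_MAGIC <- as.raw(c(0x42, 0x43, 0x46, 0x02, 0x02))   # "BCF\2\2"

.INT8_MISSING  <- -128L;        .INT8_EOV  <- -127L
.INT16_MISSING <- -32768L;      .INT16_EOV <- -32767L
.INT32_MISSING <- NA_integer_   # 0x80000000 is R's NA_integer_
.INT32_EOV     <- -2147483647L
.FLOAT_MISSING <- as.raw(c(0x01, 0x00, 0x80, 0x7f))
.FLOAT_EOV     <- as.raw(c(0x02, 0x00, 0x80, 0x7f))

## ---------------------------------------------------------------------------
## typed-value primitives
## ---------------------------------------------------------------------------

.encDescriptor <- function(count, code) {
  if (count < 15L) as.raw(count * 16L + code)
  else c(as.raw(15L * 16L + code), .encTypedIntScalar(count))
}

## smallest signed width that holds all (non-sentinel) values
.intCode <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(1L)
  lo <- min(v); hi <- max(v)
  if (lo >= -120 && hi <= 127) 1L
  else if (lo >= -32760 && hi <= 32767) 2L
  else 3L
}

.encIntAtoms <- function(v, eov, code) {
  v <- as.integer(v)
  if (code == 1L) {
    v[is.na(v)] <- .INT8_MISSING; v[eov] <- .INT8_EOV
    writeBin(v, raw(), size = 1L, endian = "little")
  } else if (code == 2L) {
    v[is.na(v)] <- .INT16_MISSING; v[eov] <- .INT16_EOV
    writeBin(v, raw(), size = 2L, endian = "little")
  } else {
    v[eov] <- .INT32_EOV                    # NA already IS the sentinel
    writeBin(v, raw(), size = 4L, endian = "little")
  }
}

.encTypedIntScalar <- function(n) {
  code <- .intCode(n)
  c(.encDescriptor(1L, code), .encIntAtoms(as.integer(n), FALSE, code))
}

## encode an integer vector as one typed value (INFO usage)
.encTypedInt <- function(v, eov = rep(FALSE, length(v))) {
  if (length(v) == 0L) return(.encDescriptor(0L, 1L))
  code <- .intCode(v[!eov])
  c(.encDescriptor(length(v), code), .encIntAtoms(v, eov, code))
}

.encFloatAtoms <- function(v, eov) {
  b <- writeBin(as.numeric(ifelse(is.na(v), 0, v)), raw(), size = 4L,
                endian = "little")
  sent <- which(is.na(v) & !eov)
  for (i in sent) b[(4L * i - 3L):(4L * i)] <- .FLOAT_MISSING
  for (i in which(eov)) b[(4L * i - 3L):(4L * i)] <- .FLOAT_EOV
  b
}

.encTypedFloat <- function(v, eov = rep(FALSE, length(v))) {
  if (length(v) == 0L) return(.encDescriptor(0L, 5L))
  c(.encDescriptor(length(v), 5L), .encFloatAtoms(v, eov))
}

.encTypedChar <- function(s) {
  if (is.na(s) || !nchar(s)) s <- "."
  b <- charToRaw(s)
  c(.encDescriptor(length(b), 7L), b)
}

## decode one typed value starting at 0-based offset `off`
## returns list(values, eov (logical mask), code, consumed)
.decTyped <- function(x, off) {
  d <- .u8(x, off)
  code <- d %% 16L
  count <- d %/% 16L
  p <- off + 1L
  if (count == 15L) {
    sc <- .decTyped(x, p)
    count <- as.integer(sc$values)
    p <- sc$consumedEnd
  }
  r <- .decAtoms(x, p, count, code)
  r$code <- code
  r$consumedEnd <- r$consumedEnd
  r
}

.decAtoms <- function(x, p, count, code) {
  if (code == 0L || count == 0L)
    return(list(values = integer(0), eov = logical(0), consumedEnd = p,
                code = code))
  if (code == 1L) {
    v <- readBin(x[(p + 1L):(p + count)], "integer", n = count, size = 1L,
                 signed = TRUE, endian = "little")
    eov <- v == .INT8_EOV
    v[v == .INT8_MISSING | eov] <- NA_integer_
    list(values = v, eov = eov, consumedEnd = p + count)
  } else if (code == 2L) {
    v <- readBin(x[(p + 1L):(p + 2L * count)], "integer", n = count,
                 size = 2L, signed = TRUE, endian = "little")
    eov <- v == .INT16_EOV
    v[v == .INT16_MISSING | eov] <- NA_integer_
    list(values = v, eov = eov, consumedEnd = p + 2L * count)
  } else if (code == 3L) {
    v <- readBin(x[(p + 1L):(p + 4L * count)], "integer", n = count,
                 size = 4L, endian = "little")
    eov <- !is.na(v) & v == .INT32_EOV
    v[eov] <- NA_integer_
    list(values = v, eov = eov, consumedEnd = p + 4L * count)
  } else if (code == 5L) {
    seg <- x[(p + 1L):(p + 4L * count)]
    v <- readBin(seg, "numeric", n = count, size = 4L, endian = "little")
    m <- matrix(seg, nrow = 4L)
    isMiss <- colSums(m == .FLOAT_MISSING) == 4L
    isEov <- colSums(m == .FLOAT_EOV) == 4L
    v[isMiss | isEov] <- NA_real_
    list(values = v, eov = isEov, consumedEnd = p + 4L * count)
  } else if (code == 7L) {
    seg <- x[(p + 1L):(p + count)]
    seg <- seg[seg != as.raw(0L)]
    list(values = if (length(seg)) rawToChar(seg) else "",
         eov = logical(0), consumedEnd = p + count)
  } else {
    vsError(sprintf("reserved BCF type code %d", code), "bcf_format")
  }
}

#' Encode / decode a single BCF typed value
#'
#' The low-level typed-value codec, exposed mainly for testing and
#' inspection.  \code{encodeTyped} picks the smallest integer width that
#' holds all values when \code{type} is omitted; missing values (\code{NA})
#' and end-of-vector padding round-trip through the per-width sentinels.
#'
#' @param values integer/numeric vector or a single character string.
#' @param type force \code{"Integer"}, \code{"Float"} or
#'   \code{"Character"}; default chooses from the R type.
#' @param eov logical mask marking trailing values that are end-of-vector
#'   padding rather than data.
#' @param x raw vector; \code{offset} 0-based start of the descriptor.
#' @return \code{encodeTyped}: raw vector.  \code{decodeTyped}: list with
#'   \code{values}, \code{eov}, \code{code} (the atom type code) and
#'   \code{consumed} (bytes).
#' @export
encodeTyped <- function(values, type = NULL,
                        eov = rep(FALSE, length(values))) {
  if (is.null(type))
    type <- if (is.character(values)) "Character"
            else if (is.integer(values) ||
                     (is.numeric(values) &&
                      all(values[!is.na(values)] == trunc(
                        values[!is.na(values)])))) "Integer"
            else "Float"
  switch(type,
         Integer = .encTypedInt(as.integer(values), eov),
         Float = .encTypedFloat(values, eov),
         Character = ,
         String = .encTypedChar(values),
         vsError(sprintf("cannot encode type '%s'", type), "bcf_format"))
}

#' @rdname encodeTyped
#' @param offset 0-based byte offset of the descriptor within \code{x}.
#' @export
decodeTyped <- function(x, offset = 0) {
  if (offset >= length(x))
    vsError("truncated typed value", "bcf_format")
  r <- tryCatch(.decTyped(x, offset), error = function(e) {
    if (inherits(e, "vsError")) stop(e)
    vsError("truncated typed value", "bcf_format")
  })
  if (r$consumedEnd > length(x))
    vsError("truncated typed value", "bcf_format")
  list(values = r$values, eov = r$eov, code = r$code,
       consumed = as.integer(r$consumedEnd - offset))
}

## ---------------------------------------------------------------------------
## header block
## ---------------------------------------------------------------------------

#' Read / write the BCF header block
#'
#' The header block is the magic \code{"BCF\\2\\2"} followed by a
#' length-prefixed, NUL-terminated copy of the VCF header text.  On write,
#' explicit \code{IDX=} attributes pin the string dictionary; on read,
#' explicit attributes are honored and otherwise indices are assigned in
#' declaration order (PASS = 0).
#'
#' @param r a \code{BgzfReader} positioned at the start of the stream.
#' @return \code{readBcfHeader}: a \linkS4class{VcfHeader}.
#' @export
readBcfHeader <- function(r) {
  magic <- bgzfRead(r, 5L)
  if (length(magic) < 5L || !identical(magic[1:3], .BCF_MAGIC[1:3]))
    vsError(sprintf("bad BCF magic: found '%s'",
                    paste(sprintf("%02x", as.integer(magic)),
                          collapse = " ")), "bcf_format")
  if (!identical(magic[4:5], .BCF_MAGIC[4:5])) {
    if (identical(magic[4], as.raw(2L)))
      warning(sprintf("BCF version 2.%d; reading best-effort as 2.2",
                      as.integer(magic[5])))
    else
      vsError(sprintf("unsupported BCF version %d.%d",
                      as.integer(magic[4]), as.integer(magic[5])),
              "bcf_format")
  }
  lenB <- bgzfRead(r, 4L)
  ltext <- .u32(lenB, 0L)
  txt <- bgzfRead(r, ltext)
  txt <- txt[txt != as.raw(0L)]
  lines <- strsplit(rawToChar(txt), "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parseVcfHeader(lines)
}

#' @rdname readBcfHeader
#' @param header a \linkS4class{VcfHeader}.
#' @param w a \code{BgzfWriter}.
#' @export
writeBcfHeader <- function(w, header) {
  txt <- paste0(paste(formatVcfHeader(header, withIdx = TRUE),
                      collapse = "\n"), "\n")
  b <- c(charToRaw(txt), as.raw(0L))
  bgzfWrite(w, .BCF_MAGIC)
  bgzfWrite(w, .putU32(length(b)))
  bgzfWrite(w, b)
  invisible(w)
}

## ---------------------------------------------------------------------------
## record block
## ---------------------------------------------------------------------------

## GT strings -> per-sample packed integer lists
.gtPack <- function(gt) {
  lapply(gt, function(s) {
    if (is.na(s) || s == ".") return(0L)          # fully missing, ploidy 1
    g <- .parseGenotype(s)
    a <- g@alleles
    phase <- c(FALSE, g@phased)
    as.integer(2L * (ifelse(is.na(a), -1L, a) + 1L) + as.integer(phase))
  })
}

.gtUnpack <- function(ints, eov) {
  ints <- ints[!eov]
  if (!length(ints)) return(".")
  a <- ints %/% 2L - 1L
  ph <- ints %% 2L == 1L
  sym <- ifelse(a < 0 | is.na(a), ".", as.character(a))
  if (length(sym) == 1L) return(sym)
  seps <- ifelse(ph[-1L], "|", "/")
  paste0(sym[1L], paste0(seps, sym[-1L], collapse = ""))
}

## pad a list of vectors to uniform length, returning values + eov mask
.padVectors <- function(vals, padLen) {
  n <- length(vals)
  out <- vector("list", n); eov <- vector("list", n)
  for (i in seq_len(n)) {
    v <- vals[[i]]
    if (length(v) == 0L) v <- NA
    k <- padLen - length(v)
    out[[i]] <- c(v, rep(if (is.numeric(v)) NA else NA, k))
    eov[[i]] <- c(rep(FALSE, length(v)), rep(TRUE, k))
  }
  list(values = unlist(out, use.names = FALSE),
       eov = unlist(eov, use.names = FALSE))
}

#' Encode a record as a BCF block
#'
#' Produces the complete binary block (including the two length prefixes).
#' All ids used by the record must exist in the header dictionary.
#' Genotypes pack as \code{(allele + 1) * 2 + phase-bit} with 0 for a
#' missing allele; samples of lower ploidy are padded with the
#' end-of-vector sentinel.
#'
#' @param record a \linkS4class{VcfRecord}.
#' @param header the governing \linkS4class{VcfHeader}.
#' @return raw vector.
#' @export
encodeBcfRecord <- function(record, header) {
  dict <- .headerDict(header)
  dictIdx <- function(id, what) {
    i <- match(id, dict)
    if (anyNA(i))
      vsError(sprintf("%s id '%s' absent from header dictionary", what,
                      paste(id[is.na(i)], collapse = ",")), "bcf_dict")
    i - 1L
  }
  ci <- match(record@chrom, header@contigs$id)
  if (is.na(ci))
    vsError(sprintf("contig '%s' absent from header", record@chrom),
            "bcf_dict")
  contigIdx <- header@contigs$idx[ci]
  if (record@nSamples != length(header@samples))
    vsError("record sample count disagrees with header", "bcf_format")

  infoEnd <- if (!is.null(record@info[["END"]]))
    as.numeric(record@info[["END"]][1]) else NA_real_
  sp <- .recordSpan(record@pos, nchar(record@ref), infoEnd)
  rlen <- sp[, "end"] - sp[, "beg"]

  shared <- list(
    .putI32(contigIdx),
    .putI32(record@pos - 1),
    .putI32(rlen),
    if (is.na(record@qual)) .FLOAT_MISSING
    else writeBin(as.numeric(record@qual), raw(), size = 4L,
                  endian = "little"),
    .putU16(length(record@info)),
    .putU16(1L + length(record@alt)),
    .putU32(record@nSamples + 16777216 * length(record@formatKeys)),
    .encTypedChar(record@id),
    .encTypedChar(record@ref))
  for (a in record@alt)
    shared[[length(shared) + 1L]] <- .encTypedChar(a)
  shared[[length(shared) + 1L]] <-
    if (all(is.na(record@filter))) .encDescriptor(0L, 1L)
    else .encTypedInt(dictIdx(record@filter, "FILTER"))
  for (k in names(record@info)) {
    v <- record@info[[k]]
    def <- .fieldDef(header, "INFO", k)
    if (is.null(def))
      vsError(sprintf("INFO id '%s' absent from header dictionary", k),
              "bcf_dict")
    shared[[length(shared) + 1L]] <- .encTypedIntScalar(dictIdx(k, "INFO"))
    shared[[length(shared) + 1L]] <- switch(def$type,
      Flag = .encDescriptor(0L, 0L),
      Integer = .encTypedInt(as.integer(v)),
      Float = .encTypedFloat(as.numeric(v)),
      .encTypedChar(paste(ifelse(is.na(v), ".", as.character(v)),
                          collapse = ",")))
  }

  indiv <- list()
  if (record@nSamples > 0L) for (k in record@formatKeys) {
    def <- .fieldDef(header, "FORMAT", k)
    if (is.null(def))
      vsError(sprintf("FORMAT id '%s' absent from header dictionary", k),
              "bcf_dict")
    indiv[[length(indiv) + 1L]] <- .encTypedIntScalar(dictIdx(k, "FORMAT"))
    if (k == "GT") {
      packed <- .gtPack(.gtStrings(record))
      width <- max(lengths(packed))
      pv <- .padVectors(packed, width)
      code <- .intCode(pv$values)
      indiv[[length(indiv) + 1L]] <-
        c(.encDescriptor(width, code),
          .encIntAtoms(pv$values, pv$eov, code))
    } else {
      vals <- formatValues(record, k, header)
      if (def$type %in% c("Integer", "Float")) {
        width <- max(lengths(vals), 1L)
        pv <- .padVectors(vals, width)
        if (def$type == "Integer") {
          code <- .intCode(pv$values)
          indiv[[length(indiv) + 1L]] <-
            c(.encDescriptor(width, code),
              .encIntAtoms(as.integer(pv$values), pv$eov, code))
        } else {
          indiv[[length(indiv) + 1L]] <-
            c(.encDescriptor(width, 5L),
              .encFloatAtoms(as.numeric(pv$values), pv$eov))
        }
      } else {
        ss <- vapply(vals, function(v) {
          if (all(is.na(v))) "." else paste(v, collapse = ",")
        }, character(1))
        width <- max(nchar(ss), 1L)
        atoms <- lapply(ss, function(s) {
          b <- charToRaw(s)
          c(b, rep(as.raw(0L), width - length(b)))
        })
        indiv[[length(indiv) + 1L]] <-
          c(.encDescriptor(width, 7L), do.call(c, atoms))
      }
    }
  }
  sharedB <- do.call(c, shared)
  indivB <- if (length(indiv)) do.call(c, indiv) else raw()
  c(.putU32(length(sharedB)), .putU32(length(indivB)), sharedB, indivB)
}

#' Decode a BCF record block
#'
#' @param shared raw vector: the shared (site-level) section, starting at
#'   CHROM and including the packed sample/format counts at its end.
#' @param indiv raw vector: the per-sample section.
#' @param header the governing \linkS4class{VcfHeader}.
#' @return a \linkS4class{VcfRecord}.
#' @rdname encodeBcfRecord
#' @export
decodeBcfRecord <- function(shared, indiv, header) {
  dict <- .headerDict(header)
  p <- 0L
  contigIdx <- .i32(shared, p); p <- p + 4L
  pos0 <- .i32(shared, p); p <- p + 4L
  p <- p + 4L                                   # rlen (derivable)
  qseg <- shared[(p + 1L):(p + 4L)]
  qual <- if (identical(qseg, .FLOAT_MISSING)) NA_real_
          else readBin(qseg, "numeric", n = 1L, size = 4L,
                       endian = "little")
  p <- p + 4L
  nInfo <- .u16(shared, p); p <- p + 2L
  nAllele <- .u16(shared, p); p <- p + 2L
  nSample <- .u32(shared, p) %% 16777216
  nFmt <- .u32(shared, p) %/% 16777216
  p <- p + 4L

  dID <- .decTyped(shared, p); p <- dID$consumedEnd
  id <- if (is.character(dID$values) && nzchar(dID$values) &&
            dID$values != ".") dID$values else NA_character_
  alleles <- character(nAllele)
  for (i in seq_len(nAllele)) {
    dA <- .decTyped(shared, p); p <- dA$consumedEnd
    alleles[i] <- dA$values
  }
  dF <- .decTyped(shared, p); p <- dF$consumedEnd
  filt <- if (length(dF$values) == 0L) NA_character_
          else dict[as.integer(dF$values) + 1L]
  info <- list()
  for (i in seq_len(nInfo)) {
    dK <- .decTyped(shared, p); p <- dK$consumedEnd
    key <- dict[as.integer(dK$values) + 1L]
    dV <- .decTyped(shared, p); p <- dV$consumedEnd
    def <- .fieldDef(header, "INFO", key)
    val <- if (!is.null(def) && def$type == "Flag") TRUE
    else if (dV$code == 7L) {
      vv <- strsplit(dV$values, ",", fixed = TRUE)[[1]]
      vv[vv == "."] <- NA_character_
      vv
    } else dV$values
    info[[key]] <- val
  }

  fmtKeys <- character(0)
  sampleData <- list()
  ip <- 0L
  contigs <- header@contigs[order(header@contigs$idx), , drop = FALSE]
  for (i in seq_len(nFmt)) {
    dK <- .decTyped(indiv, ip); ip <- dK$consumedEnd
    key <- dict[as.integer(dK$values) + 1L]
    fmtKeys <- c(fmtKeys, key)
    d <- .u8(indiv, ip)
    code <- d %% 16L; cnt <- d %/% 16L
    ip <- ip + 1L
    if (cnt == 15L) {
      sc <- .decTyped(indiv, ip)
      cnt <- as.integer(sc$values); ip <- sc$consumedEnd
    }
    if (code == 7L) {
      vals <- vector("list", nSample)
      for (s in seq_len(nSample)) {
        seg <- indiv[(ip + 1L):(ip + cnt)]
        seg <- seg[seg != as.raw(0L)]
        sv <- if (length(seg)) rawToChar(seg) else "."
        sv <- strsplit(sv, ",", fixed = TRUE)[[1]]
        sv[sv == "."] <- NA_character_
        vals[[s]] <- sv
        ip <- ip + cnt
      }
      sampleData[[key]] <- vals
    } else {
      tot <- cnt * nSample
      at <- .decAtoms(indiv, ip, tot, code)
      ip <- at$consumedEnd
      vals <- vector("list", nSample)
      for (s in seq_len(nSample)) {
        sl <- ((s - 1L) * cnt + 1L):(s * cnt)
        if (key == "GT") {
          vals[[s]] <- .gtUnpack(at$values[sl], at$eov[sl])
        } else {
          v <- at$values[sl]
          e <- at$eov[sl]
          vals[[s]] <- v[!e]
        }
      }
      sampleData[[key]] <- vals
    }
  }
  ctgRow <- match(contigIdx, contigs$idx)
  if (is.na(ctgRow))
    vsError(sprintf("contig index %d not in header dictionary", contigIdx),
            "bcf_dict")
  new("VcfRecord",
      chrom = contigs$id[ctgRow], pos = pos0 + 1,
      id = id, ref = alleles[1],
      alt = if (nAllele > 1L) alleles[-1L] else character(),
      qual = qual, filter = filt, info = info,
      formatKeys = fmtKeys, sampleRaw = character(),
      sampleData = sampleData, nSamples = as.integer(nSample))
}
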