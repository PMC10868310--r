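# Tabix-style interval index (.tbi, VCF preset) over a coordinate-sorted,
# BGZF-compressed VCF.
#
# The binning scheme divides a 2^29-bp range into 5 nested levels of bins:
# bin 0 spans the whole range, bins 1-8 span 2^26 each, 9-72 span 2^23,
# 73-584 span 2^20, 585-4680 span 2^17, and 4681-37448 span 2^14.  Each
# record is filed under the smallest bin containing its reference span;
# each bin maps to "chunks" — [begin, end) virtual-offset ranges of the
# compressed file.  A linear index of the smallest record start per
# 16384-bp window lets queries skip chunks that end before any record
# that could overlap the query.

.TBX_MAX_COOR <- 2^29
.TBX_WINDOW <- 16384
.TBX_MAGIC <- as.raw(c(0x54, 0x42, 0x49, 0x01))   # "TBI\1"

.checkBinRange <- function(beg, end) {
  if (any(beg < 0) || any(end <= beg) || any(end > .TBX_MAX_COOR))
    vsError("coordinates out of the tabix range [0, 2^29)", "tbx_range")
}

#' Tabix binning arithmetic
#'
#' \code{reg2bin} returns the smallest bin whose span fully contains the
#' 0-based half-open interval \code{[beg, end)}; \code{reg2bins} returns
#' every bin (ascending) whose span overlaps it.  Both are vectorized over
#' \code{beg}/\code{end} in \code{reg2bin}; \code{reg2bins} takes scalars.
#'
#' @param beg 0-based inclusive start(s).
#' @param end 0-based exclusive end(s); must satisfy
#'   \code{0 <= beg < end <= 2^29}.
#' @return integer bin id(s) in [0, 37448].
#' @examples
#' reg2bin(0, 1)        # 4681: the first 16-kb leaf bin
#' reg2bins(0, 1)       # its chain of enclosing bins: 0 1 9 73 585 4681
#' @export
reg2bin <- function(beg, end) {
  .checkBinRange(beg, end)
  e <- end - 1
  out <- integer(length(beg))
  lvl <- function(shift) (beg %/% 2^shift) == (e %/% 2^shift)
  done <- rep(FALSE, length(beg))
  for (p in list(c(14, 4681), c(17, 585), c(20, 73), c(23, 9), c(26, 1))) {
    hit <- !done & lvl(p[1])
    out[hit] <- p[2] + beg[hit] %/% 2^p[1]
    done <- done | hit
  }
  out[!done] <- 0L
  as.integer(out)
}

#' @rdname reg2bin
#' @export
reg2bins <- function(beg, end) {
  stopifnot(length(beg) == 1L, length(end) == 1L)
  .checkBinRange(beg, end)
  e <- end - 1
  c(0L,
    as.integer(1    + beg %/% 2^26):as.integer(1    + e %/% 2^26),
    as.integer(9    + beg %/% 2^23):as.integer(9    + e %/% 2^23),
    as.integer(73   + beg %/% 2^20):as.integer(73   + e %/% 2^20),
    as.integer(585  + beg %/% 2^17):as.integer(585  + e %/% 2^17),
    as.integer(4681 + beg %/% 2^14):as.integer(4681 + e %/% 2^14))
}

#' Parse a region string
#'
#' Accepts \code{"chr"}, \code{"chr:beg"} and \code{"chr:beg-end"}
#' (1-based, inclusive), with optional thousands separators in the
#' coordinates (\code{"chr21:5,010,000-5,020,000"}).  Without an end, the
#' region extends to the contig end.
#'
#' @param x character(1) region string, or a \code{Region} (returned
#'   unchanged).
#' @return a \linkS4class{Region}.
#' @export
parseRegion <- function(x) {
  if (is(x, "Region")) return(x)
  if (!is.character(x) || length(x) != 1L || !nzchar(x))
    vsError("region must be a single non-empty string", "region_parse")
  num <- function(s) as.numeric(gsub(",", "", s, fixed = TRUE))
  m <- regmatches(x, regexec("^(.+):([0-9][0-9,]*)-([0-9][0-9,]*)$", x))[[1]]
  if (length(m) == 4L) {
    contig <- m[2]; beg <- num(m[3]); end <- num(m[4])
  } else {
    m <- regmatches(x, regexec("^(.+):([0-9][0-9,]*)$", x))[[1]]
    if (length(m) == 3L) {
      contig <- m[2]; beg <- num(m[3]); end <- Inf
    } else if (grepl(":", x, fixed = TRUE) &&
               grepl(":[0-9,-]*$", x)) {
      vsError(sprintf("malformed region string: '%s'", x), "region_parse")
    } else {
      contig <- x; beg <- 1; end <- Inf
    }
  }
  if (is.na(beg) || beg < 1 || (is.finite(end) && end < beg))
    vsError(sprintf("malformed region string: '%s'", x), "region_parse")
  new("Region", contig = contig, start = beg, end = end)
}

setMethod("show", "Region", function(object) {
  cat(sprintf("Region %s:%s-%s\n", object@contig,
              format(object@start, big.mark = ","),
              if (is.finite(object@end))
                format(object@end, big.mark = ",") else "end"))
})

## reference span of a VCF record in 0-based half-open coordinates:
## [pos-1, pos-1 + max(len(REF), END-pos+1)); symbolic alleles honor
## INFO END.  Vectorized.
.recordSpan <- function(pos, refLen, infoEnd) {
  beg <- pos - 1
  span <- pmax(refLen, 1)
  hasEnd <- !is.na(infoEnd)
  span[hasEnd] <- pmax(span[hasEnd], infoEnd[hasEnd] - pos[hasEnd] + 1)
  cbind(beg = beg, end = beg + span)
}

## minimal vectorized body-line parse used by the indexer and the
## linear-scan fallback: CHROM, POS, REF length, INFO END
.scanBodyFields <- function(lines) {
  chrom <- sub("\t.*$", "", lines)
  rest <- sub("^[^\t]*\t", "", lines)
  pos <- as.numeric(sub("\t.*$", "", rest))
  ## field 4 (REF): skip ID
  rest <- sub("^[^\t]*\t[^\t]*\t", "", rest)
  refLen <- nchar(sub("\t.*$", "", rest))
  infoEnd <- rep(NA_real_, length(lines))
  idx <- grep("(\t|;)END=[0-9]+", lines)
  if (length(idx))
    infoEnd[idx] <- as.numeric(sub(".*(?:\t|;)END=([0-9]+).*", "\\1",
                                   lines[idx]))
  list(chrom = chrom, pos = pos, refLen = refLen, infoEnd = infoEnd)
}

#' Build a tabix index from a BGZF-compressed VCF
#'
#' Streams the file once, recording each record's virtual-offset range and
#' filing it under its bin.  Records must be coordinate-sorted within each
#' contig and contigs must not be interleaved.
#'
#' @param path path to a BGZF-compressed VCF.
#' @return a \linkS4class{TabixIndex}.
#' @seealso [queryChunks()], [writeTabix()], [readTabix()]
#' @export
buildTabixIndex <- function(path) {
  r <- bgzfOpen(path)
  on.exit(close(r))
  lines <- character(0); voffs <- numeric(0)
  chunkL <- 4096L
  lines <- vector("character", chunkL); voffs <- numeric(chunkL); n <- 0L
  repeat {
    v <- bgzfTell(r)
    ln <- bgzfReadLine(r)
    if (is.null(ln)) break
    n <- n + 1L
    if (n > length(lines)) {
      length(lines) <- 2L * length(lines); length(voffs) <- 2L * length(voffs)
    }
    lines[n] <- ln; voffs[n] <- v
  }
  endOff <- bgzfTell(r)
  length(lines) <- n; length(voffs) <- n
  body <- !startsWith(lines, "#")
  lines <- lines[body]
  begV <- voffs[body]
  endV <- c(voffs[body][-1], endOff)
  ## record i occupies [begV[i], next line start); when followed by a header
  ## line (impossible in sorted files) this would be wrong, but headers
  ## always precede the body
  if (length(lines) == 0L)
    return(new("TabixIndex", contigs = character(), chunks = list(),
               linear = list()))
  f <- .scanBodyFields(lines)
  if (any(is.na(f$pos)))
    vsError("non-numeric POS in body", "vcf_format")
  sp <- .recordSpan(f$pos, f$refLen, f$infoEnd)
  if (any(sp[, "end"] > .TBX_MAX_COOR))
    vsError("record beyond 2^29-1: outside the .tbi dialect range",
            "tbx_range")
  ## sort-order checks
  contigRle <- rle(f$chrom)
  if (anyDuplicated(contigRle$values)) {
    bad <- contigRle$values[duplicated(contigRle$values)][1]
    vsError(sprintf("records of contig '%s' are not contiguous", bad),
            "tbx_sort")
  }
  dpos <- diff(f$pos)
  newContig <- diff(match(f$chrom, contigRle$values)) != 0
  bad <- which(dpos < 0 & !newContig)
  if (length(bad))
    vsError(sprintf("unsorted input: record %s:%d follows %s:%d",
                    f$chrom[bad[1] + 1], f$pos[bad[1] + 1],
                    f$chrom[bad[1]], f$pos[bad[1]]), "tbx_sort")
  bins <- reg2bin(sp[, "beg"], sp[, "end"])
  contigs <- contigRle$values
  chunks <- vector("list", length(contigs))
  linear <- vector("list", length(contigs))
  splitIdx <- split(seq_along(lines), factor(f$chrom, levels = contigs))
  for (ci in seq_along(contigs)) {
    ii <- splitIdx[[ci]]
    b <- bins[ii]
    ## runs of identical consecutive bins become single chunks
    rl <- rle(b)
    last <- cumsum(rl$lengths)
    first <- last - rl$lengths + 1L
    ch <- data.frame(bin = as.numeric(rl$values),
                     beg = begV[ii][first], end = endV[ii][last])
    ch <- ch[order(ch$bin, ch$beg), , drop = FALSE]
    ## merge overlapping/adjacent chunks within a bin
    keep <- logical(nrow(ch)); keep[1] <- TRUE; j <- 1L
    if (nrow(ch) > 1) for (k in 2:nrow(ch)) {
      if (ch$bin[k] == ch$bin[j] && ch$beg[k] <= ch$end[j]) {
        ch$end[j] <- max(ch$end[j], ch$end[k])
      } else { j <- k; keep[k] <- TRUE }
    }
    ch <- ch[keep, , drop = FALSE]
    rownames(ch) <- NULL
    chunks[[ci]] <- ch
    ## linear index: first record start voff touching each 16-kb window
    wb <- sp[ii, "beg"] %/% .TBX_WINDOW
    we <- (sp[ii, "end"] - 1) %/% .TBX_WINDOW
    lin <- rep(NA_real_, max(we) + 1L)
    vo <- begV[ii]
    simple <- wb == we
    fidx <- !duplicated(wb) & simple
    lin[wb[fidx] + 1] <- vo[fidx]
    for (k in which(!simple)) {
      ws <- (wb[k]:we[k]) + 1
      unset <- is.na(lin[ws])
      lin[ws[unset]] <- vo[k]
    }
    linear[[ci]] <- .locf(lin, lead = 0)
  }
  names(chunks) <- names(linear) <- NULL
  new("TabixIndex", contigs = contigs, chunks = chunks, linear = linear)
}

#' Query a tabix index for candidate chunks
#'
#' Returns the merged, ascending list of virtual-offset chunks that may
#' contain records overlapping the region.  Chunks ending before the linear
#' index's lower bound for the region start are pruned; chunks closer than
#' 65536 virtual units are coalesced to avoid pointless reseeks.  A contig
#' absent from the index yields an empty result, not an error.
#'
#' @param index a \linkS4class{TabixIndex}.
#' @param region a \linkS4class{Region} or region string.
#' @return data.frame with columns \code{beg} and \code{end} (virtual
#'   offsets), possibly empty.
#' @export
queryChunks <- function(index, region) {
  region <- parseRegion(region)
  ci <- match(region@contig, index@contigs)
  empty <- data.frame(beg = numeric(), end = numeric())
  if (is.na(ci)) return(empty)
  beg0 <- region@start - 1
  end0 <- min(region@end, .TBX_MAX_COOR)
  if (beg0 >= end0) return(empty)
  bins <- reg2bins(beg0, end0)
  ch <- index@chunks[[ci]]
  ch <- ch[ch$bin %in% bins, , drop = FALSE]
  if (!nrow(ch)) return(empty)
  lin <- index@linear[[ci]]
  w <- beg0 %/% .TBX_WINDOW + 1
  if (w > length(lin)) return(empty)
  minoff <- lin[w]
  ch <- ch[ch$end > minoff, , drop = FALSE]
  if (!nrow(ch)) return(empty)
  ch$beg <- pmax(ch$beg, minoff)
  ch <- ch[order(ch$beg, ch$end), , drop = FALSE]
  beg <- ch$beg[1]; end <- ch$end[1]
  obeg <- numeric(); oend <- numeric()
  if (nrow(ch) > 1) for (k in 2:nrow(ch)) {
    if (ch$beg[k] - end < 65536) {
      end <- max(end, ch$end[k])
    } else {
      obeg <- c(obeg, beg); oend <- c(oend, end)
      beg <- ch$beg[k]; end <- ch$end[k]
    }
  }
  data.frame(beg = c(obeg, beg), end = c(oend, end))
}

## ---------------------------------------------------------------------------
## .tbi serialization (BGZF-wrapped, magic "TBI\1")
## ---------------------------------------------------------------------------

#' Read / write tabix index files
#'
#' \code{writeTabix} serializes with the tabix VCF preset meta numbers
#' (format=2, col_seq=1, col_beg=2, col_end=0, meta='#', skip=0);
#' \code{readTabix} accepts indices written by this package or by an
#' independent tabix implementation (the metadata pseudo-bin 37450 is
#' skipped).  Round trips are structurally lossless.
#'
#' @param index a \linkS4class{TabixIndex}.
#' @param path file path (conventionally \code{<vcf>.tbi}).
#' @return \code{readTabix} returns a \linkS4class{TabixIndex};
#'   \code{writeTabix} returns \code{path} invisibly.
#' @export
writeTabix <- function(index, path) {
  m <- index@meta
  nameBytes <- if (length(index@contigs))
    do.call(c, lapply(index@contigs, function(s) c(charToRaw(s),
                                                   as.raw(0L))))
  else raw()
  parts <- list(.TBX_MAGIC, .putI32(length(index@contigs)),
                .putI32(m$format), .putI32(m$col_seq), .putI32(m$col_beg),
                .putI32(m$col_end), .putI32(utf8ToInt(m$meta)),
                .putI32(m$skip), .putI32(length(nameBytes)), nameBytes)
  for (ci in seq_along(index@contigs)) {
    ch <- index@chunks[[ci]]
    ub <- unique(ch$bin)
    parts[[length(parts) + 1L]] <- .putI32(length(ub))
    for (b in ub) {
      rows <- ch[ch$bin == b, , drop = FALSE]
      parts[[length(parts) + 1L]] <- c(
        .putU32(b), .putI32(nrow(rows)),
        .putU64v(as.numeric(t(cbind(rows$beg, rows$end)))))
    }
    lin <- index@linear[[ci]]
    parts[[length(parts) + 1L]] <- c(.putI32(length(lin)), .putU64v(lin))
  }
  if (!is.na(index@nNoCoor))
    parts[[length(parts) + 1L]] <- .putU64(index@nNoCoor)
  .bgzfDump(do.call(c, parts), path)
  invisible(path)
}

#' @rdname writeTabix
#' @export
readTabix <- function(path) {
  x <- tryCatch(.bgzfSlurp(path), vsError = function(e)
    vsError(paste0("not a tabix index (", conditionMessage(e), ")"),
            "tbi_format"))
  p <- 0
  need <- function(n) if (p + n > length(x))
    vsError("truncated tabix index", "tbi_format")
  need(4L)
  if (!identical(x[1:4], .TBX_MAGIC))
    vsError("bad magic: not a .tbi file", "tbi_format")
  p <- 4
  rd32 <- function() { need(4); v <- .i32(x, p); p <<- p + 4; v }
  rd64 <- function() { need(8); v <- .u64(x, p); p <<- p + 8; v }
  nref <- rd32()
  meta <- list(format = as.numeric(rd32()), col_seq = as.numeric(rd32()),
               col_beg = as.numeric(rd32()), col_end = as.numeric(rd32()),
               meta = intToUtf8(rd32()), skip = as.numeric(rd32()))
  lnm <- rd32(); need(lnm)
  nmraw <- x[(p + 1):(p + lnm)]; p <- p + lnm
  contigs <- if (lnm) {
    ## names are NUL-terminated and concatenated; split on the NULs
    nuls <- c(0L, which(nmraw == as.raw(0)))
    vapply(seq_len(length(nuls) - 1L), function(k) {
      span <- (nuls[k] + 1L):(nuls[k + 1L] - 1L)
      if (nuls[k + 1L] - nuls[k] <= 1L) "" else rawToChar(nmraw[span])
    }, character(1))
  } else character()
  if (length(contigs) != nref)
    vsError("contig name count disagrees with n_ref", "tbi_format")
  ## vectorized u64 reader at arbitrary 0-based offsets
  u64v <- function(offs) {
    if (!length(offs)) return(numeric(0))
    b <- function(k) as.numeric(x[offs + k])
    (b(1) + 256 * b(2) + 65536 * b(3) + 16777216 * b(4)) +
      4294967296 * (b(5) + 256 * b(6) + 65536 * b(7) + 16777216 * b(8))
  }
  chunks <- vector("list", nref); linear <- vector("list", nref)
  for (ci in seq_len(max(nref, 0))) {
    nbin <- rd32()
    binId <- numeric(nbin); binN <- integer(nbin); binOff <- numeric(nbin)
    for (bi in seq_len(max(nbin, 0))) {      # walk bin headers only
      need(8)
      binId[bi] <- .u32(x, p); p <- p + 4
      binN[bi] <- .i32(x, p); p <- p + 4
      binOff[bi] <- p
      need(16 * binN[bi])
      p <- p + 16 * binN[bi]
    }
    keep <- binId <= 37448           # drop the metadata pseudo-bin 37450
    bins <- rep(binId[keep], binN[keep])
    offs <- unlist(lapply(which(keep), function(bi)
      binOff[bi] + 16 * (seq_len(binN[bi]) - 1L)), use.names = FALSE)
    if (is.null(offs)) offs <- numeric(0)
    ch <- data.frame(bin = bins, beg = u64v(offs), end = u64v(offs + 8))
    ch <- ch[order(ch$bin, ch$beg), , drop = FALSE]
    rownames(ch) <- NULL
    chunks[[ci]] <- ch
    nintv <- rd32()
    need(8 * nintv)
    linear[[ci]] <- u64v(p + 8 * (seq_len(max(nintv, 0)) - 1L))
    p <- p + 8 * nintv
  }
  nNoCoor <- if (p + 8 <= length(x)) rd64() else NA_real_
  new("TabixIndex", contigs = contigs, chunks = chunks, linear = linear,
      meta = meta, nNoCoor = nNoCoor)
}

setMethod("show", "TabixIndex", function(object) {
  cat(sprintf("TabixIndex over %d contig(s)\n", length(object@contigs)))
  for (i in seq_along(object@contigs))
    cat(sprintf("  %s: %d chunk(s), %d linear window(s)\n",
                object@contigs[i], nrow(object@chunks[[i]]),
                length(object@linear[[i]])))
})
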