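# Unified reader/writer facade over the three on-disk encodings:
# plain-text VCF, BGZF-compressed VCF (vcf.gz), and BCF.  The reader
# streams: it holds one decompressed BGZF block and surfaces at most one
# decoded record at a time, so memory use is independent of file size.
# Region constraints go through the tabix index on BGZF-compressed text
# (building one on the fly when no .tbi sidecar exists); on plain text,
# non-blocked gzip, and BCF they fall back to a linear scan with the same
# overlap predicate, so results are identical either way.

#' Sniff the on-disk encoding of a variant file
#'
#' Inspects the leading bytes: BGZF members are recognized by the gzip
#' magic plus \code{"BC"} extra field, then classified by their payload
#' prefix (\code{"BCF"} vs \code{"##"}); plain gzip without block
#' structure is \code{"vcf-gzip"} (sequential reading only); leading text
#' is \code{"vcf-plain"}.
#'
#' @param path file path.
#' @return one of \code{"vcf-plain"}, \code{"vcf-bgzf"}, \code{"vcf-gzip"},
#'   \code{"bcf"}.
#' @export
sniffFormat <- function(path) {
  head <- readBin(path, "raw", 4096L)
  if (length(head) >= 18L && isBgzf(head)) {
    payload <- tryCatch(bgzfDecompressBlock(head, 0L)$payload,
                        vsError = function(e) {
      ## first block larger than our probe: read the whole member
      n <- .bgzfParseHeader(head, 0L)$bsize
      bgzfDecompressBlock(readBin(path, "raw", n), 0L)$payload
    })
    if (length(payload) >= 3L &&
        identical(payload[1:3], .BCF_MAGIC[1:3])) return("bcf")
    if (length(payload) >= 2L && rawToChar(payload[1:2]) == "##")
      return("vcf-bgzf")
    vsError("BGZF stream with unrecognized payload", "format_unknown")
  }
  if (length(head) >= 2L && head[1] == as.raw(0x1f) &&
      head[2] == as.raw(0x8b))
    return("vcf-gzip")
  if (length(head) >= 3L && identical(head[1:3], .BCF_MAGIC[1:3]))
    return("bcf")   # raw, uncompressed BCF body
  txt <- head[seq_len(min(length(head), 64L))]
  if (length(txt) == 0L || any(txt == as.raw(0L)))
    vsError("unrecognized file format", "format_unknown")
  if (rawToChar(txt[1]) == "#") return("vcf-plain")
  vsError("unrecognized file format (no leading '#')", "format_unknown")
}

## parse a samples= request: character vector, comma list, "^"-prefixed
## exclusion, or "@file"
.resolveSamples <- function(spec, headerSamples) {
  if (is.null(spec)) return(NULL)
  if (length(spec) == 1L && startsWith(spec, "@"))
    spec <- readLines(sub("^@", "", spec), warn = FALSE)
  exclude <- length(spec) >= 1L && startsWith(spec[1], "^")
  if (exclude) spec[1] <- sub("^\\^", "", spec[1])
  spec <- unlist(strsplit(spec, ",", fixed = TRUE), use.names = FALSE)
  spec <- spec[nzchar(spec)]
  unknown <- setdiff(spec, headerSamples)
  if (length(unknown))
    vsError(paste0("unknown sample name(s): ",
                   paste(unknown, collapse = ", ")), "unknown_sample")
  if (exclude) which(!headerSamples %in% spec)
  else match(spec, headerSamples)
}

#' Open a VCF/BCF for streaming reads
#'
#' Opens any of the supported encodings, parses the header, and prepares
#' iteration under optional region and sample constraints.  Iteration via
#' \code{\link{readRecord}} then yields records in file order; with a
#' region, exactly the records whose reference span overlaps it; with
#' samples, each record's per-sample block projected to the requested
#' samples in the requested order before it is surfaced.
#'
#' @param path file path.
#' @param region optional \linkS4class{Region} or region string.
#' @param samples optional sample selection: a character vector or comma
#'   list of names (order respected), \code{"^a,b"} to exclude, or
#'   \code{"@file"} with one name per line.
#' @param strict escalate validation violations (undeclared tags, bad
#'   cardinalities) from warnings to errors.
#' @param index optional \code{.tbi} sidecar: a path, or a pre-loaded
#'   \linkS4class{TabixIndex} (handy when issuing many queries against one
#'   file); default: \code{<path>.tbi} when present, else built on the
#'   fly.
#' @return a \linkS4class{VcfReader}.
#' @examples
#' fx <- simulateVcf(seed = 1, nSamples = 3, nVariants = 50)
#' p <- tempfile(fileext = ".vcf")
#' writeLines(fx$lines, p)
#' r <- openVcf(p)
#' rec <- readRecord(r)
#' chrom(rec); pos(rec)
#' close(r)
#' @export
openVcf <- function(path, region = NULL, samples = NULL, strict = FALSE,
                    index = NULL) {
  if (!identical(path, "-") && !file.exists(path))
    vsError(sprintf("no such file: '%s'", path), "io_error")
  st <- new.env(parent = emptyenv())
  st$path <- path
  st$format <- if (identical(path, "-")) "vcf-plain" else sniffFormat(path)
  st$strict <- strict
  st$nRead <- 0
  st$current <- NULL      # the at-most-one surfaced record
  st$lineNo <- 0L

  headerLines <- character()
  if (st$format == "bcf") {
    ## the common on-disk form is BGZF-wrapped; a raw (uncompressed) body
    ## is also readable, through a reader presenting the same interface
    head <- readBin(path, "raw", 18L)
    st$bg <- if (length(head) >= 18L && isBgzf(head)) bgzfOpen(path)
             else .rawStreamReader(path)
    st$header <- readBcfHeader(st$bg)
  } else if (st$format == "vcf-bgzf") {
    st$bg <- bgzfOpen(path)
    repeat {
      v <- bgzfTell(st$bg)
      ln <- bgzfReadLine(st$bg)
      if (is.null(ln)) break
      if (startsWith(ln, "#")) headerLines <- c(headerLines, ln)
      else { st$pushback <- ln; st$pushbackVoff <- v; break }
      st$bodyVoff <- bgzfTell(st$bg)
    }
    st$header <- parseVcfHeader(headerLines)
  } else {
    st$con <- if (identical(path, "-")) stdin()
              else if (st$format == "vcf-gzip") gzfile(path, "rt")
              else file(path, "rt")
    repeat {
      ln <- readLines(st$con, n = 1L, warn = FALSE)
      if (length(ln) == 0L) break
      st$lineNo <- st$lineNo + 1L
      if (startsWith(ln, "#")) headerLines <- c(headerLines, ln)
      else { st$pushback <- ln; break }
    }
    st$header <- parseVcfHeader(headerLines)
  }

  cleanup <- function(e) {
    if (!is.null(st$bg)) close(st$bg)
    if (!is.null(st$con) && !identical(path, "-")) close(st$con)
    stop(e)
  }
  st$sampleIdx <- tryCatch(.resolveSamples(samples, st$header@samples),
                           error = cleanup)
  st$projHeader <- if (is.null(st$sampleIdx)) st$header else {
    h <- st$header
    h@samples <- h@samples[st$sampleIdx]
    h
  }

  if (!is.null(region)) {
    st$region <- tryCatch(parseRegion(region), error = cleanup)
    if (st$format == "vcf-bgzf") {
      idx <- if (is(index, "TabixIndex")) index else {
        tbi <- if (!is.null(index)) index else paste0(path, ".tbi")
        if (file.exists(tbi)) readTabix(tbi) else {
          vsNotice("no .tbi index found; building one on the fly")
          buildTabixIndex(path)
        }
      }
      st$chunks <- queryChunks(idx, st$region)
      st$chunkIdx <- 0L
      st$chunkEnd <- -Inf
      st$pushback <- NULL
    } else {
      if (st$format != "bcf")
        vsNotice("uncompressed input: region filter applied by linear scan")
      st$linearRegion <- TRUE
    }
  }
  reader <- new("VcfReader", state = st)
  reader
}

## does `rec` overlap the reader's region?
.recOverlaps <- function(rec, region) {
  if (rec@chrom != region@contig) return(FALSE)
  infoEnd <- if (!is.null(rec@info[["END"]]))
    as.numeric(rec@info[["END"]][1]) else NA_real_
  sp <- .recordSpan(rec@pos, nchar(rec@ref), infoEnd)
  sp[, "beg"] < region@end & sp[, "end"] >= region@start
}

.projectRecord <- function(rec, idx) {
  if (is.null(idx)) return(rec)
  if (length(rec@sampleRaw)) rec@sampleRaw <- rec@sampleRaw[idx]
  if (length(rec@sampleData))
    rec@sampleData <- lapply(rec@sampleData, function(v) v[idx])
  rec@nSamples <- length(idx)
  rec
}

## advisory fast path: undeclared ids only (the full checker, including
## cardinalities, runs in strict mode or on explicit validateRecord calls)
.quickViolations <- function(header, rec) {
  v <- character()
  bad <- setdiff(names(rec@info), header@infos$id)
  if (length(bad))
    v <- c(v, sprintf("INFO tag '%s' is not declared in the header", bad))
  bad <- setdiff(rec@formatKeys, header@formats$id)
  if (length(bad))
    v <- c(v, sprintf("FORMAT tag '%s' is not declared in the header", bad))
  bad <- setdiff(rec@filter[!is.na(rec@filter)],
                 c("PASS", header@filters$id))
  if (length(bad))
    v <- c(v, sprintf("FILTER id '%s' is not declared in the header", bad))
  v
}

.surfaceRecord <- function(st, rec) {
  if (st$strict) {
    viol <- validateRecord(st$header, rec)
    if (length(viol))
      vsError(paste0("validation failed at ", rec@chrom, ":", rec@pos,
                     ": ", paste(viol, collapse = "; ")), "vcf_validation")
  } else {
    viol <- .quickViolations(st$header, rec)
    if (length(viol))
      warning(paste0(rec@chrom, ":", .fmtNum(rec@pos), ": ",
                     paste(viol, collapse = "; ")), call. = FALSE)
  }
  rec <- .projectRecord(rec, st$sampleIdx)
  st$current <- rec
  st$nRead <- st$nRead + 1
  rec
}

## next raw body line honoring pushback / chunk queue; NULL at end
.nextBodyLine <- function(st) {
  if (!is.null(st$pushback)) {
    ln <- st$pushback; st$pushback <- NULL
    return(ln)
  }
  if (!is.null(st$chunks)) {
    repeat {
      if (bgzfTell(st$bg) < st$chunkEnd) {
        ln <- bgzfReadLine(st$bg)
        if (!is.null(ln)) return(ln)
      }
      st$chunkIdx <- st$chunkIdx + 1L
      if (st$chunkIdx > nrow(st$chunks)) return(NULL)
      bgzfSeek(st$bg, st$chunks$beg[st$chunkIdx])
      st$chunkEnd <- st$chunks$end[st$chunkIdx]
    }
  }
  if (!is.null(st$bg)) return(bgzfReadLine(st$bg))
  ln <- readLines(st$con, n = 1L, warn = FALSE)
  if (length(ln) == 0L) return(NULL)
  st$lineNo <- st$lineNo + 1L
  ln
}

#' Read the next record from a reader
#'
#' Yields records one at a time in file order, or \code{NULL} at end of
#' stream.  The reader keeps no backlog: at any moment at most one decoded
#' record is resident (see \code{\link{residentRecords}}).
#'
#' @param x a \linkS4class{VcfReader}.
#' @return a \linkS4class{VcfRecord} or \code{NULL}.
#' @export
setMethod("readRecord", "VcfReader", function(x, ...) {
  st <- x@state
  if (st$format == "bcf") {
    repeat {
      lens <- bgzfRead(st$bg, 8L)
      if (length(lens) == 0L) { st$current <- NULL; return(NULL) }
      if (length(lens) < 8L)
        vsError("truncated BCF record", "bcf_format")
      lShared <- .u32(lens, 0L); lIndiv <- .u32(lens, 4L)
      shared <- bgzfRead(st$bg, lShared)
      indiv <- bgzfRead(st$bg, lIndiv)
      if (length(shared) < lShared || length(indiv) < lIndiv)
        vsError("truncated BCF record", "bcf_format")
      rec <- decodeBcfRecord(shared, indiv, st$header)
      if (!is.null(st$region) && !.recOverlaps(rec, st$region)) next
      return(.surfaceRecord(st, rec))
    }
  }
  repeat {
    ln <- .nextBodyLine(st)
    if (is.null(ln)) { st$current <- NULL; return(NULL) }
    if (!nzchar(ln) || startsWith(ln, "#")) next
    rec <- tryCatch(parseVcfRecord(ln, st$header, st$lineNo),
                    vsError = function(e) {
      vsError(paste0(conditionMessage(e), " [", st$path, "]"),
              class(e)[1])
    })
    if (!is.null(st$region) && !.recOverlaps(rec, st$region)) {
      ## indexed chunks may include flanking records; linear mode scans all
      next
    }
    return(.surfaceRecord(st, rec))
  }
})

#' @describeIn openVcf number of records currently held by the reader
#'   (always 0 or 1: the streaming memory contract).
#' @param x a \linkS4class{VcfReader}.
#' @export
residentRecords <- function(x) {
  if (is.null(x@state$current)) 0L else 1L
}

#' @describeIn VcfReader-class the (sample-projected) header
#' @export
setMethod("vcfHeader", "VcfReader", function(x) x@state$projHeader)

#' @describeIn VcfReader-class surfaced sample names, in requested order
#' @export
setMethod("vcfSamples", "VcfReader", function(x) x@state$projHeader@samples)

setMethod("show", "VcfReader", function(object) {
  st <- object@state
  cat(sprintf("VcfReader [%s] %s: %d sample(s), %s record(s) read\n",
              st$format, st$path, length(st$projHeader@samples),
              format(st$nRead)))
})

#' @export
close.VcfReader <- function(con, ...) {
  st <- con@state
  if (!is.null(st$bg)) close(st$bg)
  if (!is.null(st$con) && !identical(st$path, "-")) close(st$con)
  invisible(NULL)
}

#' Collect all remaining records of a reader
#'
#' Convenience accumulation of \code{\link{readRecord}} (the streaming
#' strategy run to completion).
#'
#' @param x a \linkS4class{VcfReader}.
#' @return list of \linkS4class{VcfRecord}s.
#' @export
readAllRecords <- function(x) {
  out <- list(); n <- 0L
  repeat {
    rec <- readRecord(x)
    if (is.null(rec)) break
    n <- n + 1L
    out[[n]] <- rec
  }
  out
}

## ---------------------------------------------------------------------------
## Writer
## ---------------------------------------------------------------------------

.writerFormatFromPath <- function(path) {
  if (endsWith(path, ".bcf")) "bcf"
  else if (endsWith(path, ".gz") || endsWith(path, ".bgz")) "vcf-bgzf"
  else "vcf-plain"
}

#' Open a VCF/BCF writer
#'
#' The header is written immediately; records follow via
#' \code{\link{writeRecord}}.  \code{close} flushes pending blocks and, for
#' the BGZF-backed modes, appends the end-of-file marker, after which the
#' output re-opens cleanly with \code{\link{openVcf}}.
#'
#' @param path output path; with \code{format = "auto"} the extension picks
#'   the mode (\code{.bcf}, \code{.gz}/\code{.bgz}, else plain text).
#' @param header the \linkS4class{VcfHeader} to write.
#' @param format \code{"auto"}, \code{"vcf-plain"}, \code{"vcf-bgzf"} or
#'   \code{"bcf"}.
#' @param level BGZF compression level (0-9).
#' @return a \linkS4class{VcfWriter}.
#' @export
openVcfWriter <- function(path, header,
                          format = c("auto", "vcf-plain", "vcf-bgzf",
                                     "bcf"),
                          level = 6L) {
  format <- match.arg(format)
  if (format == "auto") format <- .writerFormatFromPath(path)
  st <- new.env(parent = emptyenv())
  st$path <- path
  st$format <- format
  st$header <- header
  st$closed <- FALSE
  st$nWritten <- 0
  if (format == "bcf") {
    st$bw <- bgzfCreate(path, level)
    writeBcfHeader(st$bw, header)
  } else if (format == "vcf-bgzf") {
    st$bw <- bgzfCreate(path, level)
    bgzfWrite(st$bw, paste0(paste(formatVcfHeader(header),
                                  collapse = "\n"), "\n"))
  } else {
    st$con <- if (identical(path, "-")) stdout() else file(path, "w")
    writeLines(formatVcfHeader(header), st$con)
  }
  new("VcfWriter", state = st)
}

#' Write one record
#'
#' @param x a \linkS4class{VcfWriter}.
#' @param record a \linkS4class{VcfRecord}; its sample count must match the
#'   writer's header.
#' @export
setMethod("writeRecord", "VcfWriter", function(x, record, ...) {
  st <- x@state
  if (st$closed) vsError("write after close", "io_usage")
  if (record@nSamples != length(st$header@samples))
    vsError(sprintf("record carries %d sample(s), header declares %d",
                    record@nSamples, length(st$header@samples)),
            "io_sample_mismatch")
  if (st$format == "bcf") {
    bgzfWrite(st$bw, encodeBcfRecord(record, st$header))
  } else if (st$format == "vcf-bgzf") {
    bgzfWrite(st$bw, paste0(formatVcfRecord(record, st$header), "\n"))
  } else {
    writeLines(formatVcfRecord(record, st$header), st$con)
  }
  st$nWritten <- st$nWritten + 1
  invisible(x)
})

#' @describeIn VcfWriter-class the header being written
#' @export
setMethod("vcfHeader", "VcfWriter", function(x) x@state$header)

setMethod("show", "VcfWriter", function(object) {
  st <- object@state
  cat(sprintf("VcfWriter [%s] %s: %s record(s) written%s\n", st$format,
              st$path, format(st$nWritten),
              if (st$closed) " (closed)" else ""))
})

#' @export
close.VcfWriter <- function(con, ...) {
  st <- con@state
  if (st$closed) return(invisible(NULL))
  if (!is.null(st$bw)) bgzfClose(st$bw)
  if (!is.null(st$con) && !identical(st$path, "-")) close(st$con)
  st$closed <- TRUE
  invisible(NULL)
}

## ---------------------------------------------------------------------------
## Conversion
## ---------------------------------------------------------------------------

#' Convert between VCF/BCF encodings
#'
#' Streams records from \code{src} to \code{dest}, preserving the header
#' and every record across any pairing of the three encodings (many C++
#' tools consume only one of them, so closing this gap is the whole point
#' of a conversion pass).  Optional region/sample constraints apply before
#' writing, in which case the written header carries the projected sample
#' list.
#'
#' @param src input path (any supported encoding).
#' @param dest output path.
#' @param format output encoding, as in \code{\link{openVcfWriter}}.
#' @param region,samples optional constraints, as in \code{\link{openVcf}}.
#' @param level BGZF compression level.
#' @return invisibly, the number of records written.
#' @export
convertVcf <- function(src, dest, format = "auto", region = NULL,
                       samples = NULL, level = 6L) {
  r <- openVcf(src, region = region, samples = samples)
  on.exit(close(r), add = TRUE)
  w <- openVcfWriter(dest, vcfHeader(r), format = format, level = level)
  n <- 0
  repeat {
    rec <- readRecord(r)
    if (is.null(rec)) break
    writeRecord(w, rec)
    n <- n + 1
  }
  close(w)
  invisible(n)
}
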