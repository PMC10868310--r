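# BGZF: blocked gzip.  A BGZF stream is a series of complete gzip members,
# each at most 64 KiB, each carrying a "BC" extra subfield holding the
# member's total size minus one (BSIZE).  Because every member is a valid
# gzip member, any multi-member gzip reader can decompress the stream
# linearly; the per-block size field is what makes random access possible.
#
# A position inside the uncompressed logical stream is a *virtual offset*:
# (compressed offset of the containing block) * 2^16 + (offset within the
# block's decompressed payload).

## conservative bound used by bgzip itself: payload up to 65280 bytes keeps
## BSIZE within 16 bits even for incompressible data
.BGZF_MAX_PAYLOAD <- 65280L

## canonical 28-byte end-of-file marker: an empty member at level "stored"
.BGZF_EOF <- as.raw(c(
  0x1f, 0x8b, 0x08, 0x04, 0x00, 0x00, 0x00, 0x00, 0x00, 0xff, 0x06, 0x00,
  0x42, 0x43, 0x02, 0x00, 0x1b, 0x00, 0x03, 0x00, 0x00, 0x00, 0x00, 0x00,
  0x00, 0x00, 0x00, 0x00))

#' Pack / unpack virtual offsets
#'
#' A virtual offset packs a BGZF block's byte offset in the compressed file
#' (\code{coffset}) with a byte offset into that block's decompressed
#' payload (\code{uoffset}, < 2^16) as \code{coffset * 2^16 + uoffset}.
#' Packed offsets order lexicographically in \code{(coffset, uoffset)},
#' so positions later in a linear read always compare greater.  Offsets
#' are held as doubles, exact for any file below 2^37 bytes.
#'
#' @param coffset,uoffset non-negative numerics (uoffset < 65536);
#'   vectorized.
#' @param v packed virtual offset(s).
#' @return \code{packVirtualOffset} returns the packed numeric;
#'   \code{unpackVirtualOffset} a list with \code{coffset} and
#'   \code{uoffset}.
#' @examples
#' packVirtualOffset(1, 0)   # 65536
#' unpackVirtualOffset(65537)
#' @export
packVirtualOffset <- function(coffset, uoffset) {
  stopifnot(all(coffset >= 0), all(uoffset >= 0), all(uoffset < 65536))
  coffset * 65536 + uoffset
}

#' @rdname packVirtualOffset
#' @export
unpackVirtualOffset <- function(v) {
  list(coffset = v %/% 65536, uoffset = v %% 65536)
}

#' Compress one BGZF block
#'
#' Wraps \code{payload} into a single complete gzip member carrying the
#' BGZF \code{"BC"} extra subfield.  Concatenations of such members form a
#' stream readable by any multi-member gzip decompressor.
#'
#' @param payload raw vector, at most 65280 bytes.
#' @param level deflate level 0-9; 0 emits stored (uncompressed) deflate
#'   blocks.
#' @return raw vector: the complete gzip member.
#' @seealso [bgzfDecompressBlock()], [bgzfWriteEof()]
#' @export
bgzfCompressBlock <- function(payload, level = 6L) {
  if (!is.raw(payload)) payload <- as.raw(payload)
  if (length(payload) > .BGZF_MAX_PAYLOAD)
    vsError(sprintf("BGZF payload too long (%d > %d bytes)",
                    length(payload), .BGZF_MAX_PAYLOAD), "bgzf_size")
  cdata <- .deflate_raw(payload, as.integer(level))
  bsize <- 12L + 6L + length(cdata) + 8L   # header + extra + cdata + trailer
  if (bsize > 65536L)
    vsError("compressed block exceeds 65536 bytes", "bgzf_size")
  c(as.raw(c(0x1f, 0x8b, 0x08, 0x04,       # magic, CM=deflate, FLG=FEXTRA
             0x00, 0x00, 0x00, 0x00,       # mtime
             0x00, 0xff,                   # XFL, OS=unknown
             0x06, 0x00,                   # XLEN = 6
             0x42, 0x43, 0x02, 0x00)),     # 'B' 'C', SLEN=2
    .putU16(bsize - 1L),
    cdata,
    .putU32(.crc32_raw(payload)),
    .putU32(length(payload)))
}

## Parse the gzip member header starting at 0-based `off`; returns
## list(bsize, dataStart) or raises.  `bsize` is the total member length.
.bgzfParseHeader <- function(x, off) {
  n <- length(x) - off
  if (n < 18L || x[off + 1L] != as.raw(0x1f) || x[off + 2L] != as.raw(0x8b))
    vsError("not a BGZF stream: gzip magic bytes absent", "bgzf_magic")
  flg <- .u8(x, off + 3L)
  if (bitwAnd(flg, 4L) == 0L)
    vsError("plain gzip member: no FEXTRA field, not BGZF", "bgzf_plain_gzip")
  xlen <- .u16(x, off + 10L)
  p <- off + 12L
  end <- p + xlen
  bsize <- NA_integer_
  while (p + 4L <= end) {
    si1 <- .u8(x, p); si2 <- .u8(x, p + 1L); slen <- .u16(x, p + 2L)
    if (si1 == 66L && si2 == 67L && slen == 2L) {   # 'B','C'
      bsize <- .u16(x, p + 4L) + 1L
      break
    }
    p <- p + 4L + slen
  }
  if (is.na(bsize))
    vsError("gzip member lacks the BGZF 'BC' subfield", "bgzf_plain_gzip")
  list(bsize = bsize, dataStart = off + 12L + xlen)
}

#' Decompress one BGZF block
#'
#' Decodes the gzip member starting at byte offset \code{offset} of
#' \code{x}, validates its CRC32, and reports how many compressed bytes the
#' member occupied (always BSIZE + 1).
#'
#' @param x raw vector containing (at least) one complete BGZF member.
#' @param offset 0-based byte offset of the member's first byte.
#' @return list with \code{payload} (raw) and \code{consumed} (integer).
#' @export
bgzfDecompressBlock <- function(x, offset = 0) {
  h <- .bgzfParseHeader(x, offset)
  if (offset + h$bsize > length(x))
    vsError("truncated BGZF block", "bgzf_truncated")
  isize <- .u32(x, offset + h$bsize - 4L)
  crc   <- .u32(x, offset + h$bsize - 8L)
  clen  <- h$bsize - (h$dataStart - offset) - 8L
  cdata <- if (clen > 0) x[(h$dataStart + 1L):(h$dataStart + clen)] else raw()
  payload <- .inflate_raw(cdata, as.integer(isize))
  if (.crc32_raw(payload) != crc)
    vsError("BGZF block CRC mismatch: stream is corrupt", "bgzf_corrupt")
  list(payload = payload, consumed = h$bsize)
}

#' Recognize a BGZF stream from its leading bytes
#'
#' True iff the bytes begin with a gzip member that carries the BGZF
#' \code{"BC"} extra subfield.  Plain text and non-blocked gzip both
#' return FALSE.
#'
#' @param bytes raw vector, at least the first 18 bytes of the stream.
#' @return logical(1).
#' @export
isBgzf <- function(bytes) {
  ok <- tryCatch({ .bgzfParseHeader(bytes, 0L); TRUE },
                 vsError = function(e) FALSE)
  ok
}

#' @rdname bgzfWriterTools
#' @export
bgzfEofMarker <- function() .BGZF_EOF

## ---------------------------------------------------------------------------
## Streaming reader over a file connection.  Exactly one decompressed block
## is cached at a time (the streaming memory contract); newline positions in
## the cached payload are pre-computed once per block so line reads are not
## quadratic.
## ---------------------------------------------------------------------------

#' Open a BGZF file for streaming reads
#'
#' The reader caches a single decompressed block.  \code{bgzfTell} reports
#' the current virtual offset; \code{bgzfSeek} repositions to a virtual
#' offset previously obtained from \code{bgzfTell} (or from an index).
#' After \code{bgzfSeek(r, bgzfTell(r))} subsequent reads reproduce the
#' same byte sequence as an uninterrupted linear read.
#'
#' @param path file path of a BGZF stream.
#' @return an object of class \code{"BgzfReader"}.
#' @seealso [bgzfReadLine()], [bgzfRead()], [bgzfTell()], [bgzfSeek()]
#' @export
bgzfOpen <- function(path) {
  st <- new.env(parent = emptyenv())
  st$con <- file(path, "rb")
  st$path <- path
  st$coffset <- 0        # coffset of cached block (block not yet loaded)
  st$nextOff <- 0        # coffset of the block after the cached one
  st$payload <- raw()
  st$upos <- 0L          # consumed bytes of cached payload
  st$nl <- integer()     # newline positions within cached payload
  st$eof <- FALSE
  st$loaded <- FALSE
  structure(st, class = "BgzfReader")
}

#' @export
close.BgzfReader <- function(con, ...) {
  if (!is.null(con$con)) close(con$con)
  invisible(NULL)
}

## load the next non-empty block; returns FALSE at physical EOF
.bgzfFill <- function(r) {
  repeat {
    if (r$eof) return(FALSE)
    hdr <- readBin(r$con, "raw", 18L)
    if (length(hdr) == 0L) { r$eof <- TRUE; return(FALSE) }
    if (length(hdr) < 18L)
      vsError("truncated BGZF block header", "bgzf_truncated")
    h <- tryCatch(.bgzfParseHeader(hdr, 0L), vsError = function(e) {
      ## re-raise with seek context: landing mid-block looks like garbage
      vsError(paste0("corrupt BGZF stream at offset ", r$nextOff, ": ",
                     conditionMessage(e)), class(e)[1])
    })
    rest <- readBin(r$con, "raw", h$bsize - 18L)
    if (length(rest) < h$bsize - 18L)
      vsError("truncated BGZF block", "bgzf_truncated")
    blk <- bgzfDecompressBlock(c(hdr, rest), 0L)
    r$coffset <- r$nextOff
    r$nextOff <- r$nextOff + h$bsize
    r$loaded <- TRUE
    if (length(blk$payload) == 0L) next      # EOF marker or empty block
    r$payload <- blk$payload
    r$upos <- 0L
    r$nl <- which(blk$payload == as.raw(10L))
    return(TRUE)
  }
}

.bgzfAvail <- function(r) length(r$payload) - r$upos

#' @rdname bgzfOpen
#' @param r a \code{BgzfReader}.
#' @return \code{bgzfTell} returns the packed virtual offset of the next
#'   byte to be read.
#' @export
bgzfTell <- function(r) {
  if (.bgzfAvail(r) > 0L) packVirtualOffset(r$coffset, r$upos)
  else packVirtualOffset(r$nextOff, 0L)   # normalized to next block start
}

#' @rdname bgzfOpen
#' @param v packed virtual offset to seek to.
#' @export
bgzfSeek <- function(r, v) {
  u <- unpackVirtualOffset(v)
  if (!r$loaded || u$coffset != r$coffset || u$uoffset < 0) {
    seek(r$con, u$coffset, origin = "start", rw = "read")
    r$nextOff <- u$coffset
    r$payload <- raw(); r$upos <- 0L; r$nl <- integer()
    r$eof <- FALSE; r$loaded <- FALSE
    if (u$uoffset > 0L) {
      if (!.bgzfFill(r))
        vsError("seek beyond end of BGZF stream", "bgzf_corrupt")
      if (u$uoffset > length(r$payload))
        vsError("virtual offset points outside its block", "bgzf_corrupt")
      r$upos <- as.integer(u$uoffset)
    }
  } else {
    if (u$uoffset > length(r$payload))
      vsError("virtual offset points outside its block", "bgzf_corrupt")
    r$upos <- as.integer(u$uoffset)
  }
  invisible(r)
}

#' Read raw bytes / one text line from a BGZF reader
#'
#' \code{bgzfRead} returns up to \code{n} bytes (fewer only at end of
#' stream).  \code{bgzfReadLine} returns the next newline-terminated line
#' (without the newline, tolerating CRLF) or \code{NULL} at end of stream;
#' lines may span block boundaries.
#'
#' @param r a \code{BgzfReader}.
#' @param n number of bytes requested.
#' @return raw vector / character(1) or NULL.
#' @export
bgzfRead <- function(r, n) {
  out <- vector("list", 4L); k <- 0L; got <- 0
  while (got < n) {
    if (.bgzfAvail(r) == 0L && !.bgzfFill(r)) break
    take <- min(n - got, .bgzfAvail(r))
    k <- k + 1L
    out[[k]] <- r$payload[(r$upos + 1L):(r$upos + take)]
    r$upos <- r$upos + as.integer(take)
    got <- got + take
  }
  if (k == 0L) raw() else do.call(c, out[seq_len(k)])
}

#' @rdname bgzfRead
#' @export
bgzfReadLine <- function(r) {
  pieces <- NULL
  repeat {
    if (.bgzfAvail(r) == 0L && !.bgzfFill(r)) {
      if (is.null(pieces)) return(NULL)
      return(rawToChar(pieces))
    }
    nxt <- r$nl[r$nl > r$upos]
    if (length(nxt)) {
      nxt <- nxt[1L]
      seg <- if (nxt - 1L >= r$upos + 1L)
        r$payload[(r$upos + 1L):(nxt - 1L)] else raw()
      r$upos <- nxt
      line <- if (is.null(pieces)) seg else c(pieces, seg)
      if (length(line) && line[length(line)] == as.raw(13L))
        line <- line[-length(line)]
      return(rawToChar(line))
    }
    seg <- r$payload[(r$upos + 1L):length(r$payload)]
    pieces <- if (is.null(pieces)) seg else c(pieces, seg)
    r$upos <- length(r$payload)
  }
}

## ---------------------------------------------------------------------------
## Streaming writer
## ---------------------------------------------------------------------------

#' Open a BGZF file for streaming writes
#'
#' Bytes are buffered and emitted as BGZF members of at most 65280 payload
#' bytes.  \code{bgzfClose} flushes the buffer and appends the canonical
#' 28-byte end-of-file marker exactly once.
#'
#' @param path output file path.
#' @param level deflate level 0-9 (0 = stored blocks).
#' @return an object of class \code{"BgzfWriter"}.
#' @name bgzfWriterTools
#' @export
bgzfCreate <- function(path, level = 6L) {
  st <- new.env(parent = emptyenv())
  st$con <- file(path, "wb")
  st$level <- as.integer(level)
  st$pending <- list()
  st$npending <- 0
  st$closed <- FALSE
  structure(st, class = "BgzfWriter")
}

#' @rdname bgzfWriterTools
#' @param w a \code{BgzfWriter}.
#' @param bytes raw vector or character (characters are written as their
#'   UTF-8 bytes).
#' @export
bgzfWrite <- function(w, bytes) {
  if (w$closed) vsError("write after close", "bgzf_usage")
  if (is.character(bytes)) bytes <- charToRaw(paste0(bytes, collapse = ""))
  w$pending[[length(w$pending) + 1L]] <- bytes
  w$npending <- w$npending + length(bytes)
  if (w$npending >= .BGZF_MAX_PAYLOAD) .bgzfDrain(w, FALSE)
  invisible(w)
}

.bgzfDrain <- function(w, all) {
  buf <- do.call(c, w$pending)
  off <- 0L
  while (length(buf) - off >= .BGZF_MAX_PAYLOAD) {
    writeBin(bgzfCompressBlock(buf[(off + 1L):(off + .BGZF_MAX_PAYLOAD)],
                               w$level), w$con)
    off <- off + .BGZF_MAX_PAYLOAD
  }
  rest <- if (off < length(buf)) buf[(off + 1L):length(buf)] else raw()
  if (all && length(rest)) {
    writeBin(bgzfCompressBlock(rest, w$level), w$con)
    rest <- raw()
  }
  w$pending <- if (length(rest)) list(rest) else list()
  w$npending <- length(rest)
  invisible(w)
}

#' @rdname bgzfWriterTools
#' @export
bgzfClose <- function(w) {
  if (w$closed) return(invisible(w))
  .bgzfDrain(w, TRUE)
  writeBin(.BGZF_EOF, w$con)
  close(w$con)
  w$closed <- TRUE
  invisible(w)
}

#' @export
close.BgzfWriter <- function(con, ...) bgzfClose(con)

## an uncompressed stream presented through the BgzfReader interface
## (sequential only; tell/seek degenerate to plain byte offsets)
.rawStreamReader <- function(path) {
  st <- new.env(parent = emptyenv())
  st$con <- NULL
  st$path <- path
  st$payload <- readBin(path, "raw", file.size(path))
  st$coffset <- 0; st$nextOff <- 0
  st$upos <- 0L
  st$nl <- which(st$payload == as.raw(10L))
  st$eof <- TRUE       # whole stream already resident; no more blocks
  st$loaded <- TRUE
  structure(st, class = "BgzfReader")
}

## convenience: decompress an entire BGZF file into one raw vector
.bgzfSlurp <- function(path) {
  x <- readBin(path, "raw", file.size(path))
  out <- list(); off <- 0; k <- 0L
  while (off < length(x)) {
    blk <- bgzfDecompressBlock(x, off)
    k <- k + 1L
    out[[k]] <- blk$payload
    off <- off + blk$consumed
  }
  if (k == 0L) raw() else do.call(c, out)
}

## compress a whole raw/character payload to path (used by writers/tests)
.bgzfDump <- function(bytes, path, level = 6L) {
  if (is.character(bytes)) bytes <- charToRaw(paste0(bytes, collapse = ""))
  w <- bgzfCreate(path, level)
  bgzfWrite(w, bytes)
  bgzfClose(w)
  invisible(path)
}
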