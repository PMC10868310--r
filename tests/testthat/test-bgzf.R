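# BGZF block codec and virtual-offset streaming.

test_that("block round trip is the identity for assorted payloads", {
  set.seed(101)
  sizes <- c(0, 1, 2, 37, 1000, 65279, 65280)
  for (lvl in c(0L, 1L, 6L, 9L)) for (n in sizes) {
    payload <- as.raw(sample(0:255, n, replace = TRUE))
    m <- bgzfCompressBlock(payload, lvl)
    expect_lte(length(m), 65536)
    got <- bgzfDecompressBlock(m)
    expect_identical(got$payload, payload)
    expect_identical(got$consumed, length(m))
  }
})

test_that("empty payload at default settings is the canonical EOF marker", {
  ## frozen after byte-comparison against the marker a reference bgzip
  ## emits for empty input
  expect_identical(bgzfCompressBlock(raw(0)), bgzfEofMarker())
  expect_length(bgzfEofMarker(), 28L)
  got <- bgzfDecompressBlock(bgzfEofMarker())
  expect_identical(got$payload, raw(0))
  expect_identical(got$consumed, 28L)
})

test_that("oversized payloads and corrupted blocks are rejected", {
  expect_error(bgzfCompressBlock(raw(65281)), class = "bgzf_size")
  m <- bgzfCompressBlock(charToRaw("ACGT"))
  bad <- m
  crcAt <- length(m) - 7L   # first CRC byte
  bad[crcAt] <- xor(bad[crcAt], as.raw(0xff))
  expect_error(bgzfDecompressBlock(bad), class = "bgzf_corrupt")
  expect_error(bgzfDecompressBlock(charToRaw("not gzip at all......")),
               class = "bgzf_magic")
  plain <- memCompress(charToRaw("x"), "gzip")
  ## memCompress yields a zlib stream, not gzip; craft a plain gzip member
  ## via a connection instead
  tf <- tempfile()
  con <- gzfile(tf, "wb"); writeBin(charToRaw("hello"), con); close(con)
  expect_error(bgzfDecompressBlock(readBin(tf, "raw", 64)),
               class = "bgzf_plain_gzip")
})

test_that("emitted streams are plain multi-member gzip to other readers", {
  set.seed(102)
  parts <- lapply(1:5, function(i)
    as.raw(sample(0:255, sample(2000, 1), TRUE)))
  tf <- tempfile()
  w <- bgzfCreate(tf)
  for (p in parts) bgzfWrite(w, p)
  bgzfClose(w)
  ## independent multi-member gzip reader
  con <- gzfile(tf, "rb")
  got <- readBin(con, "raw", sum(lengths(parts)) + 10)
  close(con)
  expect_identical(got, do.call(c, parts))
  ## and the stream ends with the bit-exact EOF marker
  bytes <- readBin(tf, "raw", file.size(tf))
  expect_identical(bytes[(length(bytes) - 27L):length(bytes)],
                   bgzfEofMarker())
})

test_that("isBgzf distinguishes BGZF from text and plain gzip", {
  m <- bgzfCompressBlock(charToRaw("##fileformat=VCFv4.2\n"))
  expect_true(isBgzf(m))
  expect_false(isBgzf(charToRaw("##fileformat=VCFv4.2 plain text here")))
  tf <- tempfile()
  con <- gzfile(tf, "wb"); writeBin(charToRaw("hello world"), con)
  close(con)
  expect_false(isBgzf(readBin(tf, "raw", 32)))
})

test_that("virtual offsets pack lexicographically and invert", {
  expect_identical(packVirtualOffset(0, 0), 0)
  expect_identical(packVirtualOffset(1, 0), 65536)
  set.seed(103)
  co <- sort(sample(0:1e6, 50)); uo <- sample(0:65535, 50, TRUE)
  v <- packVirtualOffset(co, uo)
  u <- unpackVirtualOffset(v)
  expect_equal(u$coffset, co)
  expect_equal(u$uoffset, uo)
  ## lexicographic ordering in (coffset, uoffset)
  o <- order(co, uo)
  expect_identical(order(v), o)
})

test_that("seek(tell()) reproduces the linear read from that point", {
  set.seed(104)
  ## many small writes so lines cross block boundaries
  lines <- replicate(4000, paste(sample(letters, sample(5:60, 1),
                                        TRUE), collapse = ""))
  tf <- tempfile()
  w <- bgzfCreate(tf, level = 1L)
  bgzfWrite(w, paste0(paste(lines, collapse = "\n"), "\n"))
  bgzfClose(w)
  r <- bgzfOpen(tf)
  tells <- numeric(length(lines))
  got <- character(length(lines))
  for (i in seq_along(lines)) {
    tells[i] <- bgzfTell(r)
    got[i] <- bgzfReadLine(r)
  }
  expect_identical(got, lines)
  ## offsets are monotonically non-decreasing across a linear read
  expect_false(is.unsorted(tells))
  ## seek back to 100 random remembered positions
  for (i in sample(seq_along(lines), 100)) {
    bgzfSeek(r, tells[i])
    expect_identical(bgzfReadLine(r), lines[i])
  }
  close(r)
})

test_that("write after close is a usage error", {
  tf <- tempfile()
  w <- bgzfCreate(tf)
  bgzfWrite(w, "x")
  bgzfClose(w)
  expect_error(bgzfWrite(w, "y"), class = "bgzf_usage")
})
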