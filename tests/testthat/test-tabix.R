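# Binning arithmetic, index build, region queries, and .tbi serialization.

test_that("reg2bin matches the brute-force enumerator", {
  ## frozen examples, each recomputed by the enumerator
  expect_identical(bruteBin(0, 2^29), 0L)
  expect_identical(bruteBin(0, 1), 4681L)
  expect_identical(bruteBin(16384, 16385), 4682L)
  expect_identical(reg2bin(0, 2^29), 0L)
  expect_identical(reg2bin(0, 1), 4681L)
  expect_identical(reg2bin(16384, 16385), 4682L)
  set.seed(201)
  for (i in 1:300) {
    b <- sample(0:(2^29 - 1), 1)
    e <- min(b + sample.int(2^26, 1), 2^29)
    expect_identical(reg2bin(b, e), bruteBin(b, e))
  }
})

test_that("reg2bins matches the enumerated overlap set and contains reg2bin", {
  expect_identical(reg2bins(0, 1), c(0L, 1L, 9L, 73L, 585L, 4681L))
  expect_length(reg2bins(0, 2^29), 37449L)
  set.seed(202)
  for (i in 1:200) {
    b <- sample(0:(2^29 - 1), 1)
    e <- min(b + sample.int(2^27, 1), 2^29)
    bins <- reg2bins(b, e)
    expect_identical(bins, bruteBins(b, e))
    expect_true(reg2bin(b, e) %in% bins)
    expect_false(is.unsorted(bins))
  }
  expect_error(reg2bins(-1, 5), class = "tbx_range")
  expect_error(reg2bin(10, 10), class = "tbx_range")
  expect_error(reg2bin(0, 2^29 + 1), class = "tbx_range")
})

test_that("region strings parse per the samtools convention", {
  r <- parseRegion("chr21")
  expect_identical(r@contig, "chr21")
  expect_identical(r@start, 1)
  expect_identical(r@end, Inf)
  r <- parseRegion("chr21:5,010,000-5,020,000")
  expect_identical(r@start, 5010000)
  expect_identical(r@end, 5020000)
  r <- parseRegion("chr21:42")
  expect_identical(r@start, 42)
  expect_error(parseRegion("chr21:9-5"), class = "region_parse")
  expect_error(parseRegion("chr21:0-5"), class = "region_parse")
})

fx <- simulateVcf(seed = 21, nSamples = 3, nVariants = 3000,
                  contigs = c(chr21 = 3e6, chr22 = 4e6))
fp <- fixtureFiles(fx)
scan <- textFieldScan(fx$lines)

test_that("self-query succeeds for every indexed record", {
  idx <- fp$index
  expect_identical(idx@contigs, c("chr21", "chr22"))
  ## querying each record's own position returns a chunk covering it
  set.seed(203)
  take <- sample(length(scan$pos), 300)
  for (i in take) {
    ch <- queryChunks(idx, sprintf("%s:%d-%d", scan$chrom[i], scan$pos[i],
                                   scan$pos[i]))
    expect_gt(nrow(ch), 0)
  }
})

test_that("indexed queries equal a linear scan with the overlap predicate", {
  set.seed(204)
  for (k in 1:80) {
    ctg <- sample(c("chr21", "chr22", "chrMissing"), 1)
    b <- sample.int(4e6, 1)
    e <- b + sample.int(300000, 1)
    rr <- openVcf(fp$gz, region = sprintf("%s:%d-%d", ctg, b, e),
                  index = fp$index)
    recs <- readAllRecords(rr)
    close(rr)
    expect_identical(recKeys(recs),
                     scanKeys(fx$lines, regionOracle(scan, ctg, b, e)))
  }
})

test_that("whole-contig query returns exactly that contig's records", {
  rr <- openVcf(fp$gz, region = "chr22", index = fp$index)
  recs <- readAllRecords(rr)
  close(rr)
  expect_length(recs, sum(scan$chrom == "chr22"))
  expect_true(all(vapply(recs, chrom, "") == "chr22"))
})

test_that("symbolic-allele span (INFO END) participates in overlap", {
  svAt <- which(fx$truth$categories == "SV")[1]
  p <- fx$truth$pos[svAt]; ctg <- fx$truth$chrom[svAt]
  endv <- fx$truth$infoEnd[svAt]
  stopifnot(endv - p > 10)
  mid <- floor((p + endv) / 2)   # inside the deletion, past POS
  rr <- openVcf(fp$gz, region = sprintf("%s:%d-%d", ctg, mid, mid),
                index = fp$index)
  recs <- readAllRecords(rr)
  close(rr)
  expect_true(any(vapply(recs, pos, 0) == p))
})

test_that(".tbi round trip is structurally lossless", {
  idx2 <- readTabix(fp$tbi)
  expect_identical(idx2@contigs, fp$index@contigs)
  expect_equal(idx2@chunks, fp$index@chunks)
  expect_equal(idx2@linear, fp$index@linear)
  expect_identical(idx2@meta[c("format", "col_seq", "col_beg", "col_end")],
                   list(format = 2, col_seq = 1, col_beg = 2, col_end = 0))
  ## truncation and bad magic
  raw <- readBin(fp$tbi, "raw", 40)
  tf <- tempfile(); writeBin(raw, tf)
  expect_error(readTabix(tf), class = "tbi_format")
  tf2 <- tempfile(); writeBin(charToRaw("BAI\1garbage"), tf2)
  expect_error(readTabix(tf2), class = "tbi_format")
})

test_that("an index from the reference tabix yields identical queries", {
  tbx <- Sys.which("tabix")
  expect_true(nzchar(tbx))
  file.remove(fp$tbi)
  system2(tbx, c("-p", "vcf", fp$gz))
  theirs <- readTabix(fp$tbi)
  set.seed(205)
  for (k in 1:60) {
    ctg <- sample(c("chr21", "chr22"), 1)
    b <- sample.int(4e6, 1)
    e <- b + sample.int(400000, 1)
    rr <- openVcf(fp$gz, region = sprintf("%s:%d-%d", ctg, b, e),
                  index = theirs)
    recs <- readAllRecords(rr)
    close(rr)
    expect_identical(recKeys(recs),
                     scanKeys(fx$lines, regionOracle(scan, ctg, b, e)))
  }
  ## restore the package-built sidecar for later tests
  writeTabix(fp$index, fp$tbi)
})

test_that("unsorted input is refused with the offending record named", {
  hdr <- fx$lines[startsWith(fx$lines, "#")]
  body <- fx$lines[!startsWith(fx$lines, "#")]
  bad <- c(hdr, body[2], body[1])   # decreasing pos on one contig
  tf <- tempfile(fileext = ".vcf.gz")
  w <- bgzfCreate(tf); bgzfWrite(w, paste0(paste(bad, collapse = "\n"),
                                           "\n")); bgzfClose(w)
  expect_error(buildTabixIndex(tf), class = "tbx_sort")
  ## header-only file indexes to zero contigs
  tf2 <- tempfile(fileext = ".vcf.gz")
  w <- bgzfCreate(tf2); bgzfWrite(w, paste0(paste(hdr, collapse = "\n"),
                                            "\n")); bgzfClose(w)
  idx <- buildTabixIndex(tf2)
  expect_length(idx@contigs, 0L)
})

test_that("linear index offsets are non-decreasing", {
  for (lin in fp$index@linear)
    expect_false(is.unsorted(lin))
})
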