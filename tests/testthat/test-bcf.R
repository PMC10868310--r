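# BCF2.2 codec: typed values, header block, record blocks, GT packing,
# and agreement with the reference implementation (bcftools, test oracle).

test_that("typed values round-trip including sentinels", {
  ## [0x11, 0x05] is a single int8 with value 5
  d <- decodeTyped(as.raw(c(0x11, 0x05)))
  expect_identical(d$values, 5L)
  expect_identical(d$code, 1L)
  expect_identical(d$consumed, 2L)
  ## width selection: 300 needs int16
  b <- encodeTyped(300L)
  expect_identical(as.integer(b[1]) %% 16L, 2L)
  expect_identical(decodeTyped(b)$values, 300L)
  ## escape descriptor for counts >= 15
  v <- 1:40
  b <- encodeTyped(v)
  expect_identical(decodeTyped(b)$values, v)
  set.seed(401)
  for (i in 1:50) {
    n <- sample(0:30, 1)
    v <- sample(c(NA_integer_, -120L:127L, 3000L, -70000L, 1234567L),
                n, replace = TRUE)
    b <- encodeTyped(v)
    d <- decodeTyped(b)
    expect_identical(d$values, v)
    ## re-encoding decoded values never grows the atom width
    expect_identical(as.integer(encodeTyped(d$values)[1]) %% 16L,
                     as.integer(b[1]) %% 16L)
  }
  ## floats with missing
  v <- c(1.5, NA, -2.25)
  d <- decodeTyped(encodeTyped(v, type = "Float"))
  expect_identical(d$code, 5L)
  expect_equal(d$values, v)
  ## char
  d <- decodeTyped(encodeTyped("AC,GT"))
  expect_identical(d$values, "AC,GT")
  ## reserved type code / truncation
  expect_error(decodeTyped(as.raw(c(0x14, 0x00))), class = "bcf_format")
  expect_error(decodeTyped(as.raw(0x21)), class = "bcf_format")
})

test_that("BCF header block round-trips and rejects wrong magic", {
  fx <- simulateVcf(seed = 41, nSamples = 3, nVariants = 5)
  tf <- tempfile(fileext = ".bcf")
  w <- bgzfCreate(tf)
  writeBcfHeader(w, fx$header)
  bgzfClose(w)
  r <- bgzfOpen(tf)
  h2 <- readBcfHeader(r)
  close(r)
  expect_identical(h2@samples, fx$header@samples)
  expect_identical(h2@infos$id, fx$header@infos$id)
  expect_identical(h2@infos$idx, fx$header@infos$idx)
  expect_identical(h2@contigs$id, fx$header@contigs$id)
  ## wrong magic names the found bytes
  tf2 <- tempfile()
  w <- bgzfCreate(tf2); bgzfWrite(w, charToRaw("BAM\1xxxx")); bgzfClose(w)
  r <- bgzfOpen(tf2)
  expect_error(readBcfHeader(r), class = "bcf_format")
  close(r)
})

test_that("GT integer packing matches the reference layout", {
  hdr <- parseVcfHeader(c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"ok\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##contig=<ID=chr21,length=46709983>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "A", "B", "C"), collapse = "\t")))
  rec <- parseVcfRecord("chr21\t10\t.\tA\tG\t50\tPASS\t.\tGT\t0|1\t1\t./.",
                        hdr)
  blk <- encodeBcfRecord(rec, hdr)
  lShared <- VariantStream:::.u32(blk, 0)
  lIndiv <- VariantStream:::.u32(blk, 4)
  indiv <- blk[(8 + lShared + 1):(8 + lShared + lIndiv)]
  ## key (typed int scalar), then descriptor (count 2, int8), then values:
  ## diploid "0|1" -> [2, 5]; haploid "1" -> [4, end-of-vector];
  ## "./." -> [0, 0]
  expect_identical(indiv[3], as.raw(0x21))
  expect_identical(as.integer(indiv[4:9]),
                   c(2L, 5L, 4L, 0x81L, 0L, 0L))
  ## decode reproduces the genotype strings, padding stripped
  rec2 <- decodeBcfRecord(blk[9:(8 + lShared)],
                          indiv, hdr)
  expect_identical(unlist(rec2@sampleData$GT), c("0|1", "1", "./."))
})

test_that("record encode/decode preserves every field on the edge suite", {
  suite <- adversarialSuite()
  for (nm in setdiff(names(suite), "undeclared_tag")) {
    lines <- suite[[nm]]
    hdr <- parseVcfHeader(lines[startsWith(lines, "#")])
    for (ln in lines[!startsWith(lines, "#")]) {
      rec <- parseVcfRecord(ln, hdr)
      blk <- encodeBcfRecord(rec, hdr)
      lS <- VariantStream:::.u32(blk, 0)
      lI <- VariantStream:::.u32(blk, 4)
      rec2 <- decodeBcfRecord(blk[9:(8 + lS)],
                              if (lI) blk[(8 + lS + 1):(8 + lS + lI)]
                              else raw(), hdr)
      expect_identical(formatVcfRecord(rec2, hdr),
                       formatVcfRecord(rec, hdr), info = nm)
    }
  }
})

test_that("undeclared ids are dictionary errors at encode time", {
  hdr <- parseVcfHeader(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##contig=<ID=chr21>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t")))
  rec <- parseVcfRecord("chr21\t10\t.\tA\tG\t50\tPASS\tXY=3\tGT\t0/1", hdr)
  expect_error(encodeBcfRecord(rec, hdr), class = "bcf_dict")
  rec2 <- parseVcfRecord("chrUn\t10\t.\tA\tG\t50\tPASS\t.\tGT\t0/1", hdr)
  expect_error(encodeBcfRecord(rec2, hdr), class = "bcf_dict")
})

test_that("our BCF is accepted record-for-record by the reference reader", {
  bt <- Sys.which("bcftools")
  expect_true(nzchar(bt))
  fx <- simulateVcf(seed = 42, nSamples = 4, nVariants = 500,
                    contigs = c(chr21 = 2e6), haploidFrac = 0.25)
  fp <- fixtureFiles(fx)
  theirs <- system2(bt, c("view", "--no-version", fp$bcf), stdout = TRUE,
                    stderr = FALSE)
  theirsBody <- theirs[!startsWith(theirs, "#")]
  mineBody <- canonText(fp$vcf)
  mineBody <- mineBody[!startsWith(mineBody, "#")]
  expect_identical(length(theirsBody), length(mineBody))
  ## field-level agreement; QUAL via numeric compare (float32 printing)
  for (i in seq_along(mineBody)) {
    a <- strsplit(theirsBody[i], "\t", fixed = TRUE)[[1]]
    b <- strsplit(mineBody[i], "\t", fixed = TRUE)[[1]]
    expect_identical(a[c(1:5, 7, 9:13)], b[c(1:5, 7, 9:13)])
    expect_lt(abs(as.numeric(a[6]) - as.numeric(b[6])), 1e-3)
  }
})

test_that("a BCF produced by the reference implementation decodes", {
  bt <- Sys.which("bcftools")
  fx <- simulateVcf(seed = 43, nSamples = 3, nVariants = 300,
                    contigs = c(chr21 = 2e6))
  tf <- tempfile(fileext = ".vcf")
  writeLines(fx$lines, tf)
  tb <- tempfile(fileext = ".bcf")
  system2(bt, c("view", "--no-version", "-O", "b", "-o", tb, tf))
  r <- openVcf(tb)
  recs <- readAllRecords(r)
  hdr <- vcfHeader(r)
  close(r)
  expect_length(recs, 300L)
  ## header dictionary honors the explicit IDX= fields bcftools writes
  expect_identical(sort(hdr@contigs$id), "chr21")
  ## genotypes survive
  ct <- countHets(tb)
  expect_identical(unname(ct),
                   unname(fx$truth$hets$snp1_pass1_q9))
})
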