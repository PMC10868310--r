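# Header/record object model: parsing, serialization, mutation,
# classification, genotypes, validation.

minHeader <- function(extraLines = character(), samples = character()) {
  parseVcfHeader(c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##contig=<ID=chr21,length=46709983>",
    extraLines,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t")))
}

test_that("headers parse: samples, declarations, failure modes", {
  h0 <- parseVcfHeader(c("##fileformat=VCFv4.2",
                         paste(c("#CHROM", "POS", "ID", "REF", "ALT",
                                 "QUAL", "FILTER", "INFO"),
                               collapse = "\t")))
  expect_length(vcfSamples(h0), 0L)
  h3 <- minHeader(samples = c("S1", "S2", "S3"))
  expect_identical(vcfSamples(h3), c("S1", "S2", "S3"))
  ## duplicate declaration
  expect_error(minHeader(
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"again\">"),
    class = "vcf_duplicate")
  ## no #CHROM line
  expect_error(parseVcfHeader("##fileformat=VCFv4.2"),
               class = "vcf_header")
  ## missing fileformat warns and defaults
  expect_warning(h <- parseVcfHeader(
    c("##FILTER=<ID=PASS,Description=\"ok\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO"), collapse = "\t"))), "fileformat")
  expect_identical(h@fileformat, "VCFv4.2")
  ## quoted commas in descriptions survive
  h <- minHeader("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"a, b, c\">")
  expect_identical(h@infos$description[h@infos$id == "CSQ"], "a, b, c")
})

test_that("dictionary indices are dense, stable, and shared across sections", {
  h <- minHeader(samples = "S1")
  ## PASS always 0; DP appears in INFO and FORMAT -> single slot
  expect_identical(h@filters$idx[h@filters$id == "PASS"], 0)
  expect_identical(h@infos$idx[h@infos$id == "DP"],
                   h@formats$idx[h@formats$id == "DP"])
  d <- VariantStream:::.headerDict(h)
  expect_identical(d[1], "PASS")
  expect_identical(anyDuplicated(d), 0L)
})

test_that("header mutation preserves untouched indices and inverts", {
  h <- minHeader(samples = "S1")
  before <- h@infos$idx
  h2 <- headerAdd(h, "FORMAT", "GQ", number = "1", type = "Integer",
                  description = "Genotype quality")
  expect_true("GQ" %in% h2@formats$id)
  expect_identical(h2@infos$idx, before)
  expect_match(paste(formatVcfHeader(h2), collapse = "\n"),
               "##FORMAT=<ID=GQ,", fixed = TRUE)
  h3 <- headerRemove(h2, "FORMAT", "GQ")
  expect_identical(h3@formats, h@formats)
  expect_error(headerAdd(h, "INFO", "DP"), class = "vcf_duplicate")
  expect_error(headerRemove(h, "FILTER", "nope"), class = "vcf_absent")
  ## removing an id still used by a held record warns
  rec <- parseVcfRecord("chr21\t5\t.\tA\tG\t30\tPASS\tDP=4\tGT\t0|1",
                        minHeader(samples = "S1"))
  expect_warning(headerRemove(h, "INFO", "DP", inUse = list(rec)),
                 "still used")
})

test_that("records parse with VCF missing-value semantics", {
  h <- minHeader(samples = "S1")
  rec <- parseVcfRecord("chr21\t5\t.\tA\tG\t30\tPASS\t.\tGT\t0|1", h)
  expect_identical(chrom(rec), "chr21")
  expect_identical(pos(rec), 5)
  expect_identical(alt(rec), "G")
  expect_identical(qual(rec), 30)
  expect_identical(filters(rec), "PASS")
  g <- genotypes(rec)$genotypes[[1]]
  expect_identical(g@alleles, c(0L, 1L))
  expect_true(g@phased)
  ## missing QUAL is NA, distinct from 0
  rec2 <- parseVcfRecord("chr21\t5\t.\tA\tG\t.\t.\t.\tGT\t0/0", h)
  expect_true(is.na(qual(rec2)))
  expect_true(is.na(filters(rec2)))
  ## column count enforcement
  expect_error(parseVcfRecord("chr21\t5\t.\tA\tG\t30\tPASS\t.\tGT", h),
               class = "vcf_format")
  h2 <- minHeader(samples = c("S1", "S2"))
  expect_error(parseVcfRecord(
    "chr21\t5\t.\tA\tG\t30\tPASS\t.\tGT\t0|1\t0/0\t1/1", h2),
    class = "vcf_format")
  expect_error(parseVcfRecord("chr21\tx5\t.\tA\tG\t30\tPASS\t.\tGT\t0|1",
                              h), class = "vcf_format")
  expect_error(parseVcfRecord("chr21\t5\t.\tA\tG\tbad\tPASS\t.\tGT\t0|1",
                              h), class = "vcf_format")
})

test_that("parse/format round-trips canonicalized lines on a fixture", {
  fx <- simulateVcf(seed = 31, nSamples = 4, nVariants = 400,
                    contigs = c(chr21 = 2e6))
  h <- fx$header
  body <- fx$lines[!startsWith(fx$lines, "#")]
  again <- vapply(body, function(ln)
    formatVcfRecord(parseVcfRecord(ln, h), h), character(1),
    USE.NAMES = FALSE)
  expect_identical(again, body)
})

test_that("variant classification follows allele structure", {
  h <- minHeader(samples = "S1")
  cls <- function(refA, altA, info = ".") {
    classifyVariant(parseVcfRecord(
      paste("chr21", "5", ".", refA, altA, "30", "PASS", info, "GT",
            "0/1", sep = "\t"), h))
  }
  expect_identical(cls("A", "G")$type, "SNP")
  expect_identical(cls("A", "AT")$type, "INDEL")
  expect_identical(cls("AT", "A")$type, "INDEL")
  expect_identical(cls("N", "<DEL>")$type, "SV")
  expect_identical(cls("AT", "GC")$type, "MNP")
  expect_identical(cls("A", "G,T")$multiallelic, TRUE)
  expect_identical(cls("A", "G")$multiallelic, FALSE)
  ## mixed alternate classes
  expect_identical(cls("A", "G,AT")$type, "OTHER")
  ## class invariant under alt reordering (non-mixed)
  expect_identical(cls("A", "T,G")$type, "SNP")
  ## breakend notation is SV
  expect_identical(cls("A", "A[chr22:100[")$type, "SV")
})

test_that("genotype matrix widths agree after widening", {
  h <- minHeader(samples = c("S1", "S2", "S3", "S4"))
  rec <- parseVcfRecord(
    "chr21\t5\t.\tA\tG,T\t30\tPASS\t.\tGT\t0|1\t1/2\t./.\t1",
    h)
  gFull <- genotypes(rec, "full-int")
  gSmall <- genotypes(rec, "small-int")
  gPres <- genotypes(rec, "presence")
  expect_identical(gFull$matrix,
                   matrix(c(0L, 1L, NA, 1L, 1L, 2L, NA, NA), nrow = 4))
  ## small-int: raw storage, 0xff = missing/pad; widen and compare
  m <- gSmall$matrix
  expect_true(is.raw(m))
  widened <- matrix(as.integer(m), nrow = nrow(m))
  widened[widened == 255L] <- NA_integer_
  expect_identical(widened, gFull$matrix)
  ## presence: carrier flags
  expect_identical(gPres$matrix, gFull$matrix > 0L)
  ## genotype objects are width-independent
  expect_identical(lapply(gFull$genotypes, slot, "alleles"),
                   lapply(gSmall$genotypes, slot, "alleles"))
  ## ploidy bookkeeping
  expect_identical(vapply(gFull$genotypes, slot, 0L, "ploidy"),
                   c(2L, 2L, 2L, 1L))
  ## small-int refuses > 127 alleles
  manyAlt <- paste(rep("A", 130), collapse = ",")
  rec2 <- parseVcfRecord(
    paste("chr21", "5", ".", "A", manyAlt, "30", "PASS", ".", "GT",
          "0/1", sep = "\t"), minHeader(samples = "S1"))
  expect_error(genotypes(rec2, "small-int"), class = "vcf_overflow")
  ## GT absent
  recNo <- parseVcfRecord("chr21\t5\t.\tA\tG\t30\tPASS\tDP=4", minHeader())
  expect_error(genotypes(recNo), class = "vcf_no_genotype")
})

test_that("heterozygosity follows the diploid called-and-different rule", {
  gt <- function(s) {
    h <- minHeader(samples = "S1")
    genotypes(parseVcfRecord(paste(
      "chr21", "5", ".", "A", "G,T", "30", "PASS", ".", "GT", s,
      sep = "\t"), h))$genotypes[[1]]
  }
  expect_true(isHet(gt("0/1")))
  expect_true(isHet(gt("0|1")))
  expect_true(isHet(gt("1/2")))   # multiallelic pair: alleles differ
  expect_false(isHet(gt("1/1")))
  expect_false(isHet(gt("./1")))
  expect_false(isHet(gt("./.")))
  expect_false(isHet(gt("1")))    # haploid
  expect_false(isHet(gt("0/1/2")))# triploid
})

test_that("validation reports undeclared tags and cardinality breaks", {
  h <- parseVcfHeader(c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"ok\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"freq\">",
    "##INFO=<ID=AD,Number=R,Type=Integer,Description=\"depths\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"likelihoods\">",
    "##contig=<ID=chr21>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t")))
  ok <- parseVcfRecord(
    "chr21\t5\t.\tA\tG\t30\tPASS\tAF=0.5;AD=3,4\tGT:PL\t0/1:1,2,3", h)
  expect_length(validateRecord(h, ok), 0L)
  ## undeclared FORMAT tag named in the violation
  bad <- parseVcfRecord(
    "chr21\t5\t.\tA\tG\t30\tPASS\tAF=0.5\tGT:XX\t0/1:9", h)
  v <- validateRecord(h, bad)
  expect_length(v, 1L)
  expect_match(v, "XX")
  ## Number=A with 2 values but 1 alt
  v <- validateRecord(h, parseVcfRecord(
    "chr21\t5\t.\tA\tG\t30\tPASS\tAF=0.5,0.5\tGT\t0/1", h))
  expect_match(v, "Number=A")
  ## enumerated A/R/G expectations against allele counts
  for (nalt in 1:3) {
    altStr <- paste(c("G", "T", "C")[seq_len(nalt)], collapse = ",")
    af <- paste(rep("0.1", nalt), collapse = ",")
    ad <- paste(rep("3", nalt + 1), collapse = ",")
    pl <- paste(rep("1", (nalt + 1) * (nalt + 2) / 2), collapse = ",")
    gtv <- paste0("0/", nalt)
    rec <- parseVcfRecord(paste(
      "chr21", "5", ".", "A", altStr, "30", "PASS",
      paste0("AF=", af, ";AD=", ad), "GT:PL", paste0(gtv, ":", pl),
      sep = "\t"), h)
    expect_length(validateRecord(h, rec), 0L)
  }
  ## undeclared FILTER
  v <- validateRecord(h, parseVcfRecord(
    "chr21\t5\t.\tA\tG\t30\tq99\tAF=0.5\tGT\t0/1", h))
  expect_match(v, "q99")
})
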