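# Analysis layer: heterozygosity counting, table extraction, summaries,
# and the streaming/two-step equivalence.

fx <- simulateVcf(seed = 61, nSamples = 6, nVariants = 800,
                  contigs = c(chr21 = 2e6, chr22 = 2e6),
                  haploidFrac = 1 / 6)
fp <- fixtureFiles(fx)

test_that("countHets recovers planted counts under every filter setting", {
  for (s in c(TRUE, FALSE)) for (p in c(TRUE, FALSE)) for (q in c(0, 9)) {
    got <- countHets(fp$vcf, snpOnly = s, passOnly = p, minQual = q)
    key <- sprintf("snp%d_pass%d_q%g", s, p, q)
    expect_identical(unname(got), unname(fx$truth$hets[[key]]),
                     info = key)
  }
  ## and the independent text recount agrees
  expect_identical(countHets(fp$vcf), textHetOracle(fx$lines))
  ## identical across encodings
  expect_identical(countHets(fp$gz), countHets(fp$vcf))
  expect_identical(countHets(fp$bcf), countHets(fp$vcf))
})

test_that("filter monotonicity: tighter filters never raise counts", {
  loose <- countHets(fp$vcf, snpOnly = FALSE, passOnly = FALSE,
                     minQual = 0)
  for (q in c(5, 9, 20, 40)) {
    tight <- countHets(fp$vcf, snpOnly = FALSE, passOnly = FALSE,
                       minQual = q)
    expect_true(all(tight <= loose))
    loose <- tight
  }
  expect_true(all(countHets(fp$vcf, snpOnly = TRUE) <=
                  countHets(fp$vcf, snpOnly = FALSE)))
  expect_true(all(countHets(fp$vcf, passOnly = TRUE) <=
                  countHets(fp$vcf, passOnly = FALSE)))
})

test_that("QUAL-below-nine records are excluded by the default filter", {
  lines <- c(fx$lines[startsWith(fx$lines, "#")][1:10],
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", "A", "B"),
                   collapse = "\t"),
             "chr21\t100\t.\tA\tG\t8\tPASS\tAF=0.5\tGT:DP:GQ\t0/1:9:80\t0/1:7:70")
  tf <- tempfile(fileext = ".vcf")
  writeLines(lines, tf)
  expect_identical(unname(countHets(tf)), c(0L, 0L))
  expect_identical(unname(countHets(tf, minQual = 8)), c(1L, 1L))
  ## all-homozygous input -> all-zero counts
  lines2 <- sub("0/1:9:80\t0/1:7:70", "1/1:9:80\t0/0:7:70",
                sub("\t8\t", "\t50\t", lines))
  writeLines(lines2, tf)
  expect_identical(unname(countHets(tf)), c(0L, 0L))
  ## GT undeclared -> no-genotype error
  lines3 <- lines[!grepl("^##FORMAT=<ID=GT", lines)]
  writeLines(lines3, tf)
  expect_error(suppressWarnings(countHets(tf)),
               class = "vcf_no_genotype")
})

test_that("vcfTable returns the planted DP matrix, typed", {
  tb <- vcfTable(fp$vcf, formatItem = "DP")
  v <- tableValues(tb)
  expect_true(is.integer(v))
  expect_identical(unname(v), unname(fx$truth$dp))
  expect_identical(rownames(v), vcfSamples(tb))
  ## filtered restriction equals the truth restriction
  keep <- fx$truth$categories == "SNP" & fx$truth$filter == "PASS" &
    fx$truth$qual >= 9
  tb2 <- vcfTable(fp$vcf, formatItem = "DP", snpOnly = TRUE,
                  passOnly = TRUE, minQual = 9)
  expect_identical(unname(tableValues(tb2)),
                   unname(fx$truth$dp[, keep, drop = FALSE]))
  expect_identical(tb2@pos, fx$truth$pos[keep])
  ## sample restriction, reordered
  tb3 <- vcfTable(fp$vcf, formatItem = "DP",
                  samples = c("S004", "S001"))
  expect_identical(unname(tableValues(tb3)),
                   unname(fx$truth$dp[c(4, 1), , drop = FALSE]))
})

test_that("the GT item yields the allele array, raw indices kept", {
  tb <- vcfTable(fp$vcf, formatItem = "GT")
  arr <- tableValues(tb)
  expect_identical(length(dim(arr)), 3L)
  expect_identical(unname(arr[, , 1]), unname(fx$truth$alleles1))
  diploid <- fx$truth$ploidy == 2L
  expect_identical(unname(arr[diploid, , 2]),
                   unname(fx$truth$alleles2[diploid, , drop = FALSE]))
  ## haploid rows are padding in slot 2
  expect_true(all(is.na(arr[!diploid, , 2])))
  ## worked two-sample "0|1","1|1" example
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
           "##contig=<ID=chr21>",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "A", "B"), collapse = "\t"),
           "chr21\t5\t.\tA\tG\t30\tPASS\t.\tGT\t0|1\t1|1")
  tf <- tempfile(fileext = ".vcf")
  writeLines(hdr, tf)
  arr2 <- tableValues(vcfTable(tf))
  expect_identical(arr2[1, 1, ], c(0L, 1L))
  expect_identical(arr2[2, 1, ], c(1L, 1L))
})

test_that("exactly one FORMAT item per pass; undeclared items refused", {
  expect_error(vcfTable(fp$vcf, formatItem = "DP,GT"),
               class = "single_item")
  expect_error(vcfTable(fp$vcf, formatItem = c("DP", "GT")),
               class = "single_item")
  expect_error(vcfTable(fp$vcf, formatItem = "ZZ"), class = "bcf_dict")
})

test_that("dropInfo discards the INFO block and nothing else", {
  a <- vcfTable(fp$vcf, formatItem = "DP", dropInfo = TRUE)
  b <- vcfTable(fp$vcf, formatItem = "DP", dropInfo = FALSE)
  expect_identical(ncol(a@info), 0L)
  expect_true("AF" %in% colnames(b@info))
  expect_identical(tableValues(a), tableValues(b))
  expect_identical(a@pos, b@pos)
})

test_that("streaming table equals the two-step load in all variations", {
  same <- function(a, b) {
    expect_identical(tableValues(a), tableValues(b))
    expect_identical(a@pos, b@pos)
    expect_identical(a@chrom, b@chrom)
    expect_identical(a@qual, b@qual)
    expect_identical(a@info, b@info)
  }
  same(vcfTable(fp$vcf, formatItem = "DP"),
       twoStepLoad(fp$vcf, formatItem = "DP"))
  same(vcfTable(fp$gz, formatItem = "GT", region = "chr21:1-1200000"),
       twoStepLoad(fp$gz, formatItem = "GT", region = "chr21:1-1200000"))
  same(vcfTable(fp$vcf, formatItem = "DP",
                samples = c("S005", "S002", "S001")),
       twoStepLoad(fp$vcf, formatItem = "DP",
                   samples = c("S005", "S002", "S001")))
  same(vcfTable(fp$bcf, formatItem = "GQ", snpOnly = TRUE, minQual = 9),
       twoStepLoad(fp$bcf, formatItem = "GQ", snpOnly = TRUE,
                   minQual = 9))
})

test_that("streaming accumulation equals the two-step record multiset", {
  r <- openVcf(fp$gz)
  streamed <- readAllRecords(r)
  close(r)
  hdr <- fx$header
  streamedLines <- vapply(streamed, formatVcfRecord, "", header = hdr)
  expect_identical(streamedLines,
                   fx$lines[!startsWith(fx$lines, "#")])
})

test_that("vcfSummary matches the planted composition", {
  sm <- vcfSummary(fp$vcf)
  expect_identical(unname(summaryPerFile(sm)["records"]), 800)
  tab <- table(factor(fx$truth$categories,
                      levels = c("SNP", "INDEL", "SV", "MNP")))
  expect_identical(as.numeric(summaryPerFile(sm)[c("SNP", "INDEL", "SV",
                                                   "MNP")]),
                   as.numeric(tab))
  expect_identical(unname(summaryPerContig(sm)),
                   unname(as.numeric(fx$truth$perContig)))
  ps <- as.matrix(summaryPerSample(sm))
  expect_true(all(ps[, c("SNP", "INDEL", "SV", "MNP")] ==
                  fx$truth$perSampleClass))
  expect_true(all(ps[, "het"] == fx$truth$perSampleHet))
  expect_true(all(ps[, "missing"] == fx$truth$perSampleMissing))
  ## class counters never exceed total records (invariant)
  expect_true(all(rowSums(ps[, c("SNP", "INDEL", "SV", "MNP", "OTHER")])
                  <= 800))
  ## empty body -> all-zero report
  tf <- tempfile(fileext = ".vcf")
  writeLines(adversarialSuite()$empty_body, tf)
  sm0 <- vcfSummary(tf)
  expect_identical(unname(summaryPerFile(sm0)["records"]), 0)
  expect_true(all(as.matrix(summaryPerSample(sm0)) == 0))
})

test_that("per-file summary totals are invariant under sample projection", {
  smAll <- vcfSummary(fp$vcf)
  smSub <- vcfSummary(fp$vcf, samples = c("S002", "S006"))
  expect_identical(summaryPerFile(smAll), summaryPerFile(smSub))
  expect_identical(summaryPerContig(smAll), summaryPerContig(smSub))
  ## and the subset's per-sample rows equal the full run's rows
  expect_identical(summaryPerSample(smSub),
                   summaryPerSample(smAll)[c("S002", "S006"), ])
})
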