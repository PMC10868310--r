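# Shared fixtures and independent oracles for the suite.
#
# The oracles here deliberately avoid the package's own parsing paths:
# the "second parser" works on raw text with base string ops only, so a
# bug in the record model cannot hide in both implementation and check.

## write a simulated fixture in all three encodings (+ .tbi); returns paths
fixtureFiles <- function(fx, dir = tempfile("fix")) {
  dir.create(dir, showWarnings = FALSE)
  vcf <- file.path(dir, "fx.vcf")
  writeLines(fx$lines, vcf)
  gz <- file.path(dir, "fx.vcf.gz")
  convertVcf(vcf, gz, "vcf-bgzf")
  bcf <- file.path(dir, "fx.bcf")
  convertVcf(vcf, bcf, "bcf")
  idx <- buildTabixIndex(gz)
  writeTabix(idx, paste0(gz, ".tbi"))
  list(vcf = vcf, gz = gz, bcf = bcf, tbi = paste0(gz, ".tbi"),
       index = idx, dir = dir)
}

## independent recount of per-sample heterozygotes straight from VCF text
textHetOracle <- function(lines, snpOnly = TRUE, passOnly = TRUE,
                          minQual = 9) {
  body <- lines[!startsWith(lines, "#")]
  hdr <- lines[startsWith(lines, "#CHROM")]
  samples <- strsplit(hdr, "\t", fixed = TRUE)[[1]][-(1:9)]
  counts <- integer(length(samples))
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    refA <- f[4]; alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    isSnp <- nchar(refA) == 1L && all(nchar(alts) == 1L) &&
      all(grepl("^[ACGTN]$", alts)) && grepl("^[ACGTN]$", refA)
    if (snpOnly && !isSnp) next
    if (passOnly && !("PASS" %in% strsplit(f[7], ";")[[1]])) next
    q <- suppressWarnings(as.numeric(f[6]))
    if (is.na(q) || q < minQual) next
    gt <- sub(":.*$", "", f[-(1:9)])
    a <- strsplit(gsub("|", "/", gt, fixed = TRUE), "/", fixed = TRUE)
    counts <- counts + vapply(a, function(x)
      length(x) == 2L && !any(x == ".") && x[1] != x[2], logical(1))
  }
  stats::setNames(counts, samples)
}

## minimal independent field scan for region oracles (text, base ops only)
textFieldScan <- function(lines) {
  body <- lines[!startsWith(lines, "#")]
  f <- strsplit(body, "\t", fixed = TRUE)
  chrom <- vapply(f, `[`, "", 1L)
  pos <- as.numeric(vapply(f, `[`, "", 2L))
  refLen <- nchar(vapply(f, `[`, "", 4L))
  info <- vapply(f, `[`, "", 8L)
  em <- regmatches(info, regexpr("(^|;)END=[0-9]+", info))
  infoEnd <- rep(NA_real_, length(body))
  has <- regexpr("(^|;)END=[0-9]+", info) > 0
  infoEnd[has] <- as.numeric(sub(".*END=", "", em))
  span <- pmax(refLen, 1)
  upd <- !is.na(infoEnd)
  span[upd] <- pmax(span[upd], infoEnd[upd] - pos[upd] + 1)
  list(chrom = chrom, pos = pos, beg0 = pos - 1, end0 = pos - 1 + span)
}

## which records (indices) overlap a 1-based inclusive region
regionOracle <- function(scan, contig, beg, end) {
  which(scan$chrom == contig & scan$beg0 < end & scan$end0 >= beg)
}

recKeys <- function(recs) {
  if (!length(recs)) return(character(0))
  vapply(recs, function(r)
    paste(chrom(r), pos(r), ref(r), paste(alt(r), collapse = ","),
          sep = "|"), character(1))
}

scanKeys <- function(lines, idx) {
  body <- lines[!startsWith(lines, "#")]
  if (!length(idx)) return(character(0))
  f <- strsplit(body[idx], "\t", fixed = TRUE)
  vapply(f, function(x) paste(x[1], x[2], x[4], x[5], sep = "|"),
         character(1))
}

## brute-force binning oracle: precomputed spans of all 37449 bins
binSpans <- local({
  lvl <- list(c(0L, 2^29), c(1L, 2^26), c(9L, 2^23), c(73L, 2^20),
              c(585L, 2^17), c(4681L, 2^14))
  lo <- numeric(37449); hi <- numeric(37449)
  for (p in lvl) {
    n <- 2^29 / p[2]
    ids <- p[1] + seq_len(n) - 1L
    lo[ids + 1L] <- (seq_len(n) - 1L) * p[2]
    hi[ids + 1L] <- seq_len(n) * p[2]
  }
  list(lo = lo, hi = hi)
})

bruteBins <- function(beg, end) {
  which(binSpans$lo < end & binSpans$hi > beg) - 1L
}

bruteBin <- function(beg, end) {
  containing <- which(binSpans$lo <= beg & binSpans$hi >= end) - 1L
  max(containing)   # deepest (smallest-span) containing bin
}

## canonical text of a file after one pass through the package codecs
canonText <- function(path) {
  out <- tempfile(fileext = ".vcf")
  convertVcf(path, out, "vcf-plain")
  readLines(out)
}
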