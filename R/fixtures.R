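# Deterministic synthetic-VCF generation with planted ground truth.
#
# The generator emulates the filter/category structure a small-variant
# workflow actually exercises — a mix of SNP/INDEL/SV/MNP records, a share
# of multiallelic sites, allele frequencies drawn from a Beta law,
# genotype missingness, a mix of phased and unphased calls, a QUAL
# distribution and a PASS/"."/q10 FILTER mix — while recording, by
# construction, every quantity the analysis layer later estimates
# (per-sample heterozygosity under each filter setting, DP matrices,
# per-contig counts).  Identical configuration and seed give byte-identical
# output.  What it does NOT emulate: linkage disequilibrium, population
# structure, or error processes of real callers.

.DEFAULT_CONTIGS <- c(chr20 = 64444167, chr21 = 46709983, chr22 = 50818468)

## exact integer split of n by proportions (largest remainder)
.exactSplit <- function(n, prop) {
  raw <- n * prop / sum(prop)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

.BASES <- c("A", "C", "G", "T")

#' Generate a synthetic VCF with planted ground truth
#'
#' Emits a coordinate-sorted, header-complete, validation-clean VCF as
#' text lines, together with truth tables that are exact by construction:
#' per-sample heterozygote counts under every combination of the standard
#' site filters, the DP matrix, per-sample variant-class counts, and
#' per-contig positions.
#'
#' The class mix is exact at the given \code{nVariants} (largest-remainder
#' apportionment, then a seeded shuffle), not a multinomial draw, so truth
#' tables never wobble with n.
#'
#' @param seed integer seed; same config + seed gives identical bytes.
#' @param nSamples,nVariants dimensions of the genotype matrix.
#' @param contigs named numeric vector of contig lengths; variants are
#'   apportioned proportionally to length.
#' @param mix named proportions over \code{c(SNP, INDEL, SV, MNP)}.
#' @param multiallelicFrac fraction of SNP/INDEL records given two
#'   alternate alleles.
#' @param afBeta shape parameters of the Beta allele-frequency law.
#' @param missingRate per-genotype probability of \code{"./."}.
#' @param phasedFrac per-genotype probability of phased (\code{"|"})
#'   output.
#' @param haploidFrac fraction of samples emitted as haploid throughout
#'   (ploidy-mixture stress; such samples never count as heterozygous).
#' @param qualRange uniform QUAL range, rounded to one decimal.
#' @param filterMix named proportions over \code{c(PASS, ".", q10)}.
#' @param formatItems subset of \code{c("GT", "DP", "GQ")}.
#' @param dpMean Poisson mean of the per-genotype read depth.
#' @return list with \code{lines} (character vector: the VCF text),
#'   \code{header} (the parsed \linkS4class{VcfHeader}) and \code{truth}
#'   (list: \code{hets} — named list over the 8 filter combinations,
#'   keys \code{"snp<s>_pass<p>_q<q>"}; \code{dp}; \code{gq};
#'   \code{categories}; \code{perSampleClass}; \code{perContig};
#'   \code{positions}; \code{filter}; \code{qual}; \code{alleles1/2}).
#' @export
simulateVcf <- function(seed = 1L, nSamples = 3L, nVariants = 1000L,
                        contigs = .DEFAULT_CONTIGS,
                        mix = c(SNP = 0.6, INDEL = 0.25, SV = 0.1,
                                MNP = 0.05),
                        multiallelicFrac = 0.15,
                        afBeta = c(1, 3), missingRate = 0.05,
                        phasedFrac = 0.5, haploidFrac = 0,
                        qualRange = c(0, 60),
                        filterMix = c(PASS = 0.7, "." = 0.1, q10 = 0.2),
                        formatItems = c("GT", "DP", "GQ"),
                        dpMean = 30) {
  stopifnot(nVariants >= 0, nSamples >= 0,
            abs(sum(mix) - 1) < 1e-9, abs(sum(filterMix) - 1) < 1e-9,
            "GT" %in% formatItems || length(formatItems) == 0L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  samples <- sprintf("S%03d", seq_len(nSamples))
  hdrLines <- c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FILTER=<ID=q10,Description=\"Quality below 10\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    if ("GT" %in% formatItems)
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if ("DP" %in% formatItems)
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    if ("GQ" %in% formatItems)
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs),
            as.integer(contigs)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (nSamples > 0) c("FORMAT", samples)), collapse = "\t"))
  hdrLines <- hdrLines[!vapply(hdrLines, is.null, logical(1))]

  if (nVariants == 0L) {
    return(list(lines = hdrLines, header = parseVcfHeader(hdrLines),
                truth = list(hets = NULL, dp = NULL,
                             perContig = integer(0),
                             positions = list())))
  }

  ## per-contig apportionment and positions (sorted, without replacement)
  perC <- .exactSplit(nVariants, contigs)
  maxLen <- 12          # widest REF/span margin we ever draw
  for (ci in seq_along(contigs))
    if (perC[ci] > contigs[ci] - 2000 - maxLen)
      vsError(sprintf("contig %s too short for %d variants",
                      names(contigs)[ci], perC[ci]), "fixture_capacity")
  chromV <- rep(names(contigs), perC)
  posV <- unlist(lapply(seq_along(contigs), function(ci)
    sort(sample.int(as.integer(contigs[ci]) - 2000L - maxLen,
                    perC[ci])) + 1000L), use.names = FALSE)

  ## exact class mix, shuffled
  catV <- sample(rep(names(mix), .exactSplit(nVariants, mix)))
  multi <- logical(nVariants)
  sm <- catV %in% c("SNP", "INDEL")
  multi[sm] <- stats::runif(sum(sm)) < multiallelicFrac

  refV <- character(nVariants); altV <- character(nVariants)
  endV <- rep(NA_real_, nVariants); nAlt <- 1L + as.integer(multi)
  for (i in seq_len(nVariants)) {
    b <- sample(.BASES, 1L)
    if (catV[i] == "SNP") {
      refV[i] <- b
      altV[i] <- paste(sample(setdiff(.BASES, b), nAlt[i]), collapse = ",")
    } else if (catV[i] == "MNP") {
      k <- sample(2:3, 1L)
      r <- sample(.BASES, k, replace = TRUE)
      a <- r
      flip <- sample(seq_len(k), max(1L, k - 1L))
      for (j in flip) a[j] <- sample(setdiff(.BASES, r[j]), 1L)
      refV[i] <- paste(r, collapse = ""); altV[i] <- paste(a, collapse = "")
    } else if (catV[i] == "INDEL") {
      ins <- stats::runif(1) < 0.5
      ext <- paste(sample(.BASES, sample(1:5, 1L), replace = TRUE),
                   collapse = "")
      alts <- character(nAlt[i])
      if (ins) { refV[i] <- b; alts[1] <- paste0(b, ext) }
      else { refV[i] <- paste0(b, ext); alts[1] <- b }
      if (nAlt[i] == 2L) {
        ## second allele: insertion one base longer than the first alt,
        ## so its length always differs from REF (keeps the class INDEL)
        alts[2] <- paste0(alts[1],
                          if (ins) sample(.BASES, 1L) else ext,
                          sample(.BASES, 1L))
      }
      altV[i] <- paste(alts, collapse = ",")
    } else {                                        # SV
      refV[i] <- b
      altV[i] <- "<DEL>"
      endV[i] <- posV[i] + sample(50:999, 1L)
    }
  }

  ## allele frequencies and genotypes
  ploidy <- rep(2L, nSamples)
  if (haploidFrac > 0 && nSamples > 0)
    ploidy[seq_len(round(haploidFrac * nSamples))] <- 1L
  a1 <- matrix(NA_integer_, nSamples, nVariants)  # NA = missing call
  a2 <- matrix(NA_integer_, nSamples, nVariants)  # NA for haploids/missing
  phased <- matrix(FALSE, nSamples, nVariants)
  afList <- vector("list", nVariants)
  for (i in seq_len(nVariants)) {
    af <- round(stats::rbeta(nAlt[i], afBeta[1], afBeta[2]), 3)
    af <- pmin(pmax(af, 0.001), 0.95)
    if (sum(af) >= 1) af <- af / (sum(af) + 0.05)
    af <- round(af, 3)
    afList[[i]] <- af
    p <- c(1 - sum(af), af)
    draws <- sample.int(nAlt[i] + 1L, 2L * nSamples, replace = TRUE,
                        prob = p) - 1L
    a1[, i] <- draws[seq_len(nSamples)]
    a2[, i] <- draws[nSamples + seq_len(nSamples)]
    phased[, i] <- stats::runif(nSamples) < phasedFrac
  }
  miss <- matrix(stats::runif(nSamples * nVariants) < missingRate,
                 nSamples, nVariants)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  hap <- ploidy == 1L
  a2[hap, ] <- NA_integer_
  missingCall <- miss                       # both-allele missing indicator

  qualV <- round(stats::runif(nVariants, qualRange[1], qualRange[2]), 1)
  filtV <- sample(names(filterMix), nVariants, replace = TRUE,
                  prob = filterMix)
  dp <- if ("DP" %in% formatItems)
    matrix(stats::rpois(nSamples * nVariants, dpMean), nSamples, nVariants)
  else NULL
  gq <- if ("GQ" %in% formatItems)
    matrix(sample.int(99L, nSamples * nVariants, replace = TRUE),
           nSamples, nVariants)
  else NULL

  ## assemble body lines (vectorized)
  infoV <- ifelse(catV == "SV",
                  sprintf("AF=%s;END=%d;SVTYPE=DEL",
                          vapply(afList, function(a)
                            paste(.fmtNum(a), collapse = ","), ""),
                          as.integer(endV)),
                  sprintf("AF=%s", vapply(afList, function(a)
                    paste(.fmtNum(a), collapse = ","), "")))
  body <- paste(chromV, as.integer(posV), ".", refV, altV,
                .fmtNum(qualV), filtV, infoV, sep = "\t")
  if (nSamples > 0) {
    s1 <- matrix(ifelse(is.na(a1), ".", as.character(a1)), nSamples)
    s2 <- matrix(ifelse(is.na(a2), ".", as.character(a2)), nSamples)
    sep <- matrix(ifelse(phased, "|", "/"), nSamples)
    gtM <- matrix(paste0(s1, sep, s2), nSamples)
    gtM[hap, ] <- s1[hap, ]                 # haploid samples: single allele
    colStr <- gtM
    if (!is.null(dp)) colStr <- matrix(paste0(colStr, ":", dp), nSamples)
    if (!is.null(gq)) colStr <- matrix(paste0(colStr, ":", gq), nSamples)
    fmt <- paste(formatItems, collapse = ":")
    sampleBlock <- apply(colStr, 2L, paste, collapse = "\t")
    body <- paste(body, fmt, sampleBlock, sep = "\t")
  }

  ## ---- truth tables (by construction) ----
  called <- !is.na(a1) & (hap | !is.na(a2))
  hetM <- !hap & !is.na(a1) & !is.na(a2) & (a1 != a2)   # samples x variants
  isSNP <- catV == "SNP"
  isPASS <- filtV == "PASS"
  hets <- list()
  for (s in c(TRUE, FALSE)) for (pq in c(TRUE, FALSE)) for (q in c(0, 9)) {
    keep <- (!s | isSNP) & (!pq | isPASS) & (qualV >= q)
    key <- sprintf("snp%d_pass%d_q%g", s, pq, q)
    hets[[key]] <- stats::setNames(as.integer(hetM %*% keep), samples)
  }
  carrier <- (!is.na(a1) & a1 > 0) | (!hap & !is.na(a2) & a2 > 0)
  perSampleClass <- sapply(c("SNP", "INDEL", "SV", "MNP"), function(k)
    as.integer(carrier %*% (catV == k)))
  if (nSamples == 1L) perSampleClass <- t(perSampleClass)
  rownames(perSampleClass) <- samples
  if (!is.null(dp)) dimnames(dp) <- list(samples, NULL)
  if (!is.null(gq)) dimnames(gq) <- list(samples, NULL)

  truth <- list(
    hets = hets, dp = dp, gq = gq,
    categories = catV, multiallelic = multi,
    perSampleClass = perSampleClass,
    perSampleHet = stats::setNames(as.integer(rowSums(hetM)), samples),
    perSampleMissing = stats::setNames(as.integer(rowSums(missingCall)),
                                       samples),
    perContig = stats::setNames(perC, names(contigs)),
    positions = split(as.numeric(posV),
                      factor(chromV, levels = names(contigs))),
    chrom = chromV, pos = as.numeric(posV), qual = qualV, filter = filtV,
    alleles1 = a1, alleles2 = a2, ploidy = ploidy, hetMatrix = hetM,
    infoEnd = endV)

  list(lines = c(hdrLines, body), header = parseVcfHeader(hdrLines),
       truth = truth)
}

#' Hand-built edge-case files
#'
#' A named list of small VCF texts exercising the codec corner cases:
#' mixed ploidy within one record, an all-missing GT column, a symbolic
#' deletion with INFO END, a multiallelic \code{"1/2"} heterozygote,
#' missing QUAL and FILTER, an undeclared body tag (the deliberate
#' specification violation for strict-mode tests), and an empty body.
#'
#' @return named list of character vectors (VCF lines).
#' @export
adversarialSuite <- function() {
  hdr <- function(fmt = c("GT", "DP"), samples = c("S1", "S2", "S3")) {
    c("##fileformat=VCFv4.2",
      "##FILTER=<ID=PASS,Description=\"All filters passed\">",
      "##FILTER=<ID=q10,Description=\"Quality below 10\">",
      "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
      "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
      "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
      "##INFO=<ID=DB,Number=0,Type=Flag,Description=\"dbSNP membership\">",
      if ("GT" %in% fmt)
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      if ("DP" %in% fmt)
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##contig=<ID=chr21,length=46709983>",
      "##contig=<ID=chr22,length=50818468>",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", samples), collapse = "\t"))
  }
  b <- function(...) paste(list(...), collapse = "\t")
  list(
    mixed_ploidy = c(hdr(),
      b("chr21", 10100, ".", "A", "G", 50, "PASS", "AF=0.2", "GT:DP",
        "0|1:10", "1:7", "1/1:22"),
      b("chr21", 10200, ".", "C", "T", 30, "PASS", "AF=0.1", "GT:DP",
        "0/0:9", "0:11", "0|1:13")),
    all_missing_gt = c(hdr(),
      b("chr21", 5000, ".", "G", "A", 12, "PASS", "AF=0.3", "GT:DP",
        "./.:.", "./.:.", "./.:.")),
    symbolic_sv = c(hdr(),
      b("chr21", 20000, "sv1", "N", "<DEL>", 60, "PASS",
        "AF=0.05;END=20650;SVTYPE=DEL", "GT:DP",
        "0|0:31", "0/1:28", "./.:.")),
    multiallelic_12 = c(hdr(),
      b("chr21", 30000, ".", "A", "G,T", 45, "PASS", "AF=0.2,0.1",
        "GT:DP", "1/2:18", "0|2:21", "2|2:16")),
    missing_qual_filter = c(hdr(),
      b("chr21", 40000, ".", "T", "C", ".", ".", "AF=0.4;DB", "GT:DP",
        "0/1:12", "1|1:.", "0/0:10")),
    undeclared_tag = c(hdr(),
      b("chr21", 50000, ".", "A", "T", 20, "PASS", "AF=0.2", "GT:XX",
        "0/1:7", "0/0:8", "1/1:9")),
    empty_body = hdr())
}
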