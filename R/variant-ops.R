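# Analysis operations over the streaming reader: per-sample heterozygosity
# counting, single-FORMAT-item table extraction, and per-sample variant
# summaries.
#
# All three stream record-by-record; vcfTable/twoStepLoad differ only in
# strategy (accumulate-as-you-go versus load-then-shape), a distinction
# kept explicit so the equivalence of the two is a tested property rather
# than an assumption.

.asReader <- function(x, region = NULL, samples = NULL) {
  if (is(x, "VcfReader")) list(reader = x, own = FALSE)
  else list(reader = openVcf(x, region = region, samples = samples),
            own = TRUE)
}

## shared site filter: SNP-only, PASS-only, minimum QUAL.  A missing QUAL
## always fails the QUAL filter (conservative); FILTER "." is "no filter
## applied", which is not PASS.
.sitePass <- function(rec, snpOnly, passOnly, minQual,
                      qualFilter = TRUE) {
  if (snpOnly && classifyVariant(rec)$type != "SNP") return(FALSE)
  if (passOnly && !("PASS" %in% rec@filter)) return(FALSE)
  if (qualFilter && (is.na(rec@qual) || rec@qual < minQual)) return(FALSE)
  TRUE
}

#' Count heterozygous genotypes per sample
#'
#' Streams the input once and, for every record passing the enabled site
#' filters, increments each sample whose genotype is heterozygous: diploid,
#' both alleles called, allele indices different (so \code{"1/2"} counts,
#' and haploid or partially missing calls never do).
#'
#' The default filters mirror the canonical counting loop for this task:
#' ignore non-SNP records (INDEL, SV, ...), records whose FILTER does not
#' display PASS, and records with QUAL below nine.
#'
#' @param x path or open \linkS4class{VcfReader}.
#' @param region,samples optional constraints (see \code{\link{openVcf}}).
#' @param snpOnly keep SNP records only (default TRUE).
#' @param passOnly require PASS in FILTER (default TRUE).
#' @param minQual minimum QUAL, inclusive (default 9); records with
#'   missing QUAL never pass.
#' @return named integer vector, one count per surfaced sample.
#' @examples
#' fx <- simulateVcf(seed = 7, nSamples = 3, nVariants = 200)
#' p <- tempfile(fileext = ".vcf"); writeLines(fx$lines, p)
#' countHets(p)
#' @export
countHets <- function(x, region = NULL, samples = NULL, snpOnly = TRUE,
                      passOnly = TRUE, minQual = 9) {
  if (minQual < 0) vsError("minQual must be >= 0", "bad_filter")
  h <- .asReader(x, region, samples)
  if (h$own) on.exit(close(h$reader))
  rd <- h$reader
  hdr <- vcfHeader(rd)
  if (!"GT" %in% hdr@formats$id)
    vsError("no GT FORMAT declaration: cannot count heterozygotes",
            "vcf_no_genotype")
  counts <- integer(length(hdr@samples))
  names(counts) <- hdr@samples
  repeat {
    rec <- readRecord(rd)
    if (is.null(rec)) break
    if (!.sitePass(rec, snpOnly, passOnly, minQual)) next
    gt <- .gtStrings(rec)
    if (is.null(gt)) next
    counts <- counts + .hetVec(gt)
  }
  counts
}

## ---------------------------------------------------------------------------
## vcftable
## ---------------------------------------------------------------------------

.checkSingleItem <- function(formatItem) {
  if (length(formatItem) != 1L || grepl(",", formatItem, fixed = TRUE))
    vsError(paste0("exactly one FORMAT item can be read per pass ",
                   "(requested: ", paste(formatItem, collapse = ","), ")"),
            "single_item")
  formatItem
}

## shape accumulated per-record cells into the samples x variants
## matrix/array
.shapeValues <- function(cells, nSamples, formatItem, itemType, gtPloidy) {
  nVar <- length(cells)
  if (formatItem == "GT") {
    maxP <- if (nVar) max(vapply(cells, ncol, integer(1))) else gtPloidy
    arr <- array(NA_integer_, dim = c(nSamples, nVar, maxP))
    for (j in seq_len(nVar)) {
      m <- cells[[j]]
      arr[, j, seq_len(ncol(m))] <- m
    }
    return(arr)
  }
  maxL <- if (nVar) max(vapply(cells, function(m) dim(m)[2], integer(1)))
          else 1L
  proto <- if (itemType == "Integer") NA_integer_
           else if (itemType == "Float") NA_real_ else NA_character_
  if (maxL <= 1L) {
    out <- matrix(proto, nrow = nSamples, ncol = nVar)
    for (j in seq_len(nVar)) out[, j] <- cells[[j]][, 1L]
    out
  } else {
    out <- array(proto, dim = c(nSamples, nVar, maxL))
    for (j in seq_len(nVar))
      out[, j, seq_len(dim(cells[[j]])[2])] <- cells[[j]]
    out
  }
}

## one record's cell for the requested item: a samples x width matrix
.itemCell <- function(rec, formatItem, itemType, header) {
  if (formatItem == "GT") {
    genotypes(rec, "full-int")$matrix
  } else {
    vals <- formatValues(rec, formatItem, header)
    w <- max(lengths(vals), 1L)
    proto <- if (itemType == "Integer") NA_integer_
             else if (itemType == "Float") NA_real_ else NA_character_
    m <- matrix(proto, nrow = length(vals), ncol = w)
    for (i in seq_along(vals)) {
      v <- vals[[i]]
      if (length(v)) m[i, seq_along(v)] <- v
    }
    m
  }
}

#' Load one FORMAT item as a variant table
#'
#' Streams the file once, keeping the variants that pass the optional
#' filters, and returns the site columns together with the requested
#' FORMAT item as a typed samples x variants matrix — integer or numeric
#' for declared Integer/Float items (never character), and for GT an
#' integer allele array of dimension samples x variants x ploidy.  Exactly
#' one FORMAT item can be extracted per pass over the file; requesting two
#' is an error by design.
#'
#' @param x path or open \linkS4class{VcfReader}.
#' @param region,samples optional constraints (see \code{\link{openVcf}}).
#' @param formatItem the single FORMAT id to extract (default \code{"GT"}).
#' @param snpOnly,passOnly,minQual site filters as in
#'   \code{\link{countHets}}, all disabled by default; the QUAL filter
#'   (which also drops missing-QUAL records) engages only when
#'   \code{minQual > 0}.
#' @param dropInfo omit the INFO column block.
#' @return a \linkS4class{VariantTable}.
#' @export
vcfTable <- function(x, region = NULL, samples = NULL, formatItem = "GT",
                     snpOnly = FALSE, passOnly = FALSE, minQual = 0,
                     dropInfo = FALSE) {
  .checkSingleItem(formatItem)
  h <- .asReader(x, region, samples)
  if (h$own) on.exit(close(h$reader))
  rd <- h$reader
  hdr <- vcfHeader(rd)
  def <- .fieldDef(hdr, "FORMAT", formatItem)
  if (is.null(def))
    vsError(sprintf("FORMAT item '%s' is not declared in the header",
                    formatItem), "bcf_dict")
  itemType <- if (formatItem == "GT") "Integer" else def$type
  chromV <- character(); posV <- numeric(); idV <- character()
  refV <- character(); altV <- character(); qualV <- numeric()
  filtV <- character(); infoL <- list(); cells <- list()
  n <- 0L
  repeat {
    rec <- readRecord(rd)
    if (is.null(rec)) break
    if (snpOnly || passOnly || minQual > 0) {
      if (!.sitePass(rec, snpOnly, passOnly, minQual,
                     qualFilter = minQual > 0)) next
    }
    n <- n + 1L
    chromV[n] <- rec@chrom; posV[n] <- rec@pos
    idV[n] <- rec@id; refV[n] <- rec@ref
    altV[n] <- if (length(rec@alt)) paste(rec@alt, collapse = ",") else "."
    qualV[n] <- rec@qual
    filtV[n] <- if (all(is.na(rec@filter))) "."
                else paste(rec@filter, collapse = ";")
    if (!dropInfo) infoL[[n]] <- rec@info
    cells[[n]] <- .itemCell(rec, formatItem, itemType, hdr)
  }
  info <- if (dropInfo || n == 0L) data.frame() else {
    keys <- unique(unlist(lapply(infoL, names)))
    as.data.frame(stats::setNames(lapply(keys, function(k) {
      vapply(infoL, function(ii) {
        v <- ii[[k]]
        if (is.null(v)) NA_character_
        else if (isTRUE(v) && is.logical(v)) "TRUE"
        else paste(ifelse(is.na(v), ".",
                          if (is.numeric(v)) .fmtNum(v)
                          else as.character(v)), collapse = ",")
      }, character(1))
    }), keys), optional = TRUE)
  }
  vals <- .shapeValues(cells, length(vcfSamples(rd)), formatItem, itemType,
                       2L)
  rownames(vals) <- vcfSamples(rd)
  new("VariantTable", chrom = chromV, pos = posV, id = idV, ref = refV,
      alt = altV, qual = qualV, filter = filtV, info = info,
      formatItem = formatItem, values = vals, samples = vcfSamples(rd))
}

#' Two-step load of a variant table
#'
#' Loads every (filtered) record into memory first, then shapes the table
#' — the classic load-then-analyze strategy, as opposed to the streaming
#' accumulation of \code{\link{vcfTable}}.  The result is identical by
#' construction of the shared shaping step; keeping both entry points
#' makes that equivalence an explicit, testable contract.
#'
#' @inheritParams vcfTable
#' @return a \linkS4class{VariantTable}.
#' @export
twoStepLoad <- function(x, region = NULL, samples = NULL,
                        formatItem = "GT", snpOnly = FALSE,
                        passOnly = FALSE, minQual = 0, dropInfo = FALSE) {
  .checkSingleItem(formatItem)
  h <- .asReader(x, region, samples)
  if (h$own) on.exit(close(h$reader))
  rd <- h$reader
  ## step 1: load everything
  recs <- readAllRecords(rd)
  hdr <- vcfHeader(rd)
  def <- .fieldDef(hdr, "FORMAT", formatItem)
  if (is.null(def))
    vsError(sprintf("FORMAT item '%s' is not declared in the header",
                    formatItem), "bcf_dict")
  itemType <- if (formatItem == "GT") "Integer" else def$type
  ## step 2: filter and shape
  if (snpOnly || passOnly || minQual > 0)
    recs <- Filter(function(rec)
      .sitePass(rec, snpOnly, passOnly, minQual,
                qualFilter = minQual > 0), recs)
  cells <- lapply(recs, .itemCell, formatItem, itemType, hdr)
  info <- if (dropInfo || !length(recs)) data.frame() else {
    infoL <- lapply(recs, slot, "info")
    keys <- unique(unlist(lapply(infoL, names)))
    as.data.frame(stats::setNames(lapply(keys, function(k) {
      vapply(infoL, function(ii) {
        v <- ii[[k]]
        if (is.null(v)) NA_character_
        else if (isTRUE(v) && is.logical(v)) "TRUE"
        else paste(ifelse(is.na(v), ".",
                          if (is.numeric(v)) .fmtNum(v)
                          else as.character(v)), collapse = ",")
      }, character(1))
    }), keys), optional = TRUE)
  }
  vals <- .shapeValues(cells, length(vcfSamples(rd)), formatItem, itemType,
                       2L)
  rownames(vals) <- vcfSamples(rd)
  new("VariantTable",
      chrom = vapply(recs, slot, character(1), "chrom"),
      pos = vapply(recs, slot, numeric(1), "pos"),
      id = vapply(recs, slot, character(1), "id"),
      ref = vapply(recs, slot, character(1), "ref"),
      alt = vapply(recs, function(r)
        if (length(r@alt)) paste(r@alt, collapse = ",") else ".",
        character(1)),
      qual = vapply(recs, slot, numeric(1), "qual"),
      filter = vapply(recs, function(r)
        if (all(is.na(r@filter))) "." else paste(r@filter, collapse = ";"),
        character(1)),
      info = info, formatItem = formatItem, values = vals,
      samples = vcfSamples(rd))
}

#' @describeIn VariantTable-class sample names (matrix rows)
#' @export
setMethod("vcfSamples", "VariantTable", function(x) x@samples)

setMethod("show", "VariantTable", function(object) {
  cat(sprintf("VariantTable: %d variant(s) x %d sample(s), item %s (%s)\n",
              length(object@pos), length(object@samples),
              object@formatItem, paste(class(object@values), collapse = "/")))
})

#' @export
setMethod("dim", "VariantTable", function(x)
  c(length(x@samples), length(x@pos)))

#' Site columns of a variant table as a data.frame
#'
#' @param x a \linkS4class{VariantTable}.
#' @param ... unused.
#' @return data.frame of the site columns (plus INFO columns when kept).
#' @export
as.data.frame.VariantTable <- function(x, ...) {
  d <- data.frame(chrom = x@chrom, pos = x@pos, id = x@id, ref = x@ref,
                  alt = x@alt, qual = x@qual, filter = x@filter,
                  stringsAsFactors = FALSE)
  if (ncol(x@info)) d <- cbind(d, x@info)
  d
}

#' @describeIn VariantTable-class the samples x variants value matrix (or
#'   allele array for GT)
#' @export
tableValues <- function(x) x@values

#' Export a variant table as TSV
#'
#' Site columns first, then one column per sample (multi-value cells are
#' comma-joined; GT cells print as allele strings joined with
#' \code{"/"}).
#'
#' @param x a \linkS4class{VariantTable}.
#' @param file path or connection (default: standard output).
#' @export
writeVariantTable <- function(x, file = stdout()) {
  d <- as.data.frame(x)
  v <- x@values
  n <- length(x@pos)
  sampleCols <- lapply(seq_along(x@samples), function(i) {
    vapply(seq_len(n), function(j) {
      cell <- if (length(dim(v)) == 3L) v[i, j, ] else v[i, j]
      cell <- cell[!is.na(cell)]
      if (!length(cell)) "."
      else paste(if (is.numeric(cell)) .fmtNum(cell) else cell,
                 collapse = if (x@formatItem == "GT") "/" else ",")
    }, character(1))
  })
  names(sampleCols) <- x@samples
  out <- cbind(d, as.data.frame(sampleCols, optional = TRUE))
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

## ---------------------------------------------------------------------------
## vcfsummary
## ---------------------------------------------------------------------------

#' Summarize the variants in a VCF/BCF
#'
#' One streaming pass produces per-file totals (records, variant classes,
#' per-contig counts) and per-sample counters.  A record contributes to a
#' sample's class counters only when that sample carries at least one
#' called non-reference allele (hom-ref carriers have not "found" the
#' variant); \code{het}, \code{homAlt} and \code{missing} count genotype
#' states.  When GT is absent the genotype-dependent counters are skipped
#' with a notice.
#'
#' @param x path or open \linkS4class{VcfReader}.
#' @param region,samples optional constraints (see \code{\link{openVcf}}).
#' @return a \linkS4class{SummaryReport}.
#' @export
vcfSummary <- function(x, region = NULL, samples = NULL) {
  h <- .asReader(x, region, samples)
  if (h$own) on.exit(close(h$reader))
  rd <- h$reader
  hdr <- vcfHeader(rd)
  smp <- hdr@samples
  hasGT <- "GT" %in% hdr@formats$id
  if (!hasGT && length(smp))
    vsNotice("no GT declaration: per-sample genotype counters skipped")
  classes <- c("SNP", "INDEL", "SV", "MNP", "OTHER")
  perSample <- matrix(0, nrow = length(smp),
                      ncol = length(classes) + 4L,
                      dimnames = list(smp, c(classes, "multiallelic",
                                             "het", "homAlt", "missing")))
  perFile <- stats::setNames(numeric(length(classes) + 2L),
                             c("records", classes, "multiallelic"))
  perContig <- numeric(0)
  repeat {
    rec <- readRecord(rd)
    if (is.null(rec)) break
    cl <- classifyVariant(rec)
    perFile["records"] <- perFile["records"] + 1
    perFile[cl$type] <- perFile[cl$type] + 1
    if (cl$multiallelic)
      perFile["multiallelic"] <- perFile["multiallelic"] + 1
    if (is.na(match(rec@chrom, names(perContig))))
      perContig[rec@chrom] <- 0
    perContig[rec@chrom] <- perContig[rec@chrom] + 1
    if (hasGT && length(smp)) {
      gt <- .gtStrings(rec)
      if (is.null(gt)) next
      al <- strsplit(gsub("|", "/", gt, fixed = TRUE), "/", fixed = TRUE)
      anyMiss <- vapply(al, function(a) any(a == "."), logical(1))
      carrier <- vapply(al, function(a)
        any(a != "." & a != "0"), logical(1))
      het <- .hetVec(gt)
      hom <- vapply(al, function(a)
        !any(a == ".") && length(unique(a)) == 1L && a[1] != "0",
        logical(1))
      perSample[carrier, cl$type] <- perSample[carrier, cl$type] + 1
      if (cl$multiallelic)
        perSample[carrier, "multiallelic"] <-
          perSample[carrier, "multiallelic"] + 1
      perSample[het, "het"] <- perSample[het, "het"] + 1
      perSample[hom, "homAlt"] <- perSample[hom, "homAlt"] + 1
      perSample[anyMiss, "missing"] <- perSample[anyMiss, "missing"] + 1
    }
  }
  new("SummaryReport",
      perSample = as.data.frame(perSample), perFile = perFile,
      perContig = perContig, samples = smp)
}

setMethod("show", "SummaryReport", function(object) {
  cat("SummaryReport\n")
  cat(sprintf("  records: %d over %d contig(s)\n",
              as.integer(object@perFile["records"]),
              length(object@perContig)))
  cat("  site classes:",
      paste(sprintf("%s=%d", names(object@perFile)[-1],
                    as.integer(object@perFile[-1])), collapse = " "), "\n")
  if (nrow(object@perSample)) {
    cat("  per-sample counters (first rows):\n")
    print(utils::head(object@perSample, 5))
  }
})

#' @describeIn SummaryReport-class per-sample counter data.frame
#' @export
summaryPerSample <- function(x) x@perSample
#' @describeIn SummaryReport-class named per-file totals
#' @export
summaryPerFile <- function(x) x@perFile
#' @describeIn SummaryReport-class per-contig record counts
#' @export
summaryPerContig <- function(x) x@perContig

#' Export a summary report as TSV
#'
#' @param x a \linkS4class{SummaryReport}.
#' @param file path or connection (default: standard output).
#' @export
writeSummaryReport <- function(x, file = stdout()) {
  d <- cbind(sample = rownames(x@perSample), x@perSample)
  utils::write.table(d, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
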