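# VCF body-line parsing, serialization, variant-type classification,
# genotype extraction and advisory validation.
#
# Parsing is deliberately lazy on the per-sample block: the colon-joined
# sample strings are retained verbatim and only split into typed values
# when an accessor asks for a FORMAT item.  A streaming consumer that only
# looks at GT (the common case) therefore never pays for DP/GQ parsing.

.typeConvert <- function(vals, type) {
  vals[vals == "."] <- NA_character_
  switch(type,
         Integer = suppressWarnings(as.integer(vals)),
         Float = suppressWarnings(as.numeric(vals)),
         vals)
}

.parseInfo <- function(s, header) {
  if (s == "." || s == "") return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  eq <- regexpr("=", parts, fixed = TRUE)
  keys <- ifelse(eq > 0L, substr(parts, 1L, eq - 1L), parts)
  vals <- ifelse(eq > 0L, substr(parts, eq + 1L, nchar(parts)), NA)
  out <- vector("list", length(parts))
  names(out) <- keys
  for (i in seq_along(parts)) {
    if (eq[i] < 0L) { out[[i]] <- TRUE; next }  # flag
    def <- .fieldDef(header, "INFO", keys[i])
    vv <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    out[[i]] <- if (is.null(def)) vv else .typeConvert(vv, def$type)
  }
  out
}

#' Parse one VCF body line
#'
#' Splits a TAB-delimited body line into a typed \linkS4class{VcfRecord}.
#' \code{"."} maps to missing in ID, QUAL, FILTER, INFO and sample values
#' (a missing QUAL is distinct from 0).  The per-sample block is kept as
#' raw strings and typed on demand (see \code{\link{formatValues}}).
#'
#' @param line character(1) body line.
#' @param header the \linkS4class{VcfHeader} governing the file.
#' @param lineNo optional line number quoted in error messages.
#' @return a \linkS4class{VcfRecord}.
#' @seealso [formatVcfRecord()], [validateRecord()], [classifyVariant()]
#' @export
parseVcfRecord <- function(line, header, lineNo = NA_integer_) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  nS <- length(header@samples)
  expect <- if (nS > 0L) 9L + nS else 8L
  where <- if (is.na(lineNo)) "" else sprintf(" (line %d)", lineNo)
  if (length(f) != expect) {
    ## sites-only lines are tolerated in a samples file only if exactly 8
    if (!(nS == 0L && length(f) == 9L))
      vsError(sprintf("expected %d TAB-separated fields, found %d%s",
                      expect, length(f), where), "vcf_format")
  }
  if (!grepl("^[0-9]+$", f[2]))
    vsError(sprintf("non-numeric POS '%s'%s", f[2], where), "vcf_format")
  qual <- if (f[6] == ".") NA_real_ else {
    q <- suppressWarnings(as.numeric(f[6]))
    if (is.na(q)) vsError(sprintf("non-numeric QUAL '%s'%s", f[6], where),
                          "vcf_format")
    if (q < 0) vsError(sprintf("negative QUAL%s", where), "vcf_format")
    q
  }
  alt <- if (f[5] == "." || f[5] == "") character() else
    strsplit(f[5], ",", fixed = TRUE)[[1]]
  filt <- if (f[7] == ".") NA_character_ else
    strsplit(f[7], ";", fixed = TRUE)[[1]]
  fmtKeys <- if (length(f) >= 9L && nzchar(f[9]) && f[9] != ".")
    strsplit(f[9], ":", fixed = TRUE)[[1]] else character()
  new("VcfRecord",
      chrom = f[1], pos = as.numeric(f[2]),
      id = if (f[3] == ".") NA_character_ else f[3],
      ref = f[4], alt = alt, qual = qual, filter = filt,
      info = .parseInfo(f[8], header),
      formatKeys = fmtKeys,
      sampleRaw = if (nS > 0L) f[10:length(f)] else character(),
      sampleData = list(), nSamples = nS)
}

.fmtInfo <- function(info) {
  if (!length(info)) return(".")
  paste(vapply(seq_along(info), function(i) {
    v <- info[[i]]
    if (isTRUE(v) && length(v) == 1L && is.logical(v)) names(info)[i]
    else paste0(names(info)[i], "=",
                paste(ifelse(is.na(v), ".",
                             if (is.numeric(v)) .fmtNum(v) else as.character(v)),
                      collapse = ","))
  }, character(1)), collapse = ";")
}

## per-sample colon strings, from sampleRaw if present, else sampleData
.sampleStrings <- function(rec) {
  if (length(rec@sampleRaw) || rec@nSamples == 0L) return(rec@sampleRaw)
  cols <- lapply(rec@formatKeys, function(k) {
    vals <- rec@sampleData[[k]]
    vapply(vals, function(v) {
      if (length(v) == 0L || all(is.na(v))) "."
      else paste(ifelse(is.na(v), ".",
                        if (is.numeric(v)) .fmtNum(v) else as.character(v)),
                 collapse = ",")
    }, character(1))
  })
  do.call(paste, c(cols, sep = ":"))
}

#' Serialize a record to a VCF body line
#'
#' Inverse of \code{\link{parseVcfRecord}} up to numeric canonicalization
#' (integers print bare; reals print with \code{\%g}).
#'
#' @param record a \linkS4class{VcfRecord}.
#' @param header the governing \linkS4class{VcfHeader}.
#' @return character(1) TAB-delimited line.
#' @export
formatVcfRecord <- function(record, header) {
  fields <- c(record@chrom, .fmtNum(record@pos),
              if (is.na(record@id)) "." else record@id,
              record@ref,
              if (length(record@alt)) paste(record@alt, collapse = ",")
              else ".",
              .fmtNum(record@qual),
              if (all(is.na(record@filter))) "."
              else paste(record@filter, collapse = ";"),
              .fmtInfo(record@info))
  if (record@nSamples > 0L)
    fields <- c(fields,
                if (length(record@formatKeys))
                  paste(record@formatKeys, collapse = ":") else ".",
                .sampleStrings(record))
  paste(fields, collapse = "\t")
}

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' @describeIn VcfRecord-class contig name
#' @export
setMethod("chrom", "VcfRecord", function(x) x@chrom)
#' @describeIn VcfRecord-class 1-based position
#' @export
setMethod("pos", "VcfRecord", function(x) x@pos)
#' @describeIn VcfRecord-class reference allele
#' @export
setMethod("ref", "VcfRecord", function(x) x@ref)
#' @describeIn VcfRecord-class alternate alleles (character vector)
#' @export
setMethod("alt", "VcfRecord", function(x) x@alt)
#' @describeIn VcfRecord-class site quality or NA
#' @export
setMethod("qual", "VcfRecord", function(x) x@qual)
#' @describeIn VcfRecord-class filter ids, or NA when no filter applied
#' @export
setMethod("filters", "VcfRecord", function(x) x@filter)
#' @describeIn VcfRecord-class ordered FORMAT ids
#' @export
setMethod("formatKeys", "VcfRecord", function(x) x@formatKeys)
#' @describeIn VcfRecord-class typed INFO value (TRUE for a flag; NULL when
#'   absent)
#' @export
setMethod("infoValues", "VcfRecord", function(x, id) x@info[[id]])

setMethod("show", "VcfRecord", function(object) {
  cat(sprintf("VcfRecord %s:%s %s>%s qual=%s [%d sample(s)]\n",
              object@chrom, .fmtNum(object@pos), object@ref,
              if (length(object@alt)) paste(object@alt, collapse = ",")
              else ".",
              .fmtNum(object@qual), object@nSamples))
})

#' Extract one FORMAT item's typed per-sample values
#'
#' Values are typed by the item's header declaration: Integer and Float
#' items come back numeric, never character.  Missing values (and fields
#' beyond a truncated sample string) are \code{NA}.
#'
#' @param record a \linkS4class{VcfRecord}.
#' @param key FORMAT id.
#' @param header the governing \linkS4class{VcfHeader}.
#' @return list with one typed vector per sample.
#' @export
formatValues <- function(record, key, header) {
  if (length(record@sampleData) && key %in% names(record@sampleData))
    return(record@sampleData[[key]])
  j <- match(key, record@formatKeys)
  if (is.na(j))
    return(rep(list(NA), record@nSamples))
  parts <- strsplit(record@sampleRaw, ":", fixed = TRUE)
  def <- .fieldDef(header, "FORMAT", key)
  type <- if (is.null(def)) "String" else def$type
  lapply(parts, function(p) {
    if (length(p) < j) return(.typeConvert(NA_character_, type))
    .typeConvert(strsplit(p[j], ",", fixed = TRUE)[[1]], type)
  })
}

## GT strings (fast path: GT is constrained to be the first FORMAT key)
.gtStrings <- function(record) {
  if (length(record@sampleRaw)) {
    j <- match("GT", record@formatKeys)
    if (is.na(j)) return(NULL)
    if (j == 1L) sub(":.*$", "", record@sampleRaw)
    else vapply(strsplit(record@sampleRaw, ":", fixed = TRUE),
                `[`, character(1), j)
  } else if ("GT" %in% names(record@sampleData)) {
    unlist(record@sampleData[["GT"]], use.names = FALSE)
  } else NULL
}

## ---------------------------------------------------------------------------
## Genotypes
## ---------------------------------------------------------------------------

.parseGenotype <- function(s) {
  toks <- strsplit(s, "", fixed = TRUE)[[1]]
  seps <- toks %in% c("/", "|")
  fields <- strsplit(gsub("\\|", "/", s), "/", fixed = FALSE)[[1]]
  alleles <- suppressWarnings(as.integer(fields))
  phased <- toks[seps] == "|"
  new("Genotype", alleles = alleles, phased = phased,
      ploidy = length(alleles))
}

#' Per-sample genotypes and the genotype matrix view
#'
#' Parses the GT item into \linkS4class{Genotype} objects plus a matrix
#' view whose storage width is selectable, independent of the Genotype
#' objects themselves:
#' \describe{
#'   \item{\code{"presence"}}{carrier flags — \code{TRUE} iff the allele
#'     index exceeds 0 (logical matrix; \code{NA} for missing).}
#'   \item{\code{"small-int"}}{8-bit allele indices as a raw matrix, valid
#'     while the record has at most 127 alleles; \code{0xff} marks
#'     missing/padding.}
#'   \item{\code{"full-int"}}{plain integer matrix, \code{NA} for
#'     missing/padding.}
#' }
#' The matrix has one row per sample and one column per allele slot
#' (max ploidy); samples of lower ploidy are padded.
#'
#' @param x a \linkS4class{VcfRecord} with GT among its FORMAT keys.
#' @param width storage width of the matrix view.
#' @return list with \code{genotypes} (list of \linkS4class{Genotype}) and
#'   \code{matrix}.
#' @export
setMethod("genotypes", "VcfRecord", function(x, width = c("full-int",
                                                          "small-int",
                                                          "presence")) {
  width <- match.arg(width)
  gt <- .gtStrings(x)
  if (is.null(gt))
    vsError("record has no GT FORMAT item", "vcf_no_genotype")
  gts <- lapply(gt, .parseGenotype)
  maxP <- max(vapply(gts, function(g) g@ploidy, integer(1)), 1L)
  m <- matrix(NA_integer_, nrow = length(gts), ncol = maxP)
  for (i in seq_along(gts))
    m[i, seq_len(gts[[i]]@ploidy)] <- gts[[i]]@alleles
  nAllele <- 1L + length(x@alt)
  mat <- switch(width,
    "full-int" = m,
    "small-int" = {
      if (nAllele > 127L)
        vsError("small-int genotype matrix invalid: more than 127 alleles",
                "vcf_overflow")
      r <- m; r[is.na(r)] <- 255L
      matrix(as.raw(r), nrow = nrow(m))
    },
    "presence" = m > 0L)
  rownames(mat) <- names(gts) <- NULL
  list(genotypes = gts, matrix = mat)
})

#' Heterozygosity of a single genotype
#'
#' TRUE iff the call is diploid, both alleles are called, and the two
#' allele indices differ.  Haploid calls, missing alleles and higher
#' ploidies are never heterozygous; the multiallelic pair \code{"1/2"}
#' counts (the alleles differ).
#'
#' @param x a \linkS4class{Genotype}.
#' @return logical(1).
#' @export
setMethod("isHet", "Genotype", function(x) {
  x@ploidy == 2L && !anyNA(x@alleles) && x@alleles[1] != x@alleles[2]
})

## vectorized het test on raw GT strings: exactly two numeric alleles that
## differ (backreference + negative lookahead); missing alleles fail the
## [0-9]+ atoms
.hetVec <- function(gt) {
  grepl("^([0-9]+)[/|](?!\\1$)[0-9]+$", gt, perl = TRUE)
}

## ---------------------------------------------------------------------------
## Classification
## ---------------------------------------------------------------------------

.SEQ_RE <- "^[ACGTNacgtn]+$"

.classifyAlt <- function(refStr, altStr) {
  symbolic <- startsWith(altStr, "<") |
    grepl("[][]", altStr) | altStr == "*" |
    startsWith(altStr, ".") | endsWith(altStr, ".")
  seqOk <- grepl(.SEQ_RE, altStr) & grepl(.SEQ_RE, refStr)
  rl <- nchar(refStr); al <- nchar(altStr)
  out <- rep("OTHER", length(altStr))
  out[symbolic] <- "SV"
  snp <- !symbolic & seqOk & rl == 1L & al == 1L
  mnp <- !symbolic & seqOk & rl == al & rl > 1L
  ind <- !symbolic & seqOk & rl != al
  out[snp] <- "SNP"; out[mnp] <- "MNP"; out[ind] <- "INDEL"
  out
}

#' Classify a variant record
#'
#' SNP iff every allele has length 1 and is a base; MNP for equal-length
#' multi-base substitutions; INDEL when allele lengths differ and all are
#' sequence; SV when any alternate is symbolic (\code{"<...>"}) or a
#' breakend; records mixing alternate classes are OTHER, as are sites with
#' no alternate allele.  The multiallelic flag is set iff there is more
#' than one alternate.
#'
#' @param x a \linkS4class{VcfRecord}.
#' @return list with \code{type} (one of SNP, MNP, INDEL, SV, OTHER) and
#'   \code{multiallelic} (logical).
#' @export
setMethod("classifyVariant", "VcfRecord", function(x) {
  if (length(x@alt) == 0L)
    return(list(type = "OTHER", multiallelic = FALSE))
  cls <- .classifyAlt(x@ref, x@alt)
  if (any(cls == "SV") && !all(cls == "SV"))
    type <- "OTHER"
  else if (all(cls == cls[1])) type <- cls[1]
  else type <- "OTHER"
  list(type = type, multiallelic = length(x@alt) > 1L)
})

## vectorized classification over pre-split fields (streaming ops fast path)
.classifyVec <- function(refs, altCsv) {
  alts <- strsplit(altCsv, ",", fixed = TRUE)
  vapply(seq_along(refs), function(i) {
    a <- alts[[i]]
    if (length(a) == 0L || identical(a, ".")) return("OTHER")
    cls <- .classifyAlt(refs[i], a)
    if (all(cls == cls[1])) cls[1] else "OTHER"
  }, character(1))
}

## ---------------------------------------------------------------------------
## Validation
## ---------------------------------------------------------------------------

## expected value count for a declared Number, given allele count & ploidy
.expectedCount <- function(number, nAllele, ploidy = 2L) {
  switch(number,
         "A" = nAllele - 1L,
         "R" = nAllele,
         "G" = choose(nAllele + ploidy - 1L, ploidy),
         "." = NA_integer_,
         suppressWarnings(as.integer(number)))
}

#' Validate a record against its header
#'
#' Reports (never raises) one violation per undeclared INFO, FORMAT or
#' FILTER id used by the record — a file carrying a tag in the body without
#' its header declaration violates the format specification — plus type and
#' cardinality mismatches: declared Integer/Float values that fail to
#' parse, and value counts that contradict Number declarations (A = one per
#' alternate allele, R = one per allele, G = one per genotype).
#'
#' @param header the governing \linkS4class{VcfHeader}.
#' @param record a \linkS4class{VcfRecord}.
#' @return character vector of human-readable violations (empty when
#'   clean).
#' @export
validateRecord <- function(header, record) {
  v <- character()
  nAllele <- 1L + length(record@alt)
  ## FILTER ids
  known <- c("PASS", header@filters$id)
  bad <- setdiff(record@filter[!is.na(record@filter)], known)
  for (b in bad)
    v <- c(v, sprintf("FILTER id '%s' is not declared in the header", b))
  ## INFO
  for (k in names(record@info)) {
    def <- .fieldDef(header, "INFO", k)
    if (is.null(def)) {
      v <- c(v, sprintf("INFO tag '%s' is not declared in the header", k))
      next
    }
    val <- record@info[[k]]
    if (def$type == "Flag") {
      if (!isTRUE(val))
        v <- c(v, sprintf("INFO flag '%s' carries a value", k))
      next
    }
    exp <- .expectedCount(def$number, nAllele)
    if (!is.na(exp) && length(val) != exp)
      v <- c(v, sprintf(
        "INFO '%s' has %d value(s); Number=%s implies %d for %d allele(s)",
        k, length(val), def$number, exp, nAllele))
    if (def$type %in% c("Integer", "Float") && any(is.na(val)) &&
        is.character(val))
      v <- c(v, sprintf("INFO '%s' is not parseable as %s", k, def$type))
  }
  ## FORMAT
  ploidy <- 2L
  gt <- .gtStrings(record)
  if (!is.null(gt) && length(gt))
    ploidy <- max(lengths(strsplit(gsub("\\|", "/", gt), "/",
                                   fixed = FALSE)), 1L)
  if ("GT" %in% record@formatKeys && record@formatKeys[1] != "GT")
    v <- c(v, "GT is present but not the first FORMAT key")
  for (k in record@formatKeys) {
    def <- .fieldDef(header, "FORMAT", k)
    if (is.null(def)) {
      v <- c(v, sprintf("FORMAT tag '%s' is not declared in the header", k))
      next
    }
    if (k == "GT") next
    exp <- .expectedCount(def$number, nAllele, ploidy)
    if (!is.na(exp)) {
      vals <- formatValues(record, k, header)
      nv <- lengths(vals)
      miss <- vapply(vals, function(x) all(is.na(x)), logical(1))
      if (any(!miss & nv != exp))
        v <- c(v, sprintf(
          "FORMAT '%s' has a sample with %d value(s); Number=%s implies %d",
          k, nv[!miss & nv != exp][1], def$number, exp))
    }
  }
  v
}
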