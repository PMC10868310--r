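# VCF header parsing, serialization and mutation.
#
# The header is "too important to be ignored": every INFO/FORMAT/FILTER tag
# used in the body must be declared here, and the declarations double as
# the string dictionary of the binary codec.  Dictionary index assignment
# follows the binary convention: PASS is always 0; remaining ids get dense
# indices in order of first declaration across the FILTER/INFO/FORMAT
# sections (an id declared in several sections shares one index).
# Explicit IDX= attributes, when present, are honored instead — mixing
# explicit and implicit assignment is an error.

.VALID_TYPES <- c("Integer", "Float", "String", "Character", "Flag")

## tokenize the inside of ##TAG=<...>: key=value pairs, values possibly
## quoted (quotes may contain commas and escaped quotes)
.parseStructured <- function(body) {
  pat <- '([A-Za-z0-9_.]+)=("(?:[^"\\\\]|\\\\.)*"|[^,]*)'
  m <- regmatches(body, gregexpr(pat, body, perl = TRUE))[[1]]
  keys <- sub("=.*$", "", m)
  vals <- sub("^[^=]*=", "", m)
  q <- startsWith(vals, '"')
  vals[q] <- gsub('\\\\(["\\\\])', "\\1",
                  substr(vals[q], 2L, nchar(vals[q]) - 1L))
  names(vals) <- keys
  vals
}

.quoteDesc <- function(x) paste0('"', gsub('(["\\\\])', "\\\\\\1", x), '"')

#' Parse a VCF header
#'
#' Consumes the meta-information lines (each starting \code{##}) and the
#' single column line (starting \code{#CHROM}).  All INFO/FORMAT/FILTER and
#' contig declarations are captured into field-definition tables; sample
#' names are the columns after FORMAT on the column line.  A missing
#' \code{##fileformat} line yields a warning and the default
#' \code{"VCFv4.2"}; a duplicated id within a section is an error, as is a
#' missing column line.
#'
#' @param lines character vector of header lines, in file order.
#' @return a \linkS4class{VcfHeader}.
#' @seealso [formatVcfHeader()], [headerAdd()], [headerRemove()]
#' @export
parseVcfHeader <- function(lines) {
  chromLn <- which(startsWith(lines, "#CHROM"))
  if (length(chromLn) != 1L)
    vsError("header lacks the mandatory #CHROM column line", "vcf_header")
  meta <- lines[seq_len(chromLn - 1L)]
  if (!all(startsWith(meta, "##")))
    vsError("meta lines before #CHROM must start with '##'", "vcf_header")

  fileformat <- sub("^##fileformat=", "", grep("^##fileformat=", meta,
                                               value = TRUE))
  if (length(fileformat) == 0L) {
    warning("no ##fileformat line; assuming VCFv4.2")
    fileformat <- "VCFv4.2"
  } else fileformat <- fileformat[1]

  defs <- list(INFO = .emptyFieldDefs(), FORMAT = .emptyFieldDefs(),
               FILTER = .emptyFieldDefs())
  contigs <- data.frame(id = character(), length = numeric(),
                        idx = numeric(), stringsAsFactors = FALSE)
  extra <- character()
  explicitIdx <- logical(0)  # one flag per structured line seen

  for (ln in meta) {
    m <- regmatches(ln, regexec("^##(INFO|FORMAT|FILTER|contig)=<(.*)>$",
                                ln))[[1]]
    if (length(m) == 3L) {
      sec <- m[2]; kv <- .parseStructured(m[3])
      id <- kv[["ID"]]
      if (is.null(id)) vsError(sprintf("declaration without ID: %s", ln),
                               "vcf_header")
      hasIdx <- "IDX" %in% names(kv)
      explicitIdx <- c(explicitIdx, hasIdx)
      idx <- if (hasIdx) as.numeric(kv[["IDX"]]) else NA_real_
      if (sec == "contig") {
        if (id %in% contigs$id)
          vsError(sprintf("duplicate contig declaration: %s", id),
                  "vcf_duplicate")
        len <- if ("length" %in% names(kv)) as.numeric(kv[["length"]])
               else NA_real_
        contigs <- rbind(contigs, data.frame(id = id, length = len,
                                             idx = idx))
      } else {
        d <- defs[[sec]]
        if (id %in% d$id)
          vsError(sprintf("duplicate %s declaration: %s", sec, id),
                  "vcf_duplicate")
        number <- if (sec == "FILTER") "." else kv[["Number"]]
        type <- if (sec == "FILTER") "String" else kv[["Type"]]
        if (sec != "FILTER" && (is.null(number) || is.null(type)))
          vsError(sprintf("%s %s lacks Number/Type", sec, id), "vcf_header")
        if (sec != "FILTER" && !type %in% .VALID_TYPES)
          vsError(sprintf("%s %s has invalid Type '%s'", sec, id, type),
                  "vcf_header")
        if (sec != "FILTER" && type == "Flag" && number != "0") {
          warning(sprintf("Flag field %s must have Number=0; coercing", id))
          number <- "0"
        }
        desc <- if ("Description" %in% names(kv)) kv[["Description"]] else ""
        defs[[sec]] <- rbind(d, data.frame(id = id, number = number,
                                           type = type, description = desc,
                                           idx = idx))
      }
    } else if (!startsWith(ln, "##fileformat=")) {
      extra <- c(extra, ln)
    }
  }

  ## column line -> samples
  cols <- strsplit(lines[chromLn], "\t", fixed = TRUE)[[1]]
  fixed <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(cols) < 8L || !identical(cols[1:8], fixed))
    vsError("malformed #CHROM column line", "vcf_header")
  samples <- if (length(cols) > 9L) cols[10:length(cols)]
             else character()
  if (length(cols) == 9L && cols[9] != "FORMAT")
    vsError("ninth column must be FORMAT", "vcf_header")
  if (length(cols) > 9L && cols[9] != "FORMAT")
    vsError("ninth column must be FORMAT when samples are present",
            "vcf_header")
  if (anyDuplicated(samples))
    vsError("duplicate sample names", "vcf_duplicate")

  hdr <- new("VcfHeader", fileformat = fileformat, contigs = contigs,
             infos = defs$INFO, formats = defs$FORMAT,
             filters = defs$FILTER, samples = samples, extra = extra)
  .assignDictionary(hdr, explicitIdx)
}

## Assign dictionary indices (PASS = 0; dense, declaration order) unless
## every structured line carried an explicit IDX.
.assignDictionary <- function(hdr, explicitFlags = logical(0)) {
  nExpl <- sum(explicitFlags)
  if (nExpl > 0 && nExpl < length(explicitFlags))
    vsError("mixed explicit and implicit IDX= in header", "vcf_header")
  explicit <- nExpl > 0 && nExpl == length(explicitFlags)
  if (explicit) {
    ## honor IDX as given; contigs keep theirs too
    return(hdr)
  }
  dict <- "PASS"
  assign1 <- function(ids) {
    for (id in ids) if (!id %in% dict) dict <<- c(dict, id)
  }
  ## order of first declaration across sections; we do not retain global
  ## interleaving of the original lines, so use FILTER, INFO, FORMAT order
  ## matched by the serializer (idx-sorted emission keeps round trips
  ## stable)
  assign1(hdr@filters$id); assign1(hdr@infos$id); assign1(hdr@formats$id)
  lku <- function(ids) as.numeric(match(ids, dict) - 1L)
  hdr@filters$idx <- lku(hdr@filters$id)
  hdr@infos$idx   <- lku(hdr@infos$id)
  hdr@formats$idx <- lku(hdr@formats$id)
  if (nrow(hdr@contigs)) hdr@contigs$idx <- seq_len(nrow(hdr@contigs)) - 1
  hdr
}

## the full string dictionary, idx -> id (may be sparse after removals)
.headerDict <- function(hdr) {
  ids <- c("PASS", hdr@filters$id, hdr@infos$id, hdr@formats$id)
  idx <- c(0, hdr@filters$idx, hdr@infos$idx, hdr@formats$idx)
  keep <- !duplicated(ids)
  ids <- ids[keep]; idx <- idx[keep]
  d <- character(max(idx) + 1L)
  d[idx + 1L] <- ids
  d
}

#' Serialize a VCF header to text lines
#'
#' Declarations are emitted in dictionary order (so that re-parsing with
#' implicit index assignment reproduces the same dictionary), followed by
#' contigs, preserved extra lines, and the column line.
#'
#' @param header a \linkS4class{VcfHeader}.
#' @param withIdx also emit \code{IDX=} attributes (used for BCF header
#'   text).
#' @return character vector of lines.
#' @export
formatVcfHeader <- function(header, withIdx = FALSE) {
  out <- paste0("##fileformat=", header@fileformat)
  ix <- function(i) if (withIdx) sprintf(",IDX=%d", as.integer(i)) else ""
  ## ensure PASS is written (it is always defined, explicitly or not)
  flt <- header@filters
  if (!"PASS" %in% flt$id)
    flt <- rbind(data.frame(id = "PASS", number = ".", type = "String",
                            description = "All filters passed", idx = 0),
                 flt)
  secs <- rbind(cbind(flt, sec = "FILTER"),
                if (nrow(header@infos))
                  cbind(header@infos, sec = "INFO"),
                if (nrow(header@formats))
                  cbind(header@formats, sec = "FORMAT"))
  secs <- secs[order(secs$idx, match(secs$sec,
                                     c("FILTER", "INFO", "FORMAT"))), ,
               drop = FALSE]
  for (k in seq_len(nrow(secs))) {
    s <- secs[k, ]
    out <- c(out, if (s$sec == "FILTER")
      sprintf("##FILTER=<ID=%s,Description=%s%s>", s$id,
              .quoteDesc(s$description), ix(s$idx))
    else
      sprintf("##%s=<ID=%s,Number=%s,Type=%s,Description=%s%s>", s$sec,
              s$id, s$number, s$type, .quoteDesc(s$description), ix(s$idx)))
  }
  if (nrow(header@contigs)) {
    ctg <- header@contigs[order(header@contigs$idx), , drop = FALSE]
    out <- c(out, ifelse(is.na(ctg$length),
                         sprintf("##contig=<ID=%s%s>", ctg$id,
                                 vapply(ctg$idx, ix, "")),
                         sprintf("##contig=<ID=%s,length=%d%s>", ctg$id,
                                 as.integer(ctg$length),
                                 vapply(ctg$idx, ix, ""))))
  }
  out <- c(out, header@extra)
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(header@samples))
    cols <- c(cols, "FORMAT", header@samples)
  c(out, paste(cols, collapse = "\t"))
}

#' Modify a VCF header
#'
#' \code{headerAdd} inserts a new contig, INFO, FORMAT, FILTER or sample
#' declaration; \code{headerRemove} deletes one.  Dictionary indices of
#' untouched entries are preserved: additions take the next free index,
#' removals leave a hole rather than renumbering.  Adding an existing id or
#' removing an absent one is an error; removing an id still used by records
#' supplied via \code{inUse} warns.
#'
#' @param header a \linkS4class{VcfHeader}.
#' @param section one of \code{"contig"}, \code{"INFO"}, \code{"FORMAT"},
#'   \code{"FILTER"}, \code{"sample"}.
#' @param id the declaration id (or sample name).
#' @param number,type,description field attributes (ignored for contigs,
#'   filters and samples; filters take \code{description} only).
#' @param length contig length for \code{section = "contig"}.
#' @return the modified \linkS4class{VcfHeader}.
#' @export
headerAdd <- function(header, section, id, number = "1", type = "String",
                      description = "", length = NA_real_) {
  section <- match.arg(section, c("contig", "INFO", "FORMAT", "FILTER",
                                  "sample"))
  if (section == "sample") {
    if (id %in% header@samples)
      vsError(sprintf("sample '%s' already present", id), "vcf_duplicate")
    header@samples <- c(header@samples, id)
    return(header)
  }
  if (section == "contig") {
    if (id %in% header@contigs$id)
      vsError(sprintf("contig '%s' already declared", id), "vcf_duplicate")
    nidx <- if (nrow(header@contigs)) max(header@contigs$idx) + 1 else 0
    header@contigs <- rbind(header@contigs,
                            data.frame(id = id, length = length,
                                       idx = nidx))
    return(header)
  }
  slotName <- c(INFO = "infos", FORMAT = "formats", FILTER = "filters")[
    section]
  d <- slot(header, slotName)
  if (id %in% d$id)
    vsError(sprintf("%s '%s' already declared", section, id),
            "vcf_duplicate")
  dict <- .headerDict(header)
  idx <- if (id %in% dict) match(id, dict) - 1L else base::length(dict)
  if (section == "FILTER") { number <- "."; type <- "String" }
  if (type == "Flag") number <- "0"
  slot(header, slotName) <- rbind(d, data.frame(
    id = id, number = as.character(number), type = type,
    description = description, idx = as.numeric(idx)))
  validObject(header)
  header
}

#' @rdname headerAdd
#' @param inUse optional list of \linkS4class{VcfRecord}s to check before
#'   removal; a removed id still referenced by one of them triggers a
#'   warning.
#' @export
headerRemove <- function(header, section, id, inUse = NULL) {
  section <- match.arg(section, c("contig", "INFO", "FORMAT", "FILTER",
                                  "sample"))
  if (section == "sample") {
    if (!id %in% header@samples)
      vsError(sprintf("sample '%s' not present", id), "vcf_absent")
    header@samples <- setdiff(header@samples, id)
    return(header)
  }
  if (section == "contig") {
    if (!id %in% header@contigs$id)
      vsError(sprintf("contig '%s' not declared", id), "vcf_absent")
    header@contigs <- header@contigs[header@contigs$id != id, ,
                                     drop = FALSE]
    return(header)
  }
  slotName <- c(INFO = "infos", FORMAT = "formats", FILTER = "filters")[
    section]
  d <- slot(header, slotName)
  if (!id %in% d$id)
    vsError(sprintf("%s '%s' not declared", section, id), "vcf_absent")
  if (!is.null(inUse)) {
    used <- vapply(inUse, function(rec) {
      switch(section,
             INFO = id %in% names(rec@info),
             FORMAT = id %in% rec@formatKeys,
             FILTER = id %in% rec@filter)
    }, logical(1))
    if (any(used))
      warning(sprintf("%s '%s' is still used by %d held record(s)",
                      section, id, sum(used)))
  }
  slot(header, slotName) <- d[d$id != id, , drop = FALSE]
  header
}

#' @describeIn VcfHeader-class sample names declared on the column line
#' @export
setMethod("vcfSamples", "VcfHeader", function(x) x@samples)

setMethod("show", "VcfHeader", function(object) {
  cat(sprintf(
    "VcfHeader (%s): %d contig(s), %d INFO, %d FORMAT, %d FILTER, %d sample(s)\n",
    object@fileformat, nrow(object@contigs), nrow(object@infos),
    nrow(object@formats), nrow(object@filters), length(object@samples)))
  if (length(object@samples))
    cat("  samples:", paste(utils::head(object@samples, 8), collapse = ", "),
        if (length(object@samples) > 8) "..." else "", "\n")
})

## field definition lookup helpers
.fieldDef <- function(header, section, id) {
  d <- slot(header, c(INFO = "infos", FORMAT = "formats",
                      FILTER = "filters")[section])
  i <- match(id, d$id)
  if (is.na(i)) NULL else d[i, ]
}
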