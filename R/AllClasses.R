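#' @import methods
NULL

## ---------------------------------------------------------------------------
## Header
## ---------------------------------------------------------------------------

#' VcfHeader: declarations, samples, and the shared string dictionary
#'
#' Holds the meta-information section of a VCF/BCF: the \code{##fileformat}
#' version, contig declarations, the INFO/FORMAT/FILTER field definitions,
#' the ordered sample list, and any other \code{##} lines preserved verbatim.
#'
#' Field definitions are stored as data frames with columns \code{id},
#' \code{number} (one of a non-negative integer, \code{"A"}, \code{"R"},
#' \code{"G"}, \code{"."}), \code{type} (Integer, Float, String, Character,
#' Flag), \code{description} and \code{idx}.  The \code{idx} column is the
#' position in the string dictionary shared by the text and binary codecs:
#' \code{PASS} is always index 0, and an id used in more than one section
#' (say \code{DP} as both INFO and FORMAT) occupies a single dictionary slot,
#' as the binary encoding requires.  Contigs carry their own dictionary.
#'
#' @slot fileformat character(1), e.g. \code{"VCFv4.2"}.
#' @slot contigs data.frame with columns \code{id}, \code{length} (NA when
#'   undeclared) and \code{idx}.
#' @slot infos,formats,filters field-definition data frames (see above).
#' @slot samples character vector of unique sample names (possibly empty).
#' @slot extra character vector of other \code{##} lines, kept verbatim.
#' @aliases VcfHeader
#' @exportClass VcfHeader
setClass("VcfHeader",
  representation(
    fileformat = "character",
    contigs    = "data.frame",
    infos      = "data.frame",
    formats    = "data.frame",
    filters    = "data.frame",
    samples    = "character",
    extra      = "character"
  ),
  prototype(fileformat = "VCFv4.2",
            contigs = data.frame(id = character(), length = numeric(),
                                 idx = numeric()),
            samples = character(), extra = character())
)

.emptyFieldDefs <- function() {
  data.frame(id = character(), number = character(), type = character(),
             description = character(), idx = numeric(),
             stringsAsFactors = FALSE)
}

setValidity("VcfHeader", function(object) {
  msg <- character()
  if (anyDuplicated(object@samples))
    msg <- c(msg, "sample names must be unique")
  for (sec in c("infos", "formats", "filters", "contigs")) {
    d <- slot(object, sec)
    if (anyDuplicated(d$id))
      msg <- c(msg, sprintf("duplicate id within %s", sec))
  }
  flg <- object@infos$type == "Flag" & object@infos$number != "0"
  if (any(flg))
    msg <- c(msg, "Flag fields must declare Number=0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Record
## ---------------------------------------------------------------------------

#' VcfRecord: one variant site
#'
#' One body line of a VCF (equivalently one BCF record block): the fixed
#' site fields, the typed INFO map, and the per-sample FORMAT block.
#'
#' Missing values follow VCF conventions: \code{id} and \code{filter} are
#' \code{NA} for \code{"."}; \code{qual} is \code{NA_real_} for \code{"."}
#' (distinct from 0); \code{alt} has length 0 for a site with no alternate
#' allele.  \code{filter} is \code{NA_character_} when no filter was applied
#' — deliberately distinct from \code{"PASS"}.
#'
#' The per-sample block is stored in one of two interchangeable forms:
#' \code{sampleRaw}, the raw colon-joined strings as read from text (parsed
#' into typed values on demand by \code{\link{formatValues}}), or
#' \code{sampleData}, a list keyed by FORMAT id holding one typed value
#' vector per sample (the form produced by the BCF decoder).  Accessors
#' consult whichever is populated, so streaming readers never pay for
#' fields a caller does not touch.
#'
#' @slot chrom,ref character(1).
#' @slot pos numeric(1), 1-based.
#' @slot id character(1) or NA.
#' @slot alt character vector of alternate alleles (may be symbolic
#'   \code{"<...>"}).
#' @slot qual numeric(1) or NA.
#' @slot filter character vector of filter ids, or \code{NA_character_}.
#' @slot info named list of typed INFO values (\code{TRUE} for flags).
#' @slot formatKeys ordered character vector of FORMAT ids (GT first when
#'   present).
#' @slot sampleRaw character vector, one colon-joined string per sample.
#' @slot sampleData named list: FORMAT id -> list of per-sample typed values.
#' @slot nSamples integer(1).
#' @aliases VcfRecord
#' @exportClass VcfRecord
setClass("VcfRecord",
  representation(
    chrom = "character", pos = "numeric", id = "character",
    ref = "character", alt = "character", qual = "numeric",
    filter = "character", info = "list",
    formatKeys = "character", sampleRaw = "character",
    sampleData = "list", nSamples = "integer"
  ),
  prototype(id = NA_character_, alt = character(), qual = NA_real_,
            filter = NA_character_, info = list(),
            formatKeys = character(), sampleRaw = character(),
            sampleData = list(), nSamples = 0L)
)

setValidity("VcfRecord", function(object) {
  msg <- character()
  if (length(object@pos) != 1L || is.na(object@pos) || object@pos < 1)
    msg <- c(msg, "pos must be a single 1-based coordinate")
  if (!is.na(object@qual) && object@qual < 0)
    msg <- c(msg, "qual must be non-negative or missing")
  if (length(object@sampleRaw) &&
      length(object@sampleRaw) != object@nSamples)
    msg <- c(msg, "sampleRaw length disagrees with nSamples")
  if (length(msg)) msg else TRUE
})

#' Genotype: one sample's call at one site
#'
#' @slot alleles integer vector of allele indices (0 = REF), \code{NA} for a
#'   missing allele.
#' @slot phased logical vector of length \code{ploidy - 1}, one per
#'   separator in the GT string (\code{TRUE} for \code{"|"}).
#' @slot ploidy integer(1) >= 1.
#' @aliases Genotype
#' @exportClass Genotype
setClass("Genotype",
  representation(alleles = "integer", phased = "logical",
                 ploidy = "integer"),
  validity = function(object) {
    if (object@ploidy != length(object@alleles))
      "ploidy must equal the number of alleles"
    else if (length(object@phased) != max(0L, object@ploidy - 1L))
      "phased must have one entry per allele separator"
    else TRUE
  }
)

## ---------------------------------------------------------------------------
## Index
## ---------------------------------------------------------------------------

#' TabixIndex: binned interval index over a BGZF-compressed VCF
#'
#' Per contig, a mapping of bins (5-level hierarchical binning of a 2^29-bp
#' range) to chunks of virtual offsets, plus a linear index of the lowest
#' record start per 16384-bp window.  Serializes to/from the \code{.tbi}
#' format (VCF preset).
#'
#' @slot contigs ordered character vector of indexed contig names.
#' @slot chunks list (one per contig) of data.frames with columns
#'   \code{bin}, \code{beg}, \code{end} (virtual offsets).
#' @slot linear list (one per contig) of numeric virtual-offset vectors.
#' @slot meta list with the tabix preset numbers (\code{format},
#'   \code{col_seq}, \code{col_beg}, \code{col_end}, \code{meta},
#'   \code{skip}).
#' @slot nNoCoor numeric(1), count of unmapped records (NA when absent).
#' @aliases TabixIndex
#' @exportClass TabixIndex
setClass("TabixIndex",
  representation(contigs = "character", chunks = "list", linear = "list",
                 meta = "list", nNoCoor = "numeric"),
  prototype(meta = list(format = 2, col_seq = 1, col_beg = 2, col_end = 0,
                        meta = "#", skip = 0),
            nNoCoor = NA_real_)
)

setValidity("TabixIndex", function(object) {
  msg <- character()
  if (length(object@chunks) != length(object@contigs) ||
      length(object@linear) != length(object@contigs))
    msg <- c(msg, "chunks/linear must have one entry per contig")
  for (i in seq_along(object@chunks)) {
    d <- object@chunks[[i]]
    if (nrow(d) && any(d$bin < 0 | d$bin > 37448))
      msg <- c(msg, "bin ids must lie in [0, 37448]")
    if (nrow(d) && any(d$beg >= d$end))
      msg <- c(msg, "each chunk must satisfy beg < end")
    lin <- object@linear[[i]]
    if (length(lin) && is.unsorted(lin))
      msg <- c(msg, "linear offsets must be non-decreasing")
  }
  if (length(msg)) msg else TRUE
})

#' Region: a genomic query interval
#'
#' 1-based, fully closed, following the samtools convention used by region
#' strings ("chr", "chr:beg", "chr:beg-end").  Conversion to the 0-based
#' half-open arithmetic of the index happens exactly once, at query time.
#'
#' @slot contig character(1).
#' @slot start,end numeric(1), 1-based inclusive; \code{end = Inf} when the
#'   region extends to the contig end.
#' @aliases Region
#' @exportClass Region
setClass("Region",
  representation(contig = "character", start = "numeric", end = "numeric"),
  validity = function(object) {
    if (is.na(object@start) || object@start < 1) "start must be >= 1"
    else if (!is.na(object@end) && object@end < object@start)
      "end must be >= start"
    else TRUE
  }
)

## ---------------------------------------------------------------------------
## Streams (reference semantics via an environment slot)
## ---------------------------------------------------------------------------

#' VcfReader: streaming access to VCF/BCF in any supported encoding
#'
#' Created by \code{\link{openVcf}}.  Holds the parsed header plus mutable
#' stream state (one decompressed BGZF block and at most one surfaced
#' record) in an environment, giving the object reference semantics like a
#' connection.
#'
#' @slot state environment with the open stream, region/sample constraints,
#'   and the one-record buffer.
#' @aliases VcfReader
#' @exportClass VcfReader
setClass("VcfReader", representation(state = "environment"))

#' VcfWriter: streaming VCF/BCF output
#'
#' Created by \code{\link{openVcfWriter}}.  See \code{VcfReader} for the
#' reference-semantics rationale.
#'
#' @slot state environment holding the sink and pending BGZF buffer.
#' @aliases VcfWriter
#' @exportClass VcfWriter
setClass("VcfWriter", representation(state = "environment"))

## ---------------------------------------------------------------------------
## Analysis products
## ---------------------------------------------------------------------------

#' VariantTable: site fields plus one FORMAT item as a matrix
#'
#' The two-step product of \code{\link{vcfTable}}: per-variant site columns
#' and a single FORMAT item laid out as a samples x variants matrix, typed
#' by the item's declaration (never character for numeric items).  The GT
#' item yields an integer allele array of dimension samples x variants x
#' max ploidy.
#'
#' @slot chrom,id,ref,alt,filter character vectors, one entry per variant
#'   kept (alt and filter are comma/semicolon-collapsed for display).
#' @slot pos,qual numeric vectors.
#' @slot info optional data.frame of INFO columns (zero columns when
#'   dropped).
#' @slot formatItem character(1), the extracted FORMAT id.
#' @slot values matrix (samples x variants) or 3-d array for GT/multi-value
#'   items.
#' @slot samples character vector of sample names (matrix row names).
#' @aliases VariantTable
#' @exportClass VariantTable
setClass("VariantTable",
  representation(chrom = "character", pos = "numeric", id = "character",
                 ref = "character", alt = "character", qual = "numeric",
                 filter = "character", info = "data.frame",
                 formatItem = "character", values = "ANY",
                 samples = "character"))

setValidity("VariantTable", function(object) {
  n <- length(object@pos)
  lens <- c(length(object@chrom), length(object@id), length(object@ref),
            length(object@alt), length(object@qual), length(object@filter))
  if (any(lens != n)) return("site columns must have equal length")
  d <- dim(object@values)
  if (!is.null(d) && length(d) >= 2 &&
      !(d[1] == length(object@samples) && d[2] == n))
    return("values must be a samples x variants matrix/array")
  TRUE
})

#' SummaryReport: per-sample and per-file variant summaries
#'
#' Produced by \code{\link{vcfSummary}}.  \code{perSample} holds one row per
#' sample with counters \code{SNP}, \code{INDEL}, \code{SV}, \code{MNP},
#' \code{OTHER}, \code{multiallelic} (a record is attributed to a sample
#' only when that sample carries at least one called non-reference allele),
#' plus genotype counters \code{het}, \code{homAlt} and \code{missing}.
#' \code{perFile} holds site-level totals of the same variant classes, and
#' \code{perContig} the record count per contig.
#'
#' @slot perSample data.frame, one row per sample.
#' @slot perFile named numeric vector of site-level totals.
#' @slot perContig named numeric vector of per-contig record counts.
#' @slot samples character vector.
#' @aliases SummaryReport
#' @exportClass SummaryReport
setClass("SummaryReport",
  representation(perSample = "data.frame", perFile = "numeric",
                 perContig = "numeric", samples = "character"))
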