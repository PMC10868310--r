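## Accessor generics.  Slot access from user code is deliberately avoided;
## these are the supported surface.

#' @export
setGeneric("chrom", function(x) standardGeneric("chrom"))
#' @export
setGeneric("pos", function(x) standardGeneric("pos"))
#' @export
setGeneric("ref", function(x) standardGeneric("ref"))
#' @export
setGeneric("alt", function(x) standardGeneric("alt"))
#' @export
setGeneric("qual", function(x) standardGeneric("qual"))
#' @export
setGeneric("filters", function(x) standardGeneric("filters"))
#' @export
setGeneric("vcfSamples", function(x) standardGeneric("vcfSamples"))
#' @export
setGeneric("vcfHeader", function(x) standardGeneric("vcfHeader"))
#' @export
setGeneric("infoValues", function(x, id) standardGeneric("infoValues"))
#' @export
setGeneric("formatKeys", function(x) standardGeneric("formatKeys"))

#' @export
setGeneric("readRecord", function(x, ...) standardGeneric("readRecord"))
#' @export
setGeneric("writeRecord", function(x, record, ...)
  standardGeneric("writeRecord"))

#' @export
setGeneric("isHet", function(x) standardGeneric("isHet"))
#' @export
setGeneric("classifyVariant", function(x) standardGeneric("classifyVariant"))
#' @export
setGeneric("genotypes", function(x, width = c("full-int", "small-int",
                                              "presence"))
  standardGeneric("genotypes"))
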