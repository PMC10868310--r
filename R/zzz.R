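#' VariantStream: streaming VCF/BCF toolkit
#'
#' A self-contained implementation of the variant-call-format stack: BGZF
#' block compression with virtual-offset random access, tabix-style
#' interval indexing, VCF text and BCF2 binary codecs, a streaming
#' reader/writer pair, and genotype analysis operations (per-sample
#' heterozygosity, single-FORMAT-item tables, variant summaries), plus a
#' deterministic synthetic-VCF generator with planted ground truth.
#'
#' Start with \code{\link{openVcf}} / \code{\link{readRecord}} for
#' streaming access, \code{\link{vcfTable}} for the two-step tabular
#' strategy, and \code{\link{simulateVcf}} for test data.
#'
#' @name VariantStream-package
#' @aliases VariantStream
#' @useDynLib VariantStream, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @keywords internal
"_PACKAGE"
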