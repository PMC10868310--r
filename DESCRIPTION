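Package: VariantStream
Title: Streaming VCF/BCF Toolkit with BGZF Compression and Tabix Indexing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A self-contained toolkit for the variant call format: BGZF
    block compression with virtual-offset random access, tabix-style
    interval indexing (.tbi), VCF text and BCF2 binary codecs, a streaming
    reader/writer object model, and analysis operations on genotype data
    (per-sample heterozygosity counting, single-FORMAT-item table
    extraction, and per-sample variant summaries). Every format layer is
    implemented from its published specification; a deterministic
    synthetic-VCF generator with planted ground truth makes the whole
    stack testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
SystemRequirements: zlib
Config/testthat/edition: 3
biocViews: VariantAnnotation, DataImport, Genetics, Software
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'bgzf.R'
    'tabix.R'
    'vcf-header.R'
    'vcf-record.R'
    'bcf.R'
    'io.R'
    'variant-ops.R'
    'fixtures.R'
    'cli.R'
    'zzz.R'
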