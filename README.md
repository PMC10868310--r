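# VariantStream

A self-contained R toolkit for the variant call format, written for
developers and analysts who need full control over VCF/BCF I/O without an
external C library: every format layer — BGZF block compression with
virtual-offset random access, tabix-style interval indexing (`.tbi`), the
VCF text grammar, and the BCF2.2 binary encoding — is implemented from its
published specification in this package, with the reference tools
(`bgzip`, `tabix`, `bcftools`) used only as independent oracles in the
test suite.

On top of the format stack sits a streaming object model and the three
analysis operations common to population-genetic quality control:

* **`countHets()`** — per-sample heterozygosity. A diploid genotype is
  heterozygous when both alleles are called and their indices differ
  (`0/1`, `1|0`, and the multiallelic `1/2` count; `./1`, haploid and
  polyploid calls never do). The default site filters mirror the canonical
  counting loop for this task: keep SNPs only, require `PASS` in FILTER,
  and drop records with QUAL < 9 (missing QUAL always fails).
* **`vcfTable()` / `twoStepLoad()`** — one FORMAT item per pass over the
  file, returned as a *typed* samples × variants matrix (integer or
  numeric, never character; `GT` yields an integer allele array of
  dimension samples × variants × ploidy). The two entry points implement
  the streaming and load-then-shape strategies; their equivalence is a
  tested contract, and requesting two items in one pass is a documented
  error.
* **`vcfSummary()`** — per-file and per-sample variant-class counters
  (SNP/INDEL/SV/MNP, multiallelic, het/hom-alt/missing) from a single
  streaming pass; a record is attributed to a sample only when that
  sample carries a called non-reference allele.

Readers hold one decompressed BGZF block and at most one decoded record
at a time, so memory use is independent of file size. Region queries go
through the binned index on compressed text (built on the fly when no
`.tbi` sidecar exists) and through the identical overlap predicate on
plain text and BCF, so results never depend on the access path. A
deterministic generator, `simulateVcf()`, plants ground truth (genotypes,
read depths, class mix, filter/QUAL laws) so the whole stack is testable
without external data.

## Worked example

```r
library(VariantStream)

fx  <- simulateVcf(seed = 7, nSamples = 3, nVariants = 500)
vcf <- tempfile(fileext = ".vcf"); writeLines(fx$lines, vcf)
gz  <- sub(".vcf$", ".vcf.gz", vcf)
convertVcf(vcf, gz, "vcf-bgzf")                 # BGZF-compress
writeTabix(buildTabixIndex(gz), paste0(gz, ".tbi"))

countHets(gz)
#> S001 S002 S003
#>   52   51   52
fx$truth$hets$snp1_pass1_q9                     # planted truth
#> S001 S002 S003
#>   52   51   52
```

The counts are the number of records per sample that survive the default
filters (SNP, PASS, QUAL ≥ 9) *and* carry a heterozygous genotype — here
recovered exactly from the planted truth table.

```r
r <- openVcf(gz, region = "chr21:1-20,000,000", samples = "S003,S001")
readRecord(r)
#> VcfRecord chr21:533797 T>C qual=32.4 [2 sample(s)]
close(r)

tb <- vcfTable(gz, formatItem = "DP", snpOnly = TRUE, passOnly = TRUE,
               minQual = 9, dropInfo = TRUE)
tb
#> VariantTable: 181 variant(s) x 3 sample(s), item DP (matrix/array)
tableValues(tb)[, 1:5]
#>      [,1] [,2] [,3] [,4] [,5]
#> S001   32   22   26   27   35
#> S002   35   37   27   31   19
#> S003   33   30   19   30   34

vcfSummary(gz)
#> SummaryReport
#>   records: 500 over 3 contig(s)
#>   site classes: SNP=300 INDEL=125 SV=50 MNP=25 OTHER=0 multiallelic=67
```

The DP matrix is integer-typed, ready for arithmetic without conversion;
the 181 columns are exactly the variants passing the SNP/PASS/QUAL
filters.

A command-line wrapper is installed as `exec/variantstream` inside the
package (subcommands `view`, `index`, `table`, `summary`, `hets`,
`synth`); `Rscript -e 'VariantStream::vcfCli(c("hets", "file.vcf.gz"))'`
is equivalent.

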