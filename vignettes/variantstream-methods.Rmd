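---
title: "VariantStream: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{VariantStream: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VariantStream)
```

VariantStream implements the variant-call-format stack from the byte
level up: blocked gzip (BGZF) with virtual-offset random access, the
tabix binned interval index, the VCF text grammar, the BCF2.2 binary
encoding, a streaming reader/writer pair, and the analysis operations a
genotype QC pass needs. This vignette records how each layer works, the
choices made where the design was genuinely open, what the synthetic
generator does and does not emulate, and the package's known limits.

## The format stack

### BGZF and virtual offsets

A BGZF stream is a concatenation of complete gzip members, each carrying
a two-byte `BC` extra subfield holding the member's total length minus
one. Because every member is an ordinary gzip member, any multi-member
gzip reader decompresses the stream linearly; the length field is what
allows a reader to jump to a block boundary and inflate just that block.
A position in the logical (uncompressed) stream is a *virtual offset*

$$v = c \cdot 2^{16} + u,$$

where $c$ is the file offset of the containing block's first compressed
byte and $u < 2^{16}$ the offset within its decompressed payload. Packed
offsets order lexicographically in $(c, u)$, so they are monotone along a
linear read. Offsets are held as R doubles, which represent integers
exactly to $2^{53}$; the largest coffset this can carry ($2^{37}$ bytes)
is far beyond the file sizes this package addresses.

Choices at this layer: payload per block is capped at 65,280 bytes, the
conservative bound that keeps the compressed member within $2^{16}$
bytes even for incompressible input; the deflate level defaults to 6
with level 0 producing stored blocks; the reader caches exactly one
decompressed block (newline positions within it are found once per
block, so line extraction is linear, not quadratic); the writer appends
the canonical 28-byte end-of-file marker exactly once at close. A
plain (non-blocked) gzip VCF is accepted for sequential reading through
a gzip connection but cannot be used for random access, which requires
block structure; region requests on such input fall back to a linear
scan with a notice.

### The tabix index

The index divides a $2^{29}$-bp range per contig into five nested bin
levels (one bin of $2^{29}$, 8 of $2^{26}$, 64 of $2^{23}$, 512 of
$2^{20}$, 4,096 of $2^{17}$, 32,768 of $2^{14}$; ids 0–37,448). Each
record files under the smallest bin containing its reference span, and
each bin maps to chunks — `[begin, end)` virtual-offset ranges. A linear
index stores the lowest record-start offset per 16,384-bp window; a
query prunes chunks ending before the linear bound of its start window,
coalesces chunks closer than $2^{16}$ virtual units (one whole block;
avoids pointless reseeks without changing results), and scans the
remainder with the overlap predicate.

The record span used for overlap is
$[\,\mathrm{POS}-1,\ \mathrm{POS}-1+\max(|\mathrm{REF}|,\ \mathrm{END}-\mathrm{POS}+1)\,)$,
so symbolic alleles (`<DEL>` etc.) cover their full INFO `END` extent.
This *span overlap* semantics (rather than matching by POS alone) was an
open point; it follows the index preset's column declaration and is
pinned by tests that place queries strictly inside a deletion's span.
Region strings are 1-based inclusive (the samtools convention);
conversion to the 0-based half-open internal arithmetic happens exactly
once, at the parse boundary, which is the only way to keep off-by-one
errors out of a two-convention codebase. Records with POS beyond
$2^{29}-1$ are an indexing error: that is the `.tbi` dialect's limit,
and the CSI dialect that lifts it is out of scope.

### VCF text and the BCF binary form

The header model stores field declarations as data frames and maintains
the string dictionary both codecs share: `PASS` is always index 0, and
an id declared in several sections (e.g. `DP` as INFO and FORMAT)
occupies one slot, as the binary form requires. When serializing, the
declarations are emitted in dictionary order so that re-parsing with
implicit index assignment reproduces the same dictionary — this is what
makes `parse ∘ format` an identity on headers. Explicit `IDX=`
attributes (written into BCF header text) are honored on read; mixing
explicit and implicit assignment is an error rather than a guess.

Missing-value semantics follow the format: QUAL `"."` is `NA`, distinct
from 0; FILTER `"."` means *no filter applied* and is deliberately not
`PASS` (so PASS-only filters reject it); `"."` in any value position is
`NA`. Floats print with `%g` (six significant digits), enough to invert
a value that has passed through the BCF float32 representation, which is
why text→BCF→text round trips reproduce the canonical text exactly on
QUALs written with one decimal.

BCF typed values pack a 4-bit count (15 escapes to a following typed
integer) with a 4-bit type code; integer vectors choose the smallest
width whose non-sentinel range holds every value, reserving the two
lowest values of each width for the *missing* and *end-of-vector*
sentinels (float32 uses two quiet-NaN patterns). Genotypes pack per
allele as $(a+1)\cdot 2 + \phi$ with $\phi$ the phase bit and $a=-1$ for
a missing allele; samples of lower ploidy are padded with end-of-vector.
Version 2.2 sentinels and magic are written; 2.1 input is read
best-effort with a warning. Output BCF is always BGZF-wrapped (the
common on-disk form); a raw body is still readable through the same
interface.

The per-sample block of a parsed text record is kept as the verbatim
colon-joined strings and split into typed values only when an accessor
asks for an item. A streaming pass that touches only GT (heterozygosity
counting) therefore never pays for DP/GQ parsing; this is the main
reason the 200-sample workloads below run in seconds.

### Validation

A tag used in the body without a header declaration violates the
format's contract. The validator reports rather than decides:
`validateRecord()` returns one violation per undeclared INFO/FORMAT/
FILTER id plus type and cardinality mismatches (`Number=A/R/G` checked
against allele count and ploidy). Readers run in advisory mode by
default — undeclared ids surface as warnings, since real-world files
violate the rule routinely — and in strict mode (`strict = TRUE`) any
violation, including cardinality breaks, aborts the read. The advisory
fast path checks declarations only; the full cardinality check would
force typed parsing of every sample field on every record, which is
exactly the cost the lazy sample block avoids.

## Analysis operations

`countHets()` applies three independent site filters before the per-
sample genotype test: SNP-only (via allele-structure classification),
PASS-only, and a QUAL threshold with default 9; a missing QUAL fails the
threshold at any level, the conservative reading. Heterozygosity is
allele inequality on a fully-called diploid genotype, so the
multiallelic pair `1/2` counts — the alternative (restricting to
REF/ALT pairs) would silently redefine heterozygosity at multiallelic
sites; callers who want it can drop multiallelic records first. Calls
with any missing allele are never heterozygous: a half-called `./1` is
not evidence of two distinct alleles.

`vcfTable()` extracts exactly one FORMAT item per pass — a structural
property of the single-pass column assembly, surfaced as a documented
error rather than silently doing two passes. Numeric items return typed
matrices (integer/double, never character, so downstream arithmetic
needs no conversion); GT returns raw allele indices as a
samples × variants × ploidy integer array with no multiallelic
splitting. `twoStepLoad()` is the load-then-shape strategy; both share
the shaping step, and their equality under every combination of region
and sample constraints is asserted by the suite rather than assumed.
Site filters are all off by default here (the table is an extraction
tool, not a QC gate), and the QUAL filter engages only when
`minQual > 0`.

`vcfSummary()`'s counter set is a documented choice, not a canonical
one: per-file class totals plus per-sample SNP/INDEL/SV/MNP/OTHER,
multiallelic, het, hom-alt and missing, where class counters attribute a
record to a sample only when that sample carries a called non-reference
allele — hom-ref carriers have not "found" the variant. For the
genotype-free case the per-sample block is skipped with a notice.

The "bool" genotype width question (is a 1-bit genotype a carrier flag
or a per-allele bit?) is resolved as *presence*: `genotypes(...,
"presence")` returns carrier flags (`allele > 0`), the quantity a
1-bit-per-genotype representation can actually hold. `small-int` uses
raw (1-byte) storage with `0xff` marking missing/padding, valid while
the record has ≤ 127 alleles; `full-int` is a plain integer matrix. The
`Genotype` objects are width-independent, and the widths are required by
test to agree after widening.

## The synthetic generator

`simulateVcf()` emulates the record structure the filters and counters
exercise: a class mix over SNP/INDEL/SV/MNP (default 60/25/10/5% —
dominated by SNPs with a realistic indel share and a small structural
fraction), 15% multiallelic sites among SNPs/indels, allele frequencies
from Beta(1, 3) (a typical low-frequency-skewed site spectrum),
5% genotype missingness, half the genotypes phased, QUAL uniform on
[0, 60] crossing the default threshold of 9, FILTER mixed
70% `PASS` / 10% `.` / 20% `q10`, and Poisson(30) read depths. Class
counts are exact at any n (largest-remainder apportionment, then a
seeded shuffle) rather than multinomial draws, so planted truth tables
are sharp; positions are drawn without replacement and sorted; a
haploid-sample fraction stresses mixed-ploidy handling. All randomness
flows from one seeded stream, and the caller's RNG state is restored.

What it does **not** emulate — linkage disequilibrium, population
structure, Hardy–Weinberg deviation, caller-specific error modes,
overlapping indel representation — bounds what green tests mean: they
demonstrate format-layer and counting correctness on structurally
realistic files, not statistical realism of the genotypes themselves.
The hand-built edge suite (`adversarialSuite()`) covers what sampling
will not reliably hit: mixed ploidy in one record, an all-missing GT
column, a symbolic deletion with `END`, a `1/2` heterozygote, missing
QUAL/FILTER, a deliberately undeclared tag, and an empty body.

## Verification

Each layer is checked against an oracle that does not share its code
path: BGZF streams against R's multi-member gzip reader and the frozen
28-byte EOF constant; binning against brute-force enumeration of all
37,449 bin spans; region queries against a full linear scan with the
overlap predicate, under both the package-built index and one written by
the reference tabix; the BCF codec against record-for-record agreement
with bcftools in both directions; heterozygote counts against truth
tables planted by construction and against a second, independent text
parser inside the test suite. The problem sizes — 1,000 random payloads,
10,000 random intervals, a 50,000-variant/3-contig fixture with 500
random regions, 200 samples × 10,000 variants under all eight filter
combinations — were chosen so the full suite exercises every layer at
meaningful scale while remaining a routine desk run.

## Limitations

No CSI index (coordinates beyond $2^{29}$), no remote/URL input, no
multi-file merge or on-the-fly sorting, no multithreaded block
compression, no lazy partial INFO decoding, and no plotting. Pedigree
and other structured meta lines beyond contig/INFO/FORMAT/FILTER are
preserved verbatim but not interpreted. The CLI reads `-` as standard
input only where sequential access suffices.
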