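# Low-level helpers shared across the format codecs.
#
# All multi-byte integers in BGZF, .tbi and BCF are little-endian.  64-bit
# quantities (virtual offsets, chunk bounds) are carried as R doubles: a
# double represents integers exactly up to 2^53, far beyond any file this
# package addresses (coffset < 2^37 for a 128 GiB file).

## classed error so callers/tests can distinguish failure modes
vsError <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "vsError", "error", "condition")))
}

vsNotice <- function(...) message(...)

## ---- little-endian readers over a raw vector (off is 0-based) ----

.u8  <- function(x, off) as.integer(x[off + 1L])

.u16 <- function(x, off) {
  as.integer(x[off + 1L]) + 256L * as.integer(x[off + 2L])
}

.u32 <- function(x, off) {
  as.double(as.integer(x[off + 1L])) +
    256 * as.integer(x[off + 2L]) +
    65536 * as.integer(x[off + 3L]) +
    16777216 * as.integer(x[off + 4L])
}

.i32 <- function(x, off) {
  readBin(x[(off + 1L):(off + 4L)], "integer", n = 1L, size = 4L,
          endian = "little")
}

.u64 <- function(x, off) {
  .u32(x, off) + 4294967296 * .u32(x, off + 4L)
}

## ---- little-endian writers -> raw ----

.putU16 <- function(v) as.raw(c(v %% 256, v %/% 256 %% 256))

.putU32 <- function(v) {
  as.raw(c(v %% 256, v %/% 256 %% 256, v %/% 65536 %% 256,
           v %/% 16777216 %% 256))
}

.putI32 <- function(v) writeBin(as.integer(v), raw(), size = 4L,
                                endian = "little")

.putU64 <- function(v) c(.putU32(v %% 4294967296), .putU32(v %/% 4294967296))

## vectorised u32 writer (for chunk lists)
.putU32v <- function(v) {
  m <- rbind(v %% 256, v %/% 256 %% 256, v %/% 65536 %% 256,
             v %/% 16777216 %% 256)
  as.raw(m)
}

.putU64v <- function(v) {
  lo <- v %% 4294967296
  hi <- v %/% 4294967296
  m <- rbind(lo %% 256, lo %/% 256 %% 256, lo %/% 65536 %% 256,
             lo %/% 16777216 %% 256,
             hi %% 256, hi %/% 256 %% 256, hi %/% 65536 %% 256,
             hi %/% 16777216 %% 256)
  as.raw(m)
}

## shortest-ish round-trip decimal for VCF text output: integers print bare,
## reals use %g (6 significant digits, enough to invert a float32)
.fmtNum <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- "."
  ok <- !is.na(x)
  whole <- ok & (x == trunc(x)) & abs(x) < 2^31
  out[whole] <- sprintf("%d", as.integer(x[whole]))
  rest <- ok & !whole
  out[rest] <- sprintf("%g", x[rest])
  out
}

## split "a,b,c" but map "." to empty/NA at the caller's discretion
.splitComma <- function(s) strsplit(s, ",", fixed = TRUE)

## last-value-carried-forward with a leading default
.locf <- function(v, lead = 0) {
  f <- !is.na(v)
  c(lead, v[f])[cumsum(f) + 1L]
}
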