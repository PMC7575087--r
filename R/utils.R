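# Internal helpers shared across modules.

# Derive a per-stage RNG seed from the master seed. Fixed multiplicative
# offsets keep each artifact (trees / synteny / expression / pipeline stages)
# on its own stream so adding a stage never perturbs another's output.
# Result stays inside the 32-bit signed integer range R requires.
stream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset) * 1000003) %% 2147483629)
}

# Numeric-aware chromosome ranking: "ssa2" sorts before "ssa11"; purely
# non-numeric names fall back to lexicographic order after numbered ones.
chr_rank <- function(chr) {
  num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", chr)))
  num[is.na(num)] <- Inf
  num
}

# TRUE when locus (chr1, start1) sorts before (chr2, start2) under the
# canonical pair ordering: numeric-aware chromosome, then start coordinate.
locus_before <- function(chr1, start1, chr2, start2) {
  r1 <- chr_rank(chr1)
  r2 <- chr_rank(chr2)
  ifelse(r1 != r2, r1 < r2,
    ifelse(chr1 != chr2, chr1 < chr2, start1 < start2)
  )
}

# All permutations of 1:n as an n! x n integer matrix, in lexicographic order.
all_permutations <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

# Geometric mean of strictly positive values.
geo_mean <- function(x) exp(mean(log(x)))

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

warnf <- function(fmt, ...) warn(sprintf(fmt, ...))
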