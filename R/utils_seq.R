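# Internal byte-level sequence helpers. Sequences are plain uppercase
# character scalars; these avoid per-character R objects on multi-Mb
# chromosomes.

.dna_bytes <- charToRaw("ACGT")
.n_byte <- charToRaw("N")

# Uniform random DNA of length n (no Ns).
random_dna <- function(n) {
  rawToChar(.dna_bytes[sample.int(4L, n, replace = TRUE)])
}

# Independent substitutions at the given per-base rate; Ns are left alone
# and substituted bases always change (uniform over the 3 alternatives).
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  r <- charToRaw(seq)
  n <- length(r)
  pos <- which(runif(n) < rate)
  if (length(pos) > 0) pos <- pos[r[pos] != .n_byte]
  if (length(pos) > 0) {
    code <- match(as.integer(r[pos]), as.integer(.dna_bytes)) - 1L
    code <- (code + sample.int(3L, length(pos), replace = TRUE)) %% 4L
    r[pos] <- .dna_bytes[code + 1L]
  }
  rawToChar(r)
}

# Substitute exactly `k` positions (deterministic count), returning the
# mutated sequence. Positions are 1-based; if supplied they are used as is.
mutate_fixed <- function(seq, k, positions = NULL) {
  r <- charToRaw(seq)
  if (is.null(positions)) {
    ok <- which(r != .n_byte)
    positions <- sample(ok, k)
  }
  code <- match(as.integer(r[positions]), as.integer(.dna_bytes)) - 1L
  code <- (code + sample.int(3L, length(positions), replace = TRUE)) %% 4L
  r[positions] <- .dna_bytes[code + 1L]
  rawToChar(r)
}

# Replace the 0-based half-open span [start, end) of seq with replacement
# (must have matching length unless allow_resize).
splice_span <- function(seq, start, end, replacement) {
  stopifnot(start >= 0, end <= nchar(seq), start < end)
  paste0(substring(seq, 1, start), replacement,
         substring(seq, end + 1, nchar(seq)))
}

# Hamming mismatch fraction between equal-length sequences.
mismatch_fraction <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  sum(ra != rb) / length(ra)
}
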