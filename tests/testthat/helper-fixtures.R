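# Shared fixtures, generated in code. Heavy panel fixtures are built once
# per test run and cached in this environment.

fixture_cache <- new.env(parent = emptyenv())

rand_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

mismatch_frac_str <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mean(charToRaw(a) != charToRaw(b))
}

# substitute the given 1-based positions of a sequence deterministically
sub_at <- function(seq, positions) {
  swap <- c(A = "C", C = "G", G = "T", T = "A")
  s <- strsplit(seq, "")[[1]]
  s[positions] <- swap[s[positions]]
  paste(s, collapse = "")
}

# a small mosaic panel reused by several haplotyping tests
small_panel <- function() {
  if (!is.null(fixture_cache$small_panel)) return(fixture_cache$small_panel)
  cfg <- panel_config(n_cultivars = 6, n_founders = 4, chrom_len = 3e5,
                      segment_len_mean = 6e4, scaffold_len_mean = 4e4,
                      seed = 42)
  fixture_cache$small_panel <- list(cfg = cfg, panel = simulate_panel(cfg))
  fixture_cache$small_panel
}

# naive, index-free presence oracle: fraction of a marker's canonical
# k-mers occurring anywhere in the cultivar sequence (either strand)
naive_presence <- function(marker, cultivar_seq, k, e) {
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    km <- substring(s, 1:(n - k + 1), k:n)
    km <- km[!grepl("N", km, fixed = TRUE)]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
    pmin(km, rc)
  }
  qk <- kmers_of(marker)
  if (length(qk) == 0) return(NA)
  ck <- unique(kmers_of(cultivar_seq))
  mean(qk %in% ck) >= e
}

# exhaustive edit-distance oracle via Biostrings::matchPattern with
# indels: smallest edit count in [0, max_d] at which the query matches
# the subject on either strand, or NA if none.
oracle_min_edits <- function(query, subject, max_d) {
  subj <- Biostrings::DNAString(subject)
  pats <- list(Biostrings::DNAString(query),
               Biostrings::reverseComplement(Biostrings::DNAString(query)))
  found_at <- function(d) {
    any(vapply(pats, function(p)
      length(Biostrings::matchPattern(p, subj, max.mismatch = d,
                                      with.indels = TRUE)) > 0,
      logical(1)))
  }
  if (!found_at(max_d)) return(NA_integer_)
  lo <- 0L; hi <- as.integer(max_d)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (found_at(mid)) hi <- mid else lo <- mid + 1L
  }
  lo
}

# naive Nxx/NGxx oracle: direct cumulative walk
oracle_nxx <- function(lengths, frac, total) {
  lens <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(lens)
  i <- which(cum >= frac * total)[1]
  if (is.na(i)) c(NA_real_, NA_real_) else c(lens[i], i)
}
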