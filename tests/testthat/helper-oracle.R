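# Independent brute-force oracle for the bisulfite-asymmetric alignment:
# enumerates every contiguous reference substring (the free reference end
# gaps) and scores all global alignments of the read against it by plain
# recursion. Deliberately structured differently from the package's dynamic
# program.

oracle_base_match <- function(r, b, rev) {
  if (b == r) {
    return(TRUE)
  }
  if (rev) r == "G" && b == "A" else r == "C" && b == "T"
}

oracle_global <- function(ref_chars, read_chars, rev, match, mismatch, gap) {
  m <- length(ref_chars)
  n <- length(read_chars)
  rec <- function(i, j) {
    if (i > m && j > n) {
      return(0L)
    }
    best <- -.Machine$integer.max
    if (i <= m && j <= n) {
      s <- if (oracle_base_match(ref_chars[i], read_chars[j], rev)) {
        match
      } else {
        mismatch
      }
      best <- max(best, s + rec(i + 1L, j + 1L))
    }
    if (i <= m) best <- max(best, gap + rec(i + 1L, j))
    if (j <= n) best <- max(best, gap + rec(i, j + 1L))
    best
  }
  rec(1L, 1L)
}

oracle_semiglobal <- function(read, ref, rev = FALSE, match = 1L,
                              mismatch = -1L, gap = -2L) {
  ref_chars <- strsplit(ref, "")[[1L]]
  read_chars <- strsplit(read, "")[[1L]]
  m <- length(ref_chars)
  best <- -.Machine$integer.max
  for (a in 1:(m + 1L)) {
    for (b in (a - 1L):m) {
      sub <- if (b >= a) ref_chars[a:b] else character(0L)
      best <- max(best, oracle_global(sub, read_chars, rev, match, mismatch, gap))
    }
  }
  best
}

random_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
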