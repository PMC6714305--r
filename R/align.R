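# Bisulfite-aware pairwise alignment (R surface over the compiled DP).

default_scoring <- function() list(match = 1L, mismatch = -1L, gap = -2L)

check_scoring <- function(scoring) {
  scoring <- modifyList(default_scoring(), as.list(scoring))
  if (!(scoring$match > 0 && scoring$mismatch < 0 && scoring$gap < 0)) {
    stop("scoring must satisfy match > 0 > mismatch and gap < 0",
      call. = FALSE
    )
  }
  lapply(scoring, as.integer)
}

#' Align one read against an amplicon reference, bisulfite-aware
#'
#' Global-in-read alignment against the unconverted reference, end-gap-free in
#' the reference, under bisulfite-asymmetric scoring: a reference C aligned to
#' a read T (expected conversion) or C (methylated or unconverted) scores as a
#' match, so methylation state never influences the score. Both orientations
#' are tried: bisulfite PCR amplifies the converted top strand only, so a
#' reverse read is the reverse complement of a converted-top-strand molecule
#' and is re-complemented before alignment under the same expectation
#' (equivalently, on the original read the expectation mirrors to reference
#' G ~ read A). The higher-scoring orientation is returned; ties break toward
#' forward. Within the dynamic program ties break diagonal > up > left.
#'
#' @param read Read sequence (non-empty character).
#' @param locus An [amplicon_locus()].
#' @param scoring List with `match` (> 0), `mismatch` (< 0), `gap` (< 0).
#'   Default `list(match = 1, mismatch = -1, gap = -2)`.
#' @return Object of class `BisAlignment`: `score`, `orientation`
#'   (`"forward"`/`"reverse"`), `ref_to_read` (1-based read position per
#'   reference position, `NA` where unaligned), `oriented_read` (the read as
#'   aligned, i.e. reverse-complemented for reverse orientation), `locus`.
#' @export
align_bisulfite <- function(read, locus, scoring = default_scoring()) {
  if (!is.character(read) || length(read) != 1L || nchar(read) == 0L) {
    stop("read must be one non-empty sequence", call. = FALSE)
  }
  sc <- check_scoring(scoring)
  ref <- locus$reference
  fwd <- .cpp_align_one(read, ref, FALSE, sc$match, sc$mismatch, sc$gap)
  rc <- revcomp(read)
  rev <- .cpp_align_one(rc, ref, FALSE, sc$match, sc$mismatch, sc$gap)
  use_rev <- rev$score > fwd$score
  aln <- if (use_rev) rev else fwd
  map <- aln$ref_to_read + 1L
  map[map == 0L] <- NA_integer_
  structure(
    list(
      score = aln$score,
      orientation = if (use_rev) "reverse" else "forward",
      ref_to_read = map,
      oriented_read = if (use_rev) rc else read,
      locus = locus$name
    ),
    class = "BisAlignment"
  )
}

#' @export
print.BisAlignment <- function(x, ...) {
  cat(sprintf(
    "BisAlignment to %s: score %d, %s orientation, %d/%d reference positions aligned\n",
    x$locus, x$score, x$orientation,
    sum(!is.na(x$ref_to_read)), length(x$ref_to_read)
  ))
  invisible(x)
}

#' Call the CpG methylation pattern of one aligned read
#'
#' For each CpG of the locus the aligned (top-strand-oriented) read base
#' becomes `M` (cytosine retained), `U` (converted to thymine) or `N` (gap or
#' other base); on a reverse read this mirrors to G -> M, A -> U of its
#' original bases. The per-read bisulfite conversion rate is the fraction of
#' aligned non-CpG reference cytosines read as converted; `aligned_fraction`
#' is the share of reference positions aligned to a read base.
#'
#' @param alignment A [align_bisulfite()] result.
#' @param locus The [amplicon_locus()] the read was aligned to.
#' @param read_id Read identifier carried into the pattern.
#' @return One-row data.frame (`ReadPattern`): `read_id`, `locus`,
#'   `orientation`, `calls` (string over `{M,U,N}`, one per CpG),
#'   `conversion_rate` (`NA` when no non-CpG C is aligned),
#'   `aligned_fraction`, `pass_qc` (`NA`, set by [filter_reads()]).
#' @export
call_read_pattern <- function(alignment, locus, read_id = "read") {
  stopifnot(inherits(alignment, "BisAlignment"),
    alignment$locus == locus$name
  )
  ref_len <- nchar(locus$reference)
  map <- alignment$ref_to_read
  read_chars <- str_chars(alignment$oriented_read)

  j <- map[locus$cpg_positions + 1L]
  base <- ifelse(is.na(j), NA_character_, read_chars[j])
  calls <- ifelse(is.na(base), "N",
    ifelse(base == "C", "M", ifelse(base == "T", "U", "N"))
  )

  jc <- map[locus$non_cpg_c_positions + 1L]
  aligned_c <- !is.na(jc)
  converted <- read_chars[jc[aligned_c]] == "T"
  conversion_rate <- if (sum(aligned_c) > 0L) {
    sum(converted) / sum(aligned_c)
  } else {
    NA_real_
  }

  data.frame(
    read_id = read_id,
    locus = locus$name,
    orientation = alignment$orientation,
    score = alignment$score,
    calls = paste0(calls, collapse = ""),
    conversion_rate = conversion_rate,
    aligned_fraction = sum(!is.na(map)) / ref_len,
    pass_qc = NA,
    stringsAsFactors = FALSE
  )
}

#' Align and call a batch of reads against one locus
#'
#' Batch equivalent of [align_bisulfite()] followed by
#' [call_read_pattern()], computed in compiled code.
#'
#' @param reads Named character vector of read sequences (names = read ids).
#' @param locus An [amplicon_locus()].
#' @param scoring See [align_bisulfite()].
#' @return data.frame of `ReadPattern` rows.
#' @export
call_reads <- function(reads, locus, scoring = default_scoring()) {
  sc <- check_scoring(scoring)
  if (length(reads) == 0L) {
    return(data.frame(
      read_id = character(), locus = character(), orientation = character(),
      score = integer(), calls = character(), conversion_rate = double(),
      aligned_fraction = double(), pass_qc = logical(),
      stringsAsFactors = FALSE
    ))
  }
  if (any(nchar(reads) == 0L)) stop("empty read in batch", call. = FALSE)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%05d", seq_along(reads))
  res <- .cpp_call_batch(
    unname(reads), locus$reference,
    locus$cpg_positions, locus$non_cpg_c_positions,
    sc$match, sc$mismatch, sc$gap
  )
  data.frame(
    read_id = ids,
    locus = locus$name,
    orientation = res$orientation,
    score = res$score,
    calls = res$calls,
    conversion_rate = ifelse(res$conv_den > 0L, res$conv_num / res$conv_den,
      NA_real_
    ),
    aligned_fraction = res$aligned_len / nchar(locus$reference),
    pass_qc = NA,
    stringsAsFactors = FALSE
  )
}
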