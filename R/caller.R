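# Methylation caller: demultiplexing, read QC filtering, per-sample locus
# summaries and pattern-matrix export.

#' Demultiplex reads by their sample barcode (MID) prefix
#'
#' Each read is assigned to the unique barcode within `max_mismatches`
#' Hamming distance of its prefix; the barcode (and nothing else) is trimmed
#' from assigned reads. Reads matching no barcode go to the unassigned bin.
#' All barcodes must have equal length and pairwise Hamming distance greater
#' than `2 * max_mismatches`, which makes the assignment unique.
#'
#' @param reads Named character vector of read sequences.
#' @param barcode_table Named character vector: names are MID sequences,
#'   values are sample ids.
#' @param max_mismatches Maximum Hamming distance to accept. Default 1.
#' @return List with `samples` (named list of per-sample read vectors,
#'   trimmed) and `unassigned` (untrimmed reads).
#' @export
demultiplex <- function(reads, barcode_table, max_mismatches = 1L) {
  mids <- names(barcode_table)
  if (is.null(mids) || any(mids == "")) {
    stop("barcode_table must be a named vector (names = MID sequences)",
      call. = FALSE
    )
  }
  mlen <- unique(nchar(mids))
  if (length(mlen) != 1L) {
    stop("all MIDs must have equal length", call. = FALSE)
  }
  if (length(mids) > 1L) {
    pairs <- combn(mids, 2L)
    dmin <- min(apply(pairs, 2L, function(p) hamming(p[1L], p[2L])))
    if (dmin <= 2L * max_mismatches) {
      stop(sprintf(
        "MID table violates distance precondition: min pairwise Hamming %d <= 2 * %d",
        dmin, max_mismatches
      ), call. = FALSE)
    }
  }
  prefixes <- substr(reads, 1L, mlen)
  # Hamming distance of every read prefix to every MID
  pref_mat <- do.call(rbind, strsplit(prefixes, "", fixed = TRUE))
  dist <- sapply(mids, function(mid) {
    rowSums(pref_mat != matrix(str_chars(mid),
      nrow = length(reads), ncol = mlen, byrow = TRUE
    ))
  })
  if (is.null(dim(dist))) dist <- matrix(dist, nrow = length(reads))
  hit <- apply(dist, 1L, function(d) {
    k <- which(d <= max_mismatches)
    if (length(k) == 1L) k else NA_integer_
  })
  samples <- lapply(seq_along(mids), function(k) {
    sel <- which(!is.na(hit) & hit == k)
    out <- substring(reads[sel], mlen + 1L)
    names(out) <- names(reads)[sel]
    out
  })
  names(samples) <- unname(barcode_table)
  list(samples = samples, unassigned = reads[is.na(hit)])
}

#' Generate a set of sample barcodes (MIDs)
#'
#' Random search for `n` barcodes of the given length with pairwise Hamming
#' distance at least `min_dist`.
#'
#' @param n Number of barcodes.
#' @param length Barcode length. Default 10.
#' @param min_dist Minimum pairwise Hamming distance. Default 5.
#' @param rng_seed Integer seed.
#' @return Character vector of barcode sequences.
#' @export
make_mid_set <- function(n, length = 10L, min_dist = 5L, rng_seed = 1L) {
  with_seed(rng_seed, {
    mids <- character(0L)
    tries <- 0L
    while (base::length(mids) < n) {
      cand <- chars_str(sample(c("A", "C", "G", "T"), length, replace = TRUE))
      ok <- all(vapply(mids, function(m) hamming(m, cand) >= min_dist, TRUE))
      if (ok) mids <- c(mids, cand)
      tries <- tries + 1L
      if (tries > 10000L) {
        stop("could not find enough barcodes; relax min_dist or length",
          call. = FALSE
        )
      }
    }
    mids
  })
}

#' Apply read-level quality filters
#'
#' A read passes when its per-read bisulfite conversion rate (from non-CpG
#' cytosines) is at least `min_conversion` and its aligned reference fraction
#' at least `min_aligned`. Reads whose conversion rate is undefined (no
#' non-CpG cytosine aligned) fail. A filter report (counts per reason) is
#' attached as attribute `"filter_report"`.
#'
#' @param patterns `ReadPattern` data.frame from [call_reads()].
#' @param min_conversion Minimum conversion rate, default 0.95.
#' @param min_aligned Minimum aligned reference fraction, default 0.8.
#' @return The passing rows with `pass_qc = TRUE`, report attached.
#' @export
filter_reads <- function(patterns, min_conversion = 0.95, min_aligned = 0.8) {
  stopifnot(
    min_conversion >= 0, min_conversion <= 1,
    min_aligned >= 0, min_aligned <= 1
  )
  conv_undef <- is.na(patterns$conversion_rate)
  fail_conv <- !conv_undef & patterns$conversion_rate < min_conversion
  fail_aln <- patterns$aligned_fraction < min_aligned
  pass <- !conv_undef & !fail_conv & !fail_aln
  report <- list(
    n_in = nrow(patterns),
    n_pass = sum(pass),
    n_fail_conversion = sum(fail_conv & !fail_aln),
    n_fail_aligned = sum(fail_aln),
    n_conversion_undefined = sum(conv_undef & !fail_aln),
    min_conversion = min_conversion,
    min_aligned = min_aligned
  )
  out <- patterns[pass, , drop = FALSE]
  out$pass_qc <- TRUE
  rownames(out) <- NULL
  attr(out, "filter_report") <- report
  out
}

#' @rdname filter_reads
#' @param x A filtered pattern data.frame.
#' @export
filter_report <- function(x) attr(x, "filter_report")

# Per-read methylated fraction over non-N calls (NA if all N).
read_meth_fraction <- function(calls) {
  n_m <- nchar(gsub("[^M]", "", calls))
  n_u <- nchar(gsub("[^U]", "", calls))
  ifelse(n_m + n_u > 0L, n_m / (n_m + n_u), NA_real_)
}

#' Summarize passing reads of one sample at one locus
#'
#' A read counts as unmethylated when its methylated fraction (over non-N
#' calls) is at most `read_class_max_minor`, methylated when at least
#' `1 - read_class_max_minor`, and mosaic otherwise. `mean_methylation` is
#' the mean per-read methylated fraction, in percent. With zero usable reads
#' the summary is marked missing (`NA` metrics), never fabricated as 0%.
#'
#' @param patterns Filtered `ReadPattern` rows of one sample x locus.
#' @param sample_id,locus_name Labels for the summary row (defaulted from the
#'   patterns when unambiguous).
#' @param read_class_max_minor Class threshold, default 0.1 (tolerates one
#'   miscall on a 10-CpG amplicon).
#' @return One-row data.frame (`LocusSummary`): `sample_id`, `locus`,
#'   `n_reads_pass`, `mean_methylation` (percent), `p_unmeth`, `p_meth`,
#'   `p_mosaic`, and a list column `read_fracs` holding the per-read
#'   methylated fractions (used by the bootstrap downstream).
#' @export
summarize_locus <- function(patterns, sample_id = NULL, locus_name = NULL,
                            read_class_max_minor = 0.1) {
  if (is.null(locus_name)) {
    locus_name <- if (nrow(patterns) > 0L) patterns$locus[1L] else NA_character_
  }
  if (is.null(sample_id)) sample_id <- "sample"
  fr <- read_meth_fraction(patterns$calls)
  fr <- fr[!is.na(fr)]
  n <- length(fr)
  if (n == 0L) {
    out <- data.frame(
      sample_id = sample_id, locus = locus_name, n_reads_pass = 0L,
      mean_methylation = NA_real_, p_unmeth = NA_real_, p_meth = NA_real_,
      p_mosaic = NA_real_, stringsAsFactors = FALSE
    )
    out$read_fracs <- list(numeric(0L))
    return(out)
  }
  unmeth <- fr <= read_class_max_minor
  meth <- fr >= 1 - read_class_max_minor
  out <- data.frame(
    sample_id = sample_id, locus = locus_name, n_reads_pass = n,
    mean_methylation = mean(fr) * 100,
    p_unmeth = mean(unmeth),
    p_meth = mean(meth),
    p_mosaic = mean(!unmeth & !meth),
    stringsAsFactors = FALSE
  )
  out$read_fracs <- list(fr)
  out
}

#' Call, filter and summarize all loci of one sample
#'
#' Runs [call_reads()] per locus, applies [filter_reads()], and stacks the
#' [summarize_locus()] rows. Reads are assigned to loci from their read ids
#' (which encode the locus, as written by the simulator and by demultiplexed
#' amplicon libraries); reads naming no panel locus are dropped and counted.
#'
#' @param reads Named character vector of one sample's reads.
#' @param panel An `AmpliconPanel`.
#' @param sample_id Sample label.
#' @param min_conversion,min_aligned See [filter_reads()].
#' @param read_class_max_minor See [summarize_locus()].
#' @param scoring See [align_bisulfite()].
#' @return List: `summary` (LocusSummary data.frame, one row per locus),
#'   `patterns` (filtered ReadPattern rows), `filter_report` (per locus).
#' @export
call_sample <- function(reads, panel, sample_id = "sample",
                        min_conversion = 0.95, min_aligned = 0.8,
                        read_class_max_minor = 0.1,
                        scoring = default_scoring()) {
  locus_of <- assign_locus_from_ids(names(reads), names(panel))
  reports <- list()
  summaries <- list()
  patterns <- list()
  for (nm in names(panel)) {
    sel <- which(!is.na(locus_of) & locus_of == nm)
    pat <- call_reads(reads[sel], panel[[nm]], scoring = scoring)
    flt <- filter_reads(pat,
      min_conversion = min_conversion,
      min_aligned = min_aligned
    )
    reports[[nm]] <- filter_report(flt)
    patterns[[nm]] <- flt
    summaries[[nm]] <- summarize_locus(flt,
      sample_id = sample_id, locus_name = nm,
      read_class_max_minor = read_class_max_minor
    )
  }
  list(
    summary = do.call(rbind, c(unname(summaries), list(make.row.names = FALSE))),
    patterns = do.call(rbind, c(unname(patterns), list(make.row.names = FALSE))),
    filter_report = reports,
    n_unassigned = sum(is.na(locus_of))
  )
}

# Reads carry "<sample>|<locus>|r<index>" ids; match the locus token.
assign_locus_from_ids <- function(ids, locus_names) {
  if (is.null(ids)) {
    return(rep(NA_character_, 0L))
  }
  parts <- strsplit(ids, "|", fixed = TRUE)
  vapply(parts, function(p) {
    hit <- p[p %in% locus_names]
    if (length(hit) >= 1L) hit[1L] else NA_character_
  }, "")
}

#' Export the read x CpG pattern matrix of one sample x locus
#'
#' TSV with one row per read and one column per CpG (named by 1-based
#' reference position when the locus is supplied), cells in `{M, U, N}`.
#' Rows are ordered by descending per-read methylated fraction, then read id,
#' so the file renders directly as a lollipop-style methylation plot.
#'
#' @param patterns `ReadPattern` rows of one sample x locus.
#' @param path Output TSV path.
#' @param locus Optional [amplicon_locus()] for CpG coordinate column names.
#' @return The matrix data.frame, invisibly.
#' @export
export_pattern_matrix <- function(patterns, path, locus = NULL) {
  n_cpg <- if (!is.null(locus)) {
    length(locus$cpg_positions)
  } else if (nrow(patterns) > 0L) {
    nchar(patterns$calls[1L])
  } else {
    0L
  }
  col_names <- if (!is.null(locus)) {
    paste0("CpG_", locus$cpg_positions + 1L)
  } else {
    paste0("CpG_", seq_len(n_cpg))
  }
  if (nrow(patterns) == 0L) {
    warning("no patterns to export; writing header-only file: ", path)
    df <- setNames(
      as.data.frame(c(
        list(read_id = character(0L)),
        replicate(n_cpg, character(0L), simplify = FALSE)
      )),
      c("read_id", col_names)
    )
  } else {
    fr <- read_meth_fraction(patterns$calls)
    ord <- order(-ifelse(is.na(fr), -1, fr), patterns$read_id)
    calls <- do.call(rbind, strsplit(patterns$calls[ord], "", fixed = TRUE))
    df <- setNames(
      data.frame(patterns$read_id[ord], calls, stringsAsFactors = FALSE),
      c("read_id", col_names)
    )
  }
  tryCatch(
    write_tsv(df, path),
    error = function(e) {
      stop("failed to write pattern matrix to ", path, ": ",
        conditionMessage(e),
        call. = FALSE
      )
    }
  )
  invisible(df)
}
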