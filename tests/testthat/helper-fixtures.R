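# Shared fixtures built in code.

test_panel <- function(seed = 11L, n_cpgs = 10L, len = 200L) {
  make_locus_panel(n_cpgs, len, rng_seed = seed)
}

# A minimal hand-built locus where every coordinate is known by construction:
# CpGs at 0-based offsets 2, 8, 14, 20, 26 and non-CpG Cs at 0, 6, 12, 18, 24.
toy_locus <- function() {
  #       0123456789012345678901234567890
  ref <- "CACGTACACGTACACGTACACGTACACGTAA"
  amplicon_locus(
    name = "TOY", imprint_class = "germ_marker",
    reference = ref, cpg_positions = c(2L, 8L, 14L, 20L, 26L)
  )
}

# 24 bp locus used in scoring examples; read "ACGT" matches its prefix.
toy_scoring_locus <- function() {
  amplicon_locus("S4", "germ_marker",
    paste0("ACGT", strrep("CA", 5), "CGCGACGACG"),
    cpg_positions = c(1, 14, 16, 19, 22)
  )
}

# Noise-free read for a locus given a per-CpG methylation vector: non-CpG Cs
# fully converted, CpGs by state.
clean_read <- function(locus, meth) {
  chars <- strsplit(locus$reference, "")[[1L]]
  chars[locus$non_cpg_c_positions + 1L] <- "T"
  chars[locus$cpg_positions + 1L] <- ifelse(meth, "C", "T")
  paste0(chars, collapse = "")
}

# LocusSummary row built directly from a vector of per-read methylated
# fractions (bypassing the caller), for unit tests of the mixture module.
summary_from_fracs <- function(sample_id, locus, fracs,
                               read_class_max_minor = 0.1) {
  out <- data.frame(
    sample_id = sample_id, locus = locus, n_reads_pass = length(fracs),
    mean_methylation = mean(fracs) * 100,
    p_unmeth = mean(fracs <= read_class_max_minor),
    p_meth = mean(fracs >= 1 - read_class_max_minor),
    p_mosaic = mean(fracs > read_class_max_minor &
      fracs < 1 - read_class_max_minor),
    stringsAsFactors = FALSE
  )
  out$read_fracs <- list(fracs)
  out
}
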