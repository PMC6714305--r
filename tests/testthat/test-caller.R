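test_that("demultiplexing assigns reads within the mismatch budget and trims MIDs", {
  mids <- c(ACGTACGTAC = "S1", TGCATGCAGG = "S2", GATCGATCTT = "S3")
  reads <- c(
    r1 = paste0("ACGTACGTAC", "AAAA"), # exact S1
    r2 = paste0("TGCATGCAGG", "CCCC"), # exact S2
    r3 = paste0("ACGTACGTAA", "GGGG"), # 1 mismatch from S1
    r4 = paste0("ACGTACTTAA", "TTTT") # 2 mismatches from S1 -> unassigned
  )
  out <- demultiplex(reads, mids, max_mismatches = 1)
  expect_equal(unname(out$samples$S1), c("AAAA", "GGGG"))
  expect_equal(unname(out$samples$S2), "CCCC")
  expect_length(out$samples$S3, 0)
  expect_named(out$unassigned, "r4")
  # partition is exhaustive and disjoint
  expect_equal(
    sum(lengths(out$samples)) + length(out$unassigned), length(reads)
  )
})

test_that("demultiplexing recovers 1000 reads with one planted mismatch each", {
  set.seed(31)
  mids <- make_mid_set(4, length = 10, min_dist = 5, rng_seed = 8)
  table <- setNames(paste0("S", 1:4), mids)
  truth <- sample(1:4, 1000, replace = TRUE)
  reads <- vapply(truth, function(k) {
    mid <- strsplit(mids[k], "")[[1]]
    pos <- sample(10, 1)
    mid[pos] <- sample(setdiff(c("A", "C", "G", "T"), mid[pos]), 1)
    paste0(paste0(mid, collapse = ""), random_dna(20))
  }, "")
  names(reads) <- sprintf("r%04d", seq_along(reads))
  out <- demultiplex(reads, table, max_mismatches = 1)
  expect_length(out$unassigned, 0)
  got <- rep(NA_integer_, 1000)
  for (k in 1:4) {
    got[names(reads) %in% names(out$samples[[paste0("S", k)]])] <- k
  }
  expect_equal(got, truth)
})

test_that("demultiplexing rejects barcode tables violating the distance bound", {
  mids <- c(ACGTACGTAC = "S1", ACGTACGTTT = "S2") # Hamming 2
  expect_error(demultiplex(c(r = "ACGTACGTACAA"), mids, max_mismatches = 1),
    "distance precondition"
  )
})

test_that("pattern calls and conversion rates reflect the read content", {
  locus <- toy_locus()
  # fully converted unmethylated read
  aln <- align_bisulfite(clean_read(locus, rep(FALSE, 5)), locus)
  pat <- call_read_pattern(aln, locus, read_id = "u")
  expect_equal(pat$calls, "UUUUU")
  expect_equal(pat$conversion_rate, 1)
  expect_equal(pat$aligned_fraction, 1)
  # methylated read: C at every CpG, T at every non-CpG C
  aln2 <- align_bisulfite(clean_read(locus, rep(TRUE, 5)), locus)
  pat2 <- call_read_pattern(aln2, locus, read_id = "m")
  expect_equal(pat2$calls, "MMMMM")
  expect_equal(pat2$conversion_rate, 1)
})

test_that("planted conversion failures are quantified per read", {
  # 20 non-CpG Cs; plant failures (retained C) at 2 of them -> rate 0.9
  ref <- paste0(strrep("CAA", 20), strrep("ACGAA", 5))
  locus <- amplicon_locus("B", "germ_marker", ref,
    cpg_positions = 60 + c(1, 6, 11, 16, 21)
  )
  chars <- strsplit(ref, "")[[1]]
  chars[locus$non_cpg_c_positions + 1] <- "T"
  chars[locus$non_cpg_c_positions[c(3, 11)] + 1] <- "C"
  chars[locus$cpg_positions + 1] <- "T"
  pat <- call_read_pattern(
    align_bisulfite(paste0(chars, collapse = ""), locus), locus
  )
  expect_equal(pat$conversion_rate, 0.9)
  expect_equal(pat$calls, "UUUUU")
})

test_that("batch calling agrees with the single-read path", {
  panel <- test_panel()
  locus <- panel$LIT1
  spec <- sample_spec("S", fraction = "SN", germ_fraction = 0.5,
    n_reads_per_locus = 80
  )
  sim <- simulate_sample_reads(panel["LIT1"], spec, rng_seed = 13)
  batch <- call_reads(sim$reads, locus)
  single <- do.call(rbind, lapply(seq_along(sim$reads), function(i) {
    call_read_pattern(
      align_bisulfite(sim$reads[[i]], locus), locus,
      read_id = names(sim$reads)[i]
    )
  }))
  expect_equal(batch$calls, single$calls)
  expect_equal(batch$score, single$score)
  expect_equal(batch$conversion_rate, single$conversion_rate)
  expect_equal(batch$aligned_fraction, single$aligned_fraction)
  # calls conservation: #M + #U + #N equals the CpG count for every read
  expect_true(all(nchar(batch$calls) == length(locus$cpg_positions)))
  expect_true(all(grepl("^[MUN]+$", batch$calls)))
})

test_that("the conversion filter removes exactly the planted low-conversion reads", {
  panel <- test_panel()
  locus <- panel$DDX4
  good <- sample_spec("S", fraction = "SN", germ_fraction = 0.5,
    n_reads_per_locus = 190, conversion_rate = 1, seq_error_rate = 0
  )
  bad <- sample_spec("S", fraction = "SN", germ_fraction = 0.5,
    n_reads_per_locus = 10, conversion_rate = 0.5, seq_error_rate = 0
  )
  sim_good <- simulate_sample_reads(panel["DDX4"], good, rng_seed = 1)
  sim_bad <- simulate_sample_reads(panel["DDX4"], bad, rng_seed = 2)
  reads <- c(sim_good$reads, setNames(
    sim_bad$reads, sub("\\|r", "|bad", names(sim_bad$reads))
  ))
  pat <- call_reads(reads, locus)
  flt <- filter_reads(pat, min_conversion = 0.95)
  expect_false(any(grepl("bad", flt$read_id)))
  expect_true(all(grepl("bad", setdiff(pat$read_id, flt$read_id))))
  rep <- filter_report(flt)
  expect_equal(rep$n_in, 200)
  expect_equal(rep$n_pass, 190)
  expect_equal(rep$n_fail_conversion, 10)
})

test_that("locus summaries compute means, classes and the missing state", {
  pat <- data.frame(
    read_id = paste0("r", 1:10),
    locus = "X",
    calls = c(rep(strrep("M", 10), 4), rep(strrep("U", 10), 6)),
    stringsAsFactors = FALSE
  )
  s <- summarize_locus(pat, sample_id = "S", read_class_max_minor = 0.1)
  expect_equal(s$mean_methylation, 40)
  expect_equal(s$p_unmeth, 0.6)
  expect_equal(s$p_meth, 0.4)
  expect_equal(s$p_mosaic, 0)
  expect_equal(s$p_unmeth + s$p_meth + s$p_mosaic, 1, tolerance = 1e-9)

  # threshold rule: 1 M among 12 calls is still "unmethylated"
  one_m <- data.frame(
    read_id = "r", locus = "X",
    calls = paste0("M", strrep("U", 11)), stringsAsFactors = FALSE
  )
  expect_equal(summarize_locus(one_m, "S")$p_unmeth, 1)
  # and 2 M among 12 is mosaic
  two_m <- data.frame(
    read_id = "r", locus = "X",
    calls = paste0("MM", strrep("U", 10)), stringsAsFactors = FALSE
  )
  expect_equal(summarize_locus(two_m, "S")$p_mosaic, 1)

  empty <- summarize_locus(pat[0, ], sample_id = "S", locus_name = "X")
  expect_equal(empty$n_reads_pass, 0)
  expect_true(is.na(empty$mean_methylation))
})

test_that("the pattern matrix export is ordered, complete and consistent", {
  locus <- toy_locus()
  pat <- data.frame(
    read_id = c("b", "a", "c"),
    locus = "TOY",
    calls = c("MUMUM", "MMMMM", "UUUUU"),
    stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".tsv")
  export_pattern_matrix(pat, path, locus = locus)
  mat <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(dim(mat), c(3, 6))
  expect_equal(mat$read_id, c("a", "b", "c")) # by descending M fraction
  expect_equal(names(mat), c("read_id", paste0("CpG_", locus$cpg_positions + 1)))
  m_counts <- rowSums(mat[, -1] == "M")
  expect_equal(unname(m_counts), c(5, 3, 0))

  expect_warning(
    export_pattern_matrix(pat[0, ], path, locus = locus),
    "header-only"
  )
  hdr <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(nrow(hdr), 0)
  expect_equal(ncol(hdr), 6)
})
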