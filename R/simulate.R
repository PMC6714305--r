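# Synthetic deep-bisulfite-sequencing read generator.
#
# The allele model is epiallele-coherent: a single Bernoulli draw per read
# decides whether the whole allele is methylated, reproducing the
# fully-methylated / fully-unmethylated read structure of single-allele DBS
# data. Per-CpG noise enters only through incomplete bisulfite conversion and
# sequencing error.

# Baseline allele-methylation probability for one compartment at one locus.
allele_meth_prob <- function(locus, compartment, karyotype, epimutation = 0) {
  p <- switch(locus$imprint_class,
    germ_marker = if (compartment == "soma") 1 else locus$germ_level,
    maternal_imprint = if (compartment == "soma") 0.5 else locus$germ_level,
    paternal_imprint = if (compartment == "soma") 0.5 else locus$germ_level,
    x_inactivation = if (compartment == "soma") {
      if (karyotype == "46,XY") 1 else 0.5
    } else {
      locus$germ_level
    }
  )
  if (compartment == "germ") p <- clamp(p + epimutation, 0, 1)
  p
}

#' Draw the methylation profile of one allele
#'
#' Draws a single Bernoulli variable with the compartment's
#' allele-methylation probability and applies it to every CpG of the locus
#' (epiallele coherence): germ-marker loci are fully methylated in soma and
#' unmethylated in germ cells; maternally imprinted DMRs are ~50% methylated
#' in soma and unmethylated in germ cells; the paternally methylated H19
#' IG-DMR is ~50% in soma and fully methylated in germ cells; the XIST CpG
#' island is fully methylated in 46,XY soma, ~50% in 46,XX / 47,XXY soma and
#' unmethylated in the male germline. An epimutation magnitude `e` shifts the
#' germ compartment's probability (clamped to `[0, 1]`).
#'
#' @param locus An [amplicon_locus()].
#' @param compartment `"germ"` or `"soma"`.
#' @param karyotype `"46,XY"`, `"46,XX"` or `"47,XXY"`.
#' @param epimutation Magnitude `e` in `[-1, 1]`; only meaningful for the
#'   germ compartment.
#' @return Logical vector, one entry per CpG, all identical.
#' @export
allele_methylation_profile <- function(locus, compartment = c("germ", "soma"),
                                       karyotype = "46,XY", epimutation = 0) {
  compartment <- match.arg(compartment)
  p <- allele_meth_prob(locus, compartment, karyotype, epimutation)
  rep(runif(1L) < p, length(locus$cpg_positions))
}

#' Bisulfite-convert one allele into a read sequence
#'
#' Simulates the bisulfite chemistry and sequencing of a single allele: every
#' non-CpG cytosine converts to thymine with probability `conversion_rate`;
#' a CpG cytosine converts to thymine with probability `conversion_rate` when
#' the allele is unmethylated, and is retained as cytosine with probability
#' `conversion_rate` when methylated (failures emit the opposite letter,
#' modelling inappropriate non-conversion and over-conversion with one shared
#' rate). Each base is then substituted uniformly to another base with
#' probability `seq_error_rate`. No indels are simulated, so the read length
#' equals the reference length.
#'
#' @param locus An [amplicon_locus()].
#' @param allele_methylation Logical per-CpG methylation of the allele.
#' @param conversion_rate,seq_error_rate Noise levels in `[0, 1]`.
#' @return Read sequence (character).
#' @export
bisulfite_convert <- function(locus, allele_methylation,
                              conversion_rate = 0.995,
                              seq_error_rate = 0.002) {
  stopifnot(length(allele_methylation) == length(locus$cpg_positions))
  chars <- str_chars(locus$reference)
  nc <- locus$non_cpg_c_positions + 1L
  chars[nc] <- ifelse(runif(length(nc)) < conversion_rate, "T", "C")
  cg <- locus$cpg_positions + 1L
  converted <- runif(length(cg)) < conversion_rate
  chars[cg] <- ifelse(allele_methylation,
    ifelse(converted, "C", "T"),
    ifelse(converted, "T", "C")
  )
  err <- which(runif(length(chars)) < seq_error_rate)
  if (length(err) > 0L) {
    bases <- c("A", "C", "G", "T")
    chars[err] <- vapply(
      chars[err],
      function(b) sample(setdiff(bases, b), 1L), ""
    )
  }
  chars_str(chars)
}

# Vectorised batch generator for one sample x locus. Returns reads plus the
# per-read ground truth. exact_proportions replaces the Bernoulli draws for
# compartment membership and allele methylation with deterministic rounded
# allocations (variance reduction; noise parameters still apply).
simulate_locus_reads <- function(locus, n, germ_fraction, karyotype = "46,XY",
                                 epimutation = 0,
                                 conversion_rate = 0.995,
                                 seq_error_rate = 0.002,
                                 sample_id = "S", exact_proportions = FALSE) {
  p_germ_meth <- allele_meth_prob(locus, "germ", karyotype, epimutation)
  p_soma_meth <- allele_meth_prob(locus, "soma", karyotype)
  if (exact_proportions) {
    n_germ <- round(germ_fraction * n)
    is_germ <- rep(c(TRUE, FALSE), c(n_germ, n - n_germ))
    meth <- logical(n)
    meth[is_germ] <- rep(
      c(TRUE, FALSE),
      c(round(p_germ_meth * n_germ), n_germ - round(p_germ_meth * n_germ))
    )
    n_soma <- n - n_germ
    meth[!is_germ] <- rep(
      c(TRUE, FALSE),
      c(round(p_soma_meth * n_soma), n_soma - round(p_soma_meth * n_soma))
    )
  } else {
    is_germ <- runif(n) < germ_fraction
    meth <- ifelse(is_germ, runif(n) < p_germ_meth, runif(n) < p_soma_meth)
  }

  len <- nchar(locus$reference)
  ref_chars <- str_chars(locus$reference)
  mat <- matrix(ref_chars, nrow = n, ncol = len, byrow = TRUE)

  nc <- locus$non_cpg_c_positions + 1L
  if (length(nc) > 0L) {
    conv <- matrix(runif(n * length(nc)) < conversion_rate, nrow = n)
    mat[, nc] <- ifelse(conv, "T", "C")
  }
  cg <- locus$cpg_positions + 1L
  conv <- matrix(runif(n * length(cg)) < conversion_rate, nrow = n)
  mat[, cg] <- ifelse(conv == meth, "C", "T")

  if (seq_error_rate > 0) {
    err <- which(matrix(runif(n * len) < seq_error_rate, nrow = n))
    if (length(err) > 0L) {
      bases <- c("A", "C", "G", "T")
      # uniform substitution to one of the three other bases
      shift <- sample.int(3L, length(err), replace = TRUE)
      old <- match(mat[err], bases)
      mat[err] <- bases[((old - 1L + shift) %% 4L) + 1L]
    }
  }

  reads <- apply(mat, 1L, paste0, collapse = "")
  read_ids <- sprintf("%s|%s|r%05d", sample_id, locus$name, seq_len(n))
  truth <- data.frame(
    sample_id = sample_id,
    locus = locus$name,
    read_id = read_ids,
    compartment = ifelse(is_germ, "germ", "soma"),
    allele_methylated = meth,
    stringsAsFactors = FALSE
  )
  list(reads = setNames(reads, read_ids), truth = truth)
}

#' Simulate amplicon reads for one sample across a panel
#'
#' In-memory equivalent of one sample of [simulate_cohort()]: draws
#' `n_reads_per_locus` alleles per locus from the germ/soma mixture defined
#' by the sample specification, bisulfite-converts them and returns reads
#' plus ground truth.
#'
#' @param panel An `AmpliconPanel` (or a sub-list of loci).
#' @param spec A [sample_spec()].
#' @param rng_seed Integer seed.
#' @param exact_proportions Use deterministic rounded compartment/allele
#'   allocations instead of Bernoulli draws (variance reduction for
#'   noise-free checks). Default `FALSE`.
#' @return List with elements `reads` (named character vector) and `truth`
#'   (data.frame, one row per read).
#' @export
simulate_sample_reads <- function(panel, spec, rng_seed = 1L,
                                  exact_proportions = FALSE) {
  with_seed(rng_seed, {
    out <- lapply(panel, function(locus) {
      e <- 0
      if (!is.null(spec$epimutations) &&
        locus$name %in% names(spec$epimutations)) {
        e <- unname(spec$epimutations[[locus$name]])
      }
      simulate_locus_reads(
        locus,
        n = spec$n_reads_per_locus,
        germ_fraction = spec$germ_fraction,
        karyotype = spec$karyotype,
        epimutation = e,
        conversion_rate = spec$conversion_rate,
        seq_error_rate = spec$seq_error_rate,
        sample_id = spec$sample_id,
        exact_proportions = exact_proportions
      )
    })
    list(
      reads = do.call(c, unname(lapply(out, `[[`, "reads"))),
      truth = do.call(rbind, c(unname(lapply(out, `[[`, "truth")),
        list(make.row.names = FALSE)
      ))
    )
  })
}

#' Simulate a full cohort and write its files
#'
#' For every sample spec, emits `n_reads_per_locus` reads per panel locus
#' (each read drawn from the germ compartment with probability
#' `germ_fraction`), writes one FASTQ per sample (constant quality `I`; read
#' names encode sample, locus and read index), a TSV ground-truth table, a
#' TSV sample sheet, the panel FASTA/TSV, and a JSON cohort configuration.
#' Fully reproducible from `rng_seed`.
#'
#' @param panel An `AmpliconPanel`.
#' @param specs List of [sample_spec()] objects (unique sample ids).
#' @param rng_seed Integer seed.
#' @param out_dir Output directory (created if missing). If `NULL`, nothing
#'   is written and reads are returned in memory.
#' @return List with `sheet`, `truth`, `reads` (per-sample list) and, when
#'   `out_dir` is given, the output `paths`.
#' @export
simulate_cohort <- function(panel, specs, rng_seed = 1L, out_dir = NULL) {
  ids <- vapply(specs, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id in cohort specs: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  sheet <- sample_sheet(specs)
  per_sample <- lapply(seq_along(specs), function(i) {
    simulate_sample_reads(panel, specs[[i]],
      rng_seed = derive_seed(rng_seed, "simulate", i)
    )
  })
  names(per_sample) <- ids
  truth <- do.call(rbind, c(unname(lapply(per_sample, `[[`, "truth")),
    list(make.row.names = FALSE)
  ))
  reads <- lapply(per_sample, `[[`, "reads")
  result <- list(sheet = sheet, truth = truth, reads = reads)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fastq_paths <- setNames(file.path(out_dir, paste0(ids, ".fastq")), ids)
    for (id in ids) write_reads_fastq(reads[[id]], fastq_paths[[id]])
    paths <- list(
      fastq = fastq_paths,
      truth = write_tsv(truth, file.path(out_dir, "truth.tsv")),
      sheet = write_tsv(sheet, file.path(out_dir, "sample_sheet.tsv")),
      panel_fasta = write_panel_fasta(panel, file.path(out_dir, "panel.fa")),
      panel_tsv = write_panel_tsv(panel, file.path(out_dir, "panel.tsv"))
    )
    jsonlite::write_json(
      list(
        rng_seed = rng_seed,
        n_samples = length(specs),
        n_loci = length(panel),
        samples = sheet
      ),
      file.path(out_dir, "cohort.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    paths$config <- file.path(out_dir, "cohort.json")
    result$paths <- paths
  }
  result
}

#' Write reads as 4-line FASTQ with constant quality
#'
#' @param reads Named character vector (names become read ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(unname(reads))
  names(seqs) <- names(reads)
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read amplicon reads from FASTQ or FASTA
#'
#' @param path Input path.
#' @param format `"fastq"` (default) or `"fasta"`.
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  seqs <- Biostrings::readDNAStringSet(path, format = format)
  setNames(as.character(seqs), names(seqs))
}
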