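# Amplicon locus panel: the eight targeted regions analysed by deep bisulfite
# sequencing (two paternally and two maternally imprinted DMRs, three
# germ-cell marker promoters, and the XIST CpG island).

PANEL_DEF <- data.frame(
  name = c("H19", "MEG3", "MEST", "LIT1", "FGFR3", "DDX4", "RHOXF1", "XIST"),
  imprint_class = c(
    "paternal_imprint", "paternal_imprint",
    "maternal_imprint", "maternal_imprint",
    "germ_marker", "germ_marker", "germ_marker",
    "x_inactivation"
  ),
  # Allele-methylation probability of the germ compartment. MEG3 is assayed at
  # its TSS-DMR, a secondary DMR that is unmethylated in sperm, so its germ
  # level is 0 even though the locus is paternally imprinted.
  germ_level = c(1, 0, 0, 0, 0, 0, 0, 0),
  stringsAsFactors = FALSE
)

GERM_MARKER_LOCI <- c("FGFR3", "DDX4", "RHOXF1")
IMPRINTED_LOCI <- c("H19", "MEG3", "MEST", "LIT1", "XIST")

#' Construct an amplicon locus
#'
#' An `AmpliconLocus` describes one targeted bisulfite amplicon: the
#' unconverted genomic top-strand reference, the 0-based offsets of its CpG
#' cytosines, the offsets of its non-CpG cytosines (used to estimate per-read
#' bisulfite conversion), an imprint class, and the allele-methylation
#' probability of germ-cell-derived alleles (`germ_level`).
#'
#' @param name Locus label (e.g. `"DDX4"`).
#' @param imprint_class One of `"paternal_imprint"`, `"maternal_imprint"`,
#'   `"germ_marker"`, `"x_inactivation"`.
#' @param reference Unconverted reference sequence (character, ACGT).
#' @param cpg_positions 0-based offsets of CpG cytosines (strictly increasing).
#' @param germ_level Allele-methylation probability in germ cells (0 or 1 for
#'   the canonical classes). Defaults by class: 1 for `paternal_imprint`, 0
#'   otherwise.
#' @return An object of class `AmpliconLocus`.
#' @export
amplicon_locus <- function(name, imprint_class, reference, cpg_positions,
                           germ_level = NULL) {
  imprint_class <- match.arg(imprint_class, c(
    "paternal_imprint", "maternal_imprint", "germ_marker", "x_inactivation"
  ))
  if (is.null(germ_level)) {
    germ_level <- if (imprint_class == "paternal_imprint") 1 else 0
  }
  chars <- str_chars(reference)
  cpg_positions <- as.integer(sort(cpg_positions))
  bad <- cpg_positions[chars[cpg_positions + 1L] != "C" |
    chars[cpg_positions + 2L] != "G"]
  if (length(bad) > 0L) {
    stop("cpg_positions must point at CpG dinucleotides; offending offsets: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  all_c <- which(chars == "C") - 1L
  non_cpg <- setdiff(all_c, cpg_positions)
  obj <- structure(
    list(
      name = name,
      imprint_class = imprint_class,
      reference = reference,
      cpg_positions = cpg_positions,
      non_cpg_c_positions = as.integer(non_cpg),
      germ_level = germ_level
    ),
    class = "AmpliconLocus"
  )
  validate_locus(obj)
  obj
}

validate_locus <- function(locus) {
  chars <- str_chars(locus$reference)
  p <- locus$cpg_positions
  q <- locus$non_cpg_c_positions
  stopifnot(
    all(chars[p + 1L] == "C"), all(chars[p + 2L] == "G"),
    all(diff(p) > 0L), all(diff(q) >= 0L) || length(q) < 2L,
    length(intersect(p, q)) == 0L,
    length(p) >= 5L, length(q) >= 5L,
    locus$germ_level >= 0, locus$germ_level <= 1
  )
  invisible(locus)
}

#' @export
print.AmpliconLocus <- function(x, ...) {
  cat(sprintf(
    "AmpliconLocus %s [%s]: %d bp, %d CpGs, %d non-CpG Cs, germ level %.2g\n",
    x$name, x$imprint_class, nchar(x$reference),
    length(x$cpg_positions), length(x$non_cpg_c_positions), x$germ_level
  ))
  invisible(x)
}

# Generate one random amplicon reference with exactly n_cpgs CpGs and no
# accidental CpG elsewhere. CpG starts are placed one per equal-width window
# so spacing is always >= 2.
random_amplicon <- function(n_cpgs, len) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  for (i in seq_len(len - 1L)) {
    if (chars[i] == "C" && chars[i + 1L] == "G") chars[i + 1L] <- "T"
  }
  bounds <- floor(seq(1L, len, length.out = n_cpgs + 1L))
  starts <- integer(n_cpgs)
  for (k in seq_len(n_cpgs)) {
    lo <- bounds[k]
    # keep at least one base between consecutive CpG pairs so plants never
    # overwrite each other
    hi <- min(bounds[k + 1L] - 2L, len - 1L)
    starts[k] <- if (hi > lo) sample(lo:hi, 1L) else lo
  }
  chars[starts] <- "C"
  chars[starts + 1L] <- "G"
  # planting may have created a C directly before a planted C..G pair is fine;
  # but a pre-existing C before a planted G was overwritten above. Re-check
  # for stray CpGs introduced at plant boundaries.
  for (i in setdiff(which(chars == "C"), starts)) {
    if (i < len && chars[i + 1L] == "G") chars[i + 1L] <- "T"
  }
  non_cpg_c <- setdiff(which(chars == "C"), starts)
  if (length(non_cpg_c) < 5L) {
    cand <- which(chars %in% c("A", "T"))
    cand <- cand[cand < len & chars[pmin(cand + 1L, len)] != "G"]
    cand <- setdiff(cand, c(starts, starts + 1L))
    add <- sample(cand, 5L - length(non_cpg_c))
    chars[add] <- "C"
  }
  list(reference = chars_str(chars), cpg_positions = starts - 1L)
}

#' Generate the eight-locus synthetic amplicon panel
#'
#' Builds randomly generated stand-in amplicon sequences for the eight loci of
#' the deep-bisulfite-sequencing assay: H19 and MEG3 (paternally imprinted),
#' MEST and LIT1/KCNQ1OT1 (maternally imprinted), FGFR3, DDX4/VASA and RHOXF1
#' (germ-cell markers) and XIST (X inactivation). Each amplicon carries exactly
#' `n_cpgs_per_locus` CpG sites plus at least five non-CpG cytosines so that
#' per-read bisulfite conversion is estimable.
#'
#' @param n_cpgs_per_locus CpGs per amplicon (>= 5). Default 10.
#' @param amplicon_length Amplicon length in bp (>= 4 * `n_cpgs_per_locus`).
#'   Default 200.
#' @param rng_seed Integer seed; the same seed reproduces the panel exactly.
#' @return Named list of [amplicon_locus()] objects (class `AmpliconPanel`).
#' @export
make_locus_panel <- function(n_cpgs_per_locus = 10L, amplicon_length = 200L,
                             rng_seed = 1L) {
  if (n_cpgs_per_locus < 5L) {
    stop("n_cpgs_per_locus must be >= 5", call. = FALSE)
  }
  if (amplicon_length < 4L * n_cpgs_per_locus) {
    stop(sprintf(
      "amplicon_length %d too small to place %d CpGs (need >= %d)",
      amplicon_length, n_cpgs_per_locus, 4L * n_cpgs_per_locus
    ), call. = FALSE)
  }
  panel <- with_seed(rng_seed, {
    lapply(seq_len(nrow(PANEL_DEF)), function(i) {
      amp <- random_amplicon(n_cpgs_per_locus, amplicon_length)
      amplicon_locus(
        name = PANEL_DEF$name[i],
        imprint_class = PANEL_DEF$imprint_class[i],
        reference = amp$reference,
        cpg_positions = amp$cpg_positions,
        germ_level = PANEL_DEF$germ_level[i]
      )
    })
  })
  names(panel) <- PANEL_DEF$name
  class(panel) <- "AmpliconPanel"
  panel
}

#' @export
print.AmpliconPanel <- function(x, ...) {
  cat(sprintf("AmpliconPanel with %d loci:\n", length(x)))
  for (locus in x) print(locus)
  invisible(x)
}

#' Write panel references as FASTA
#'
#' @param panel An `AmpliconPanel`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_panel_fasta <- function(panel, path) {
  seqs <- Biostrings::DNAStringSet(vapply(panel, `[[`, "", "reference"))
  names(seqs) <- vapply(panel, `[[`, "", "name")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write the locus panel table as TSV
#'
#' Columns: locus name, imprint class, germ level, comma-separated 1-based CpG
#' positions (coordinates are 1-based inclusive in all reports).
#'
#' @param panel An `AmpliconPanel`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  df <- data.frame(
    name = vapply(panel, `[[`, "", "name"),
    imprint_class = vapply(panel, `[[`, "", "imprint_class"),
    germ_level = vapply(panel, `[[`, 0, "germ_level"),
    n_cpgs = vapply(panel, function(l) length(l$cpg_positions), 0L),
    cpg_positions_1based = vapply(
      panel,
      function(l) paste(l$cpg_positions + 1L, collapse = ","), ""
    ),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' Read a panel back from FASTA + TSV
#'
#' @param fasta_path FASTA of unconverted references.
#' @param tsv_path Panel table written by [write_panel_tsv()].
#' @return An `AmpliconPanel`.
#' @export
read_panel <- function(fasta_path, tsv_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  tab <- read_tsv(tsv_path)
  panel <- lapply(seq_len(nrow(tab)), function(i) {
    nm <- tab$name[i]
    amplicon_locus(
      name = nm,
      imprint_class = tab$imprint_class[i],
      reference = as.character(seqs[[nm]]),
      cpg_positions = as.integer(strsplit(
        tab$cpg_positions_1based[i], ","
      )[[1L]]) - 1L,
      germ_level = as.numeric(tab$germ_level[i])
    )
  })
  names(panel) <- tab$name
  class(panel) <- "AmpliconPanel"
  panel
}
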