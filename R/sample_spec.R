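# Sample specifications for the synthetic cohort generator.

FRACTIONS <- c("SN", "AT", "blood", "sperm", "SCO")
KARYOTYPES <- c("46,XY", "46,XX", "47,XXY")

#' Specify one simulated sample
#'
#' A `SampleSpec` fixes everything the generator needs for one biological
#' sample: its group and cell fraction, karyotype, the true proportion `f` of
#' germ-cell-derived alleles, sequencing depth and noise levels, and any
#' imprinting epimutations to inject into the germ compartment.
#'
#' @param sample_id Unique sample label.
#' @param group `"normal"` or `"KS"` (Klinefelter).
#' @param fraction One of `"SN"` (germ-cell-enriched supernatant), `"AT"`
#'   (attached somatic), `"blood"`, `"sperm"`, `"SCO"` (Sertoli cell-only).
#' @param karyotype `"46,XY"`, `"46,XX"` or `"47,XXY"`.
#' @param germ_fraction True proportion of germ-cell alleles in `[0, 1]`.
#'   Forced to 0 for SCO/blood and 1 for sperm.
#' @param patient_id Patient the sample belongs to (pairs AT and SN fractions
#'   of one patient); defaults to `sample_id`.
#' @param n_reads_per_locus Reads simulated per locus. Default 500.
#' @param conversion_rate Probability that an unmethylated cytosine reads as
#'   thymine (and that a methylated cytosine is correctly retained as
#'   cytosine). Default 0.995.
#' @param seq_error_rate Per-base substitution error probability. Default
#'   0.002.
#' @param epimutations Named numeric vector: locus name -> magnitude `e` in
#'   `[-1, 1]` added to the germ compartment's allele-methylation probability
#'   at that locus (clamped to `[0, 1]`).
#' @param purity_gated Should the 4 % marker purity gate apply to this sample?
#'   Defaults to `TRUE` for normal-group SN fractions (KS SN fractions are
#'   enrichment-only and bypass the gate).
#' @return A list of class `SampleSpec`.
#' @export
sample_spec <- function(sample_id, group = c("normal", "KS"),
                        fraction = FRACTIONS, karyotype = KARYOTYPES,
                        germ_fraction = 0, patient_id = sample_id,
                        n_reads_per_locus = 500L,
                        conversion_rate = 0.995, seq_error_rate = 0.002,
                        epimutations = NULL, purity_gated = NULL) {
  group <- match.arg(group)
  fraction <- match.arg(fraction)
  karyotype <- match.arg(karyotype)
  if (fraction %in% c("SCO", "blood")) germ_fraction <- 0
  if (fraction == "sperm") germ_fraction <- 1
  stopifnot(
    germ_fraction >= 0, germ_fraction <= 1,
    conversion_rate >= 0, conversion_rate <= 1,
    seq_error_rate >= 0, seq_error_rate <= 1,
    n_reads_per_locus >= 1
  )
  if (!is.null(epimutations)) {
    stopifnot(
      !is.null(names(epimutations)),
      all(abs(epimutations) <= 1)
    )
  }
  if (is.null(purity_gated)) {
    purity_gated <- group == "normal" && fraction == "SN"
  }
  structure(
    list(
      sample_id = sample_id, patient_id = patient_id, group = group,
      fraction = fraction, karyotype = karyotype,
      germ_fraction = germ_fraction,
      n_reads_per_locus = as.integer(n_reads_per_locus),
      conversion_rate = conversion_rate, seq_error_rate = seq_error_rate,
      epimutations = epimutations, purity_gated = purity_gated
    ),
    class = "SampleSpec"
  )
}

#' Build the machine-readable sample sheet for a list of specs
#'
#' @param specs List of [sample_spec()] objects.
#' @return data.frame with one row per sample.
#' @export
sample_sheet <- function(specs) {
  data.frame(
    sample_id = vapply(specs, `[[`, "", "sample_id"),
    patient_id = vapply(specs, `[[`, "", "patient_id"),
    group = vapply(specs, `[[`, "", "group"),
    fraction = vapply(specs, `[[`, "", "fraction"),
    karyotype = vapply(specs, `[[`, "", "karyotype"),
    germ_fraction = vapply(specs, `[[`, 0, "germ_fraction"),
    purity_gated = vapply(specs, `[[`, TRUE, "purity_gated"),
    stringsAsFactors = FALSE
  )
}
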