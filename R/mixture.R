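# Germ-cell mixture inference: marker purity gating, germ-cell fraction
# estimation from unmethylated reads, the expected mixture-driven methylation
# shift at imprinted loci, and aberration flagging.

#' Gate germ-cell-enriched fractions on marker purity
#'
#' A germ-cell fraction whose marker-locus (VASA/DDX4 by default) mean
#' methylation exceeds `threshold` percent contains appreciable somatic DNA
#' and is excluded. The gate applies only to samples declared purity-gated in
#' the sample sheet (normal-group SN fractions; KS SN fractions are
#' enrichment-only and bypass the gate). A gated sample without a usable
#' marker summary is flagged unevaluable, never silently included.
#'
#' @param summaries `LocusSummary` data.frame (all samples).
#' @param sheet Sample sheet with columns `sample_id` and `purity_gated`.
#' @param marker Marker locus name. Default `"DDX4"`.
#' @param threshold Exclusion threshold in percent (strict `>`). Default 4.
#' @return List: `included`, `excluded`, `unevaluable` (sample id vectors;
#'   `included` contains every sample not excluded) and `report` (one row per
#'   gated sample with its marker methylation and decision).
#' @export
purity_gate <- function(summaries, sheet, marker = "DDX4", threshold = 4.0) {
  gated_ids <- sheet$sample_id[sheet$purity_gated]
  rows <- summaries[summaries$locus == marker &
    summaries$sample_id %in% gated_ids, , drop = FALSE]
  value <- setNames(rep(NA_real_, length(gated_ids)), gated_ids)
  value[rows$sample_id[rows$n_reads_pass > 0L]] <-
    rows$mean_methylation[rows$n_reads_pass > 0L]
  decision <- ifelse(is.na(value), "unevaluable",
    ifelse(value > threshold, "excluded", "included")
  )
  report <- data.frame(
    sample_id = gated_ids,
    marker = rep(marker, length(gated_ids)),
    marker_methylation = unname(value),
    decision = unname(decision),
    stringsAsFactors = FALSE
  )
  excluded <- gated_ids[decision == "excluded"]
  unevaluable <- gated_ids[decision == "unevaluable"]
  list(
    included = setdiff(sheet$sample_id, c(excluded, unevaluable)),
    excluded = excluded,
    unevaluable = unevaluable,
    report = report
  )
}

#' Estimate the germ-cell fraction of one sample
#'
#' At germ-cell marker loci, somatic alleles are fully methylated and
#' germ-cell alleles fully unmethylated, so the proportion of unmethylated
#' reads estimates the germ-cell fraction `f` directly. The per-locus
#' estimates are combined as a read-count-weighted mean; the 95% confidence
#' interval comes from a seeded nonparametric bootstrap over reads (the
#' resampled per-locus statistic is a mean of binary read labels, drawn as a
#' binomial).
#'
#' @param summaries `LocusSummary` rows of one sample.
#' @param germ_marker_loci Marker loci to use. Default FGFR3, DDX4, RHOXF1.
#' @param n_bootstrap Bootstrap replicates. Default 1000.
#' @param rng_seed Integer seed.
#' @return One-row data.frame (`FractionEstimate`): `sample_id`, `f_hat`,
#'   `ci_low`, `ci_high`, `n_reads_used`, plus `f_<locus>` per-marker
#'   columns. `NA` estimate (with a message) when no marker reads exist.
#' @export
estimate_germ_fraction <- function(summaries,
                                   germ_marker_loci = GERM_MARKER_LOCI,
                                   n_bootstrap = 1000L, rng_seed = 1L) {
  sample_id <- unique(summaries$sample_id)
  stopifnot(length(sample_id) == 1L)
  rows <- summaries[summaries$locus %in% germ_marker_loci &
    summaries$n_reads_pass > 0L, , drop = FALSE]
  per_locus <- setNames(
    rep(NA_real_, length(germ_marker_loci)),
    paste0("f_", germ_marker_loci)
  )
  if (nrow(rows) == 0L) {
    out <- data.frame(
      sample_id = sample_id, f_hat = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, n_reads_used = 0L, stringsAsFactors = FALSE
    )
    return(cbind(out, as.data.frame(as.list(per_locus))))
  }
  per_locus[paste0("f_", rows$locus)] <- rows$p_unmeth
  w <- rows$n_reads_pass
  f_hat <- weighted.mean(rows$p_unmeth, w)
  boot <- with_seed(rng_seed, {
    mat <- vapply(seq_len(nrow(rows)), function(k) {
      rbinom(n_bootstrap, rows$n_reads_pass[k], rows$p_unmeth[k]) /
        rows$n_reads_pass[k]
    }, numeric(n_bootstrap))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = n_bootstrap)
    as.numeric(mat %*% (w / sum(w)))
  })
  ci <- unname(quantile(boot, c(0.025, 0.975), type = 7))
  out <- data.frame(
    sample_id = sample_id,
    f_hat = f_hat,
    ci_low = min(ci[1L], f_hat),
    ci_high = max(ci[2L], f_hat),
    n_reads_used = sum(w),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(as.list(per_locus)))
}

germ_ref_level <- function(locus_or_class) {
  if (inherits(locus_or_class, "AmpliconLocus")) {
    return(100 * locus_or_class$germ_level)
  }
  cls <- match.arg(locus_or_class, c(
    "paternal_imprint", "maternal_imprint", "germ_marker", "x_inactivation"
  ))
  if (cls == "paternal_imprint") 100 else 0
}

#' Expected methylation of a germ-cell-enriched fraction
#'
#' The methylation of a mixed fraction is a linear blend of the somatic
#' reference level `s` and the germ-cell reference level `g` (0% for
#' maternally imprinted DMRs, germ-cell markers and XIST; 100% for the
#' paternally methylated H19 IG-DMR). `s` is inferred from the patient's own
#' somatic AT fraction by inverting the mixture,
#' `s = (m_AT - f_AT * g) / (1 - f_AT)`, which absorbs residual germ cells in
#' AT; the expected supernatant level is then
#' `m_expected = (1 - f_SN) * s + f_SN * g`, clamped to `[0, 100]`.
#'
#' @param locus Either an [amplicon_locus()] (its `germ_level` is used, which
#'   handles secondary DMRs such as MEG3's TSS-DMR) or an imprint class
#'   string.
#' @param karyotype Sample karyotype (kept for interface completeness; the
#'   somatic reference is taken from the AT fraction, so the karyotype does
#'   not enter the computation).
#' @param m_AT Observed AT (somatic) methylation, percent.
#' @param f_AT Germ-cell fraction of the AT sample, in `[0, 1)`.
#' @param f_SN Germ-cell fraction of the SN sample, `f_AT <= f_SN <= 1`.
#' @return Expected SN methylation, percent.
#' @export
expected_methylation <- function(locus, karyotype = "46,XY", m_AT, f_AT, f_SN) {
  if (f_AT >= 1) {
    stop("f_AT must be < 1: the somatic reference is undefined for a pure ",
      "germ-cell AT fraction",
      call. = FALSE
    )
  }
  stopifnot(f_AT >= 0, f_SN >= 0, f_SN <= 1)
  g <- germ_ref_level(locus)
  s <- (m_AT - f_AT * g) / (1 - f_AT)
  clamp((1 - f_SN) * s + f_SN * g, 0, 100)
}

expected_sign <- function(locus) {
  g <- germ_ref_level(locus)
  if (g >= 50) "up" else "down"
}

# Bootstrap means of a per-read fraction vector.
boot_means <- function(fr, n_bootstrap) {
  n <- length(fr)
  idx <- matrix(sample.int(n, n * n_bootstrap, replace = TRUE), nrow = n_bootstrap)
  rowMeans(matrix(fr[idx], nrow = n_bootstrap))
}

#' Assess the methylation shift of one patient at one locus
#'
#' Compares the observed supernatant (SN, germ-cell-enriched) methylation
#' with the level expected from the mixture model given the patient's AT
#' (somatic) methylation and the estimated germ-cell fractions, and flags
#' imprinting aberrations by three rules, checked in order:
#' \describe{
#'   \item{wrong_direction}{the observed AT-to-SN shift opposes the expected
#'     direction while the expected shift magnitude exceeds
#'     `tolerance_delta`;}
#'   \item{no_shift}{the observed shift is within the bootstrap 95% null
#'     width while the expected shift magnitude exceeds `tolerance_delta`;}
#'   \item{magnitude}{the deviation `delta = m_SN - m_expected` exceeds
#'     `tolerance_delta` and the bootstrap 95% CI of `m_SN` excludes
#'     `m_expected`.}
#' }
#'
#' @param at_summary,sn_summary One-row `LocusSummary` of the same locus for
#'   the patient's AT and SN fractions (with `read_fracs`).
#' @param locus The [amplicon_locus()].
#' @param f_AT,f_SN Estimated germ-cell fractions of the two fractions.
#' @param karyotype Patient karyotype (see [expected_methylation()]).
#' @param patient_id Patient label (defaults to the SN sample id).
#' @param tolerance_delta Tolerated deviation, percentage points. Default 10.
#' @param n_bootstrap Bootstrap replicates. Default 1000.
#' @param rng_seed Integer seed.
#' @return One-row data.frame (`ShiftAssessment`): `patient_id`, `locus`,
#'   `m_AT`, `m_SN`, `f_AT`, `f_SN`, `expected_sign`, `m_expected`, `delta`,
#'   `aberrant`, `reason`.
#' @export
assess_shift <- function(at_summary, sn_summary, locus, f_AT, f_SN,
                         karyotype = "46,XY", patient_id = NULL,
                         tolerance_delta = 10, n_bootstrap = 1000L,
                         rng_seed = 1L) {
  stopifnot(
    nrow(at_summary) == 1L, nrow(sn_summary) == 1L,
    at_summary$locus == locus$name, sn_summary$locus == locus$name
  )
  if (is.null(patient_id)) patient_id <- sn_summary$sample_id
  m_AT <- at_summary$mean_methylation
  m_SN <- sn_summary$mean_methylation
  m_exp <- expected_methylation(locus, karyotype, m_AT, f_AT, f_SN)
  sign_exp <- expected_sign(locus)
  d_obs <- m_SN - m_AT
  delta <- m_SN - m_exp
  expected_shift <- m_exp - m_AT

  fr_at <- at_summary$read_fracs[[1L]] * 100
  fr_sn <- sn_summary$read_fracs[[1L]] * 100
  boots <- with_seed(rng_seed, {
    list(
      sn = boot_means(fr_sn, n_bootstrap),
      at = boot_means(fr_at, n_bootstrap)
    )
  })
  sn_ci <- unname(quantile(boots$sn, c(0.025, 0.975)))
  d_boot <- boots$sn - boots$at
  null_width <- unname(quantile(abs(d_boot - d_obs), 0.95))

  aberrant <- FALSE
  reason <- "consistent"
  if (abs(expected_shift) > tolerance_delta &&
    sign(d_obs) != 0 && sign(d_obs) != sign(expected_shift)) {
    aberrant <- TRUE
    reason <- "wrong_direction"
  } else if (abs(expected_shift) > tolerance_delta &&
    abs(d_obs) <= null_width) {
    aberrant <- TRUE
    reason <- "no_shift"
  } else if (abs(delta) > tolerance_delta &&
    (m_exp < sn_ci[1L] || m_exp > sn_ci[2L])) {
    aberrant <- TRUE
    reason <- "magnitude"
  }

  data.frame(
    patient_id = patient_id, locus = locus$name,
    m_AT = m_AT, m_SN = m_SN, f_AT = f_AT, f_SN = f_SN,
    expected_sign = sign_exp, m_expected = m_exp, delta = delta,
    observed_shift = d_obs, null_width = null_width,
    sn_ci_low = sn_ci[1L], sn_ci_high = sn_ci[2L],
    aberrant = aberrant, reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Run the full mixture analysis over a cohort
#'
#' Applies the purity gate, estimates germ-cell fractions for all retained
#' samples, pairs each patient's AT and SN fractions, and assesses every
#' non-marker locus (imprinted DMRs and XIST) for aberrations.
#'
#' @param summaries `LocusSummary` data.frame for the whole cohort (with
#'   `read_fracs`).
#' @param sheet Sample sheet (columns `sample_id`, `patient_id`, `group`,
#'   `fraction`, `karyotype`, `purity_gated`).
#' @param panel An `AmpliconPanel`.
#' @param purity_marker,purity_threshold See [purity_gate()].
#' @param tolerance_delta,n_bootstrap See [assess_shift()].
#' @param rng_seed Integer seed.
#' @return List: `gate` ([purity_gate()] result), `estimates`
#'   (`FractionEstimate` rows for retained samples), `assessments`
#'   (`ShiftAssessment` rows), `skipped` (patients lacking a usable pair).
#' @export
analyze_cohort <- function(summaries, sheet, panel,
                           purity_marker = "DDX4", purity_threshold = 4.0,
                           tolerance_delta = 10, n_bootstrap = 1000L,
                           rng_seed = 1L) {
  gate <- purity_gate(summaries, sheet,
    marker = purity_marker,
    threshold = purity_threshold
  )
  keep <- gate$included
  estimates <- do.call(rbind, c(lapply(seq_along(keep), function(i) {
    estimate_germ_fraction(
      summaries[summaries$sample_id == keep[i], , drop = FALSE],
      n_bootstrap = n_bootstrap,
      rng_seed = derive_seed(rng_seed, "estimate", i)
    )
  }), list(make.row.names = FALSE)))

  assess_loci <- panel[setdiff(names(panel), GERM_MARKER_LOCI)]
  testis <- sheet[sheet$fraction %in% c("AT", "SN") &
    sheet$sample_id %in% keep, , drop = FALSE]
  assessments <- list()
  skipped <- list()
  for (pid in unique(testis$patient_id)) {
    at_id <- testis$sample_id[testis$patient_id == pid & testis$fraction == "AT"]
    sn_id <- testis$sample_id[testis$patient_id == pid & testis$fraction == "SN"]
    if (length(at_id) != 1L || length(sn_id) != 1L) {
      skipped[[pid]] <- "missing AT/SN pair member"
      next
    }
    f_AT <- estimates$f_hat[estimates$sample_id == at_id]
    f_SN <- estimates$f_hat[estimates$sample_id == sn_id]
    if (length(f_SN) != 1L || is.na(f_SN) || length(f_AT) != 1L) {
      skipped[[pid]] <- "no germ-cell fraction estimate"
      next
    }
    if (is.na(f_AT)) f_AT <- 0
    karyo <- sheet$karyotype[sheet$sample_id == sn_id]
    for (locus in assess_loci) {
      at_row <- summaries[summaries$sample_id == at_id &
        summaries$locus == locus$name, , drop = FALSE]
      sn_row <- summaries[summaries$sample_id == sn_id &
        summaries$locus == locus$name, , drop = FALSE]
      if (nrow(at_row) != 1L || nrow(sn_row) != 1L ||
        at_row$n_reads_pass == 0L || sn_row$n_reads_pass == 0L) {
        skipped[[paste(pid, locus$name, sep = ":")]] <- "missing locus summary"
        next
      }
      assessments[[paste(pid, locus$name, sep = ":")]] <- assess_shift(
        at_row, sn_row, locus,
        f_AT = f_AT, f_SN = f_SN,
        karyotype = karyo, patient_id = pid,
        tolerance_delta = tolerance_delta, n_bootstrap = n_bootstrap,
        rng_seed = derive_seed(rng_seed, paste0("assess", pid, locus$name))
      )
    }
  }
  list(
    gate = gate,
    estimates = estimates,
    assessments = do.call(rbind, c(unname(assessments),
      list(make.row.names = FALSE)
    )),
    skipped = skipped
  )
}

#' Structured cohort report
#'
#' Collates the per-patient, per-locus shift assessments, per-group counts of
#' aberrant loci, and the paired AT-to-SN line-plot data.
#'
#' @param analysis Result of [analyze_cohort()].
#' @param sheet The sample sheet.
#' @return List: `assessments` (table), `group_counts` (aberrant flags per
#'   group x locus), `pairs` (plot data: patient, locus, m_AT, m_SN).
#' @export
cohort_report <- function(analysis, sheet) {
  a <- analysis$assessments
  if (is.null(a) || nrow(a) == 0L) {
    return(list(
      assessments = a, group_counts = NULL, pairs = NULL,
      gate = analysis$gate$report, estimates = drop_list_cols(analysis$estimates)
    ))
  }
  grp <- setNames(sheet$group, sheet$patient_id)
  a$group <- unname(grp[a$patient_id])
  counts <- stats::aggregate(aberrant ~ group + locus, data = a, FUN = sum)
  names(counts)[names(counts) == "aberrant"] <- "n_aberrant"
  counts$n_assessed <- stats::aggregate(aberrant ~ group + locus,
    data = a, FUN = length
  )$aberrant
  pairs <- a[, c("patient_id", "group", "locus", "m_AT", "m_SN")]
  list(
    assessments = a,
    group_counts = counts,
    pairs = pairs,
    gate = analysis$gate$report,
    estimates = drop_list_cols(analysis$estimates)
  )
}
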