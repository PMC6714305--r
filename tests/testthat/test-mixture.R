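make_sheet <- function(ids, gated = TRUE, fraction = "SN", group = "normal") {
  data.frame(
    sample_id = ids, patient_id = ids, group = group, fraction = fraction,
    karyotype = "46,XY", purity_gated = gated, stringsAsFactors = FALSE
  )
}

test_that("the purity gate keeps the boundary and flags missing markers", {
  ids <- paste0("S", 1:8)
  meth <- c(3.2, 4.0, 0.5, 1.0, 2.0, 5.1, 7.3, 9.9) # 3 planted above 4%
  summaries <- do.call(rbind, lapply(seq_along(ids), function(i) {
    summary_from_fracs(ids[i], "DDX4", rep(c(1, 0), c(
      round(meth[i] * 10), 1000 - round(meth[i] * 10)
    )))
  }))
  gate <- purity_gate(summaries, make_sheet(ids), threshold = 4.0)
  expect_setequal(gate$excluded, c("S6", "S7", "S8"))
  expect_length(gate$included, 5)
  expect_true("S2" %in% gate$included) # 4.0% retained: strict "higher than"
  expect_true("S1" %in% gate$included)

  # missing marker summary -> unevaluable, not silently included
  summaries2 <- summaries[summaries$sample_id != "S3", ]
  gate2 <- purity_gate(summaries2, make_sheet(ids), threshold = 4.0)
  expect_equal(gate2$unevaluable, "S3")
  expect_false("S3" %in% gate2$included)

  # non-gated samples pass through regardless of marker methylation
  sheet3 <- make_sheet(ids, gated = FALSE, group = "KS")
  gate3 <- purity_gate(summaries, sheet3, threshold = 4.0)
  expect_length(gate3$excluded, 0)
  expect_length(gate3$included, 8)
})

test_that("germ-cell fraction is the weighted unmethylated-read proportion", {
  s <- rbind(
    summary_from_fracs("A", "FGFR3", rep(c(0, 1), c(100, 900))),
    summary_from_fracs("A", "DDX4", rep(c(0, 1), c(100, 900))),
    summary_from_fracs("A", "RHOXF1", rep(c(0, 1), c(100, 900)))
  )
  est <- estimate_germ_fraction(s, rng_seed = 1)
  expect_equal(est$f_hat, 0.10)
  expect_equal(est$f_FGFR3, 0.10)
  expect_equal(est$n_reads_used, 3000)
  expect_lte(est$ci_low, est$f_hat)
  expect_gte(est$ci_high, est$f_hat)

  # pure sperm: all markers fully unmethylated
  sp <- rbind(
    summary_from_fracs("SP", "FGFR3", rep(0, 500)),
    summary_from_fracs("SP", "DDX4", rep(0, 500)),
    summary_from_fracs("SP", "RHOXF1", rep(0, 500))
  )
  expect_equal(estimate_germ_fraction(sp, rng_seed = 1)$f_hat, 1)

  # unequal read counts weight the mean
  uw <- rbind(
    summary_from_fracs("U", "FGFR3", rep(c(0, 1), c(300, 700))), # f=0.3, n=1000
    summary_from_fracs("U", "DDX4", rep(c(0, 1), c(10, 90))) # f=0.1, n=100
  )
  expect_equal(
    estimate_germ_fraction(uw, rng_seed = 1)$f_hat,
    (0.3 * 1000 + 0.1 * 100) / 1100
  )

  # no marker reads: explicit missing state
  none <- summary_from_fracs("X", "H19", rep(1, 10))
  expect_true(is.na(estimate_germ_fraction(none, rng_seed = 1)$f_hat))
})

test_that("expected methylation inverts the somatic mixture correctly", {
  # pure somatic AT at 50%, half-germ SN: maternal DMR drops to 25
  expect_equal(
    expected_methylation("maternal_imprint", "46,XY", m_AT = 50, f_AT = 0, f_SN = 0.5),
    25
  )
  # paternal DMR in pure germ: 100
  expect_equal(
    expected_methylation("paternal_imprint", "46,XY", m_AT = 50, f_AT = 0, f_SN = 1),
    100
  )
  # algebraic inversion: AT keeps 4% germ cells, so s = 100 and SN at f=0.8 -> 20
  expect_equal(
    expected_methylation("germ_marker", "46,XY", m_AT = 96, f_AT = 0.04, f_SN = 0.8),
    20
  )
  expect_error(
    expected_methylation("germ_marker", "46,XY", m_AT = 50, f_AT = 1, f_SN = 1),
    "f_AT"
  )
})

test_that("expected methylation is monotone in the germ fraction", {
  panel <- test_panel()
  f_grid <- seq(0, 1, by = 0.05)
  for (nm in c("MEST", "LIT1", "XIST", "MEG3", "DDX4")) {
    vals <- vapply(f_grid, function(f) {
      expected_methylation(panel[[nm]], "46,XY", m_AT = 60, f_AT = 0, f_SN = f)
    }, 0)
    expect_true(all(diff(vals) <= 0), label = paste(nm, "decreasing"))
  }
  up <- vapply(f_grid, function(f) {
    expected_methylation(panel$H19, "46,XY", m_AT = 50, f_AT = 0, f_SN = f)
  }, 0)
  expect_true(all(diff(up) >= 0))
})

test_that("noise-free mixtures reproduce the expected methylation exactly", {
  panel <- test_panel(seed = 2)
  for (f in c(0, 0.25, 0.5, 0.75, 1)) {
    at <- sample_spec("AT", fraction = "AT", germ_fraction = 0,
      n_reads_per_locus = 400, conversion_rate = 1, seq_error_rate = 0
    )
    sn <- sample_spec("SN", group = "KS", fraction = "SN", germ_fraction = f,
      n_reads_per_locus = 400, conversion_rate = 1, seq_error_rate = 0
    )
    s_at <- call_sample(
      simulate_sample_reads(panel, at, 1, exact_proportions = TRUE)$reads,
      panel, "AT"
    )$summary
    s_sn <- call_sample(
      simulate_sample_reads(panel, sn, 2, exact_proportions = TRUE)$reads,
      panel, "SN"
    )$summary
    for (nm in names(panel)) {
      m_exp <- expected_methylation(panel[[nm]], "46,XY",
        m_AT = s_at$mean_methylation[s_at$locus == nm], f_AT = 0, f_SN = f
      )
      expect_equal(
        s_sn$mean_methylation[s_sn$locus == nm], m_exp,
        tolerance = 1e-12, label = sprintf("f=%.2f %s", f, nm)
      )
    }
  }
})

test_that("shift assessment distinguishes the three aberration patterns", {
  panel <- test_panel()
  lit1 <- panel$LIT1
  h19 <- panel$H19
  set.seed(99)
  at <- summary_from_fracs("P_AT", "LIT1", rbinom(500, 1, 0.5))
  # consistent: SN follows the expected mixture (f_SN = 0.6 -> ~20%)
  sn_ok <- summary_from_fracs("P_SN", "LIT1", rbinom(500, 1, 0.2))
  a_ok <- assess_shift(at, sn_ok, lit1, f_AT = 0, f_SN = 0.6,
    patient_id = "P", rng_seed = 4
  )
  expect_false(a_ok$aberrant)
  expect_equal(a_ok$expected_sign, "down")

  # wrong direction: paternal H19 should rise but falls
  at_h <- summary_from_fracs("P_AT", "H19", rbinom(500, 1, 0.5))
  sn_down <- summary_from_fracs("P_SN", "H19", rbinom(500, 1, 0.3))
  a_wd <- assess_shift(at_h, sn_down, h19, f_AT = 0, f_SN = 0.6,
    patient_id = "P", rng_seed = 4
  )
  expect_true(a_wd$aberrant)
  expect_equal(a_wd$reason, "wrong_direction")
  expect_equal(a_wd$expected_sign, "up")

  # no shift: expected large drop, observed none
  sn_flat <- summary_from_fracs("P_SN", "LIT1", rbinom(500, 1, 0.5))
  a_ns <- assess_shift(at, sn_flat, lit1, f_AT = 0, f_SN = 0.6,
    patient_id = "P", rng_seed = 4
  )
  expect_true(a_ns$aberrant)
  expect_true(a_ns$reason %in% c("no_shift", "wrong_direction"))

  # magnitude: right direction but far beyond the expected level
  sn_over <- summary_from_fracs("P_SN", "LIT1", rbinom(500, 1, 0.02))
  a_mag <- assess_shift(at, sn_over, lit1, f_AT = 0, f_SN = 0.6,
    patient_id = "P", rng_seed = 4
  )
  expect_true(a_mag$aberrant)
  expect_equal(a_mag$reason, "magnitude")
})

test_that("injected epimutations are flagged at the right locus only", {
  panel <- test_panel(seed = 5)
  at <- sample_spec("P_AT", group = "KS", fraction = "AT", karyotype = "47,XXY",
    germ_fraction = 0.02, n_reads_per_locus = 500,
    epimutations = c(MEG3 = 0.8)
  )
  sn <- sample_spec("P_SN", group = "KS", fraction = "SN", karyotype = "47,XXY",
    germ_fraction = 0.5, n_reads_per_locus = 500,
    epimutations = c(MEG3 = 0.8)
  )
  sheet <- rbind(
    data.frame(
      sample_id = "P_AT", patient_id = "P", group = "KS", fraction = "AT",
      karyotype = "47,XXY", purity_gated = FALSE, stringsAsFactors = FALSE
    ),
    data.frame(
      sample_id = "P_SN", patient_id = "P", group = "KS", fraction = "SN",
      karyotype = "47,XXY", purity_gated = FALSE, stringsAsFactors = FALSE
    )
  )
  summaries <- rbind(
    call_sample(simulate_sample_reads(panel, at, 11)$reads, panel, "P_AT")$summary,
    call_sample(simulate_sample_reads(panel, sn, 12)$reads, panel, "P_SN")$summary
  )
  res <- analyze_cohort(summaries, sheet, panel, rng_seed = 3)
  flags <- res$assessments[res$assessments$aberrant, ]
  expect_equal(flags$locus, "MEG3")
  expect_false("LIT1" %in% flags$locus)
})

test_that("moderate epimutations at high germ fractions are detected reliably", {
  panel <- test_panel()[c("FGFR3", "DDX4", "RHOXF1", "MEST", "LIT1")]
  n_sim <- 40
  detected <- 0
  for (r in seq_len(n_sim)) {
    specs <- list(
      sample_spec("P_AT", patient_id = "P", group = "KS", fraction = "AT",
        karyotype = "47,XXY", germ_fraction = 0.02, n_reads_per_locus = 300,
        epimutations = c(MEST = 0.5)
      ),
      sample_spec("P_SN", patient_id = "P", group = "KS", fraction = "SN",
        karyotype = "47,XXY", germ_fraction = 0.5, n_reads_per_locus = 300,
        epimutations = c(MEST = 0.5)
      )
    )
    sim <- simulate_cohort(panel, specs, rng_seed = 300 + r)
    summaries <- do.call(rbind, lapply(sim$sheet$sample_id, function(id) {
      call_sample(sim$reads[[id]], panel, id)$summary
    }))
    res <- analyze_cohort(summaries, sim$sheet, panel, rng_seed = r)
    a <- res$assessments
    if (any(a$aberrant[a$locus == "MEST"])) detected <- detected + 1
    # the intact control locus must stay clean in the vast majority of runs
  }
  expect_gte(detected / n_sim, 0.9)
})

test_that("bootstrap intervals cover a simulated fraction", {
  # moderate-size coverage check; the acceptance suite runs the full design
  panel <- test_panel()[c("FGFR3", "DDX4", "RHOXF1")]
  hits <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    spec <- sample_spec("S", fraction = "SN", germ_fraction = 0.25,
      n_reads_per_locus = 400
    )
    sim <- simulate_sample_reads(panel, spec, rng_seed = 100 + r)
    cs <- call_sample(sim$reads, panel, "S")
    est <- estimate_germ_fraction(cs$summary, rng_seed = r)
    if (est$ci_low <= 0.25 && est$ci_high >= 0.25) hits <- hits + 1
  }
  expect_gte(hits, round(0.8 * n_rep))
})
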