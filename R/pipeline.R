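# End-to-end pipeline: simulate -> call -> gate -> estimate -> assess ->
# group stats, driven by one serializable run configuration.

#' Build a run configuration
#'
#' Collects every tunable of a pipeline run: the master seed (fanned out to
#' per-stage child seeds by stable derivation), panel geometry, noise levels,
#' thresholds and the cohort specification. The configuration serializes
#' losslessly to YAML/JSON.
#'
#' @param seed Master integer seed.
#' @param cohort List of [sample_spec()] objects.
#' @param n_cpgs_per_locus,amplicon_length Panel geometry (defaults 10, 200).
#' @param min_conversion,min_aligned Read QC thresholds (defaults 0.95, 0.8).
#' @param read_class_max_minor Read classification threshold (default 0.1).
#' @param purity_threshold Marker purity gate, percent (default 4).
#' @param purity_marker Marker locus (default `"DDX4"`).
#' @param tolerance_delta Aberration tolerance, percentage points (default
#'   10).
#' @param n_bootstrap Bootstrap replicates (default 1000).
#' @param out_dir Run directory (default `NULL`: in-memory run).
#' @return List of class `RunConfig`.
#' @export
run_config <- function(seed = 1L, cohort = list(),
                       n_cpgs_per_locus = 10L, amplicon_length = 200L,
                       min_conversion = 0.95, min_aligned = 0.8,
                       read_class_max_minor = 0.1,
                       purity_threshold = 4.0, purity_marker = "DDX4",
                       tolerance_delta = 10, n_bootstrap = 1000L,
                       out_dir = NULL) {
  structure(
    list(
      seed = as.integer(seed),
      n_cpgs_per_locus = as.integer(n_cpgs_per_locus),
      amplicon_length = as.integer(amplicon_length),
      min_conversion = min_conversion, min_aligned = min_aligned,
      read_class_max_minor = read_class_max_minor,
      purity_threshold = purity_threshold, purity_marker = purity_marker,
      tolerance_delta = tolerance_delta,
      n_bootstrap = as.integer(n_bootstrap),
      out_dir = out_dir,
      cohort = cohort
    ),
    class = "RunConfig"
  )
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML path.
#' @return `path` / the `RunConfig`.
#' @export
write_config <- function(config, path) {
  lst <- unclass(config)
  lst$cohort <- lapply(config$cohort, function(s) {
    s <- unclass(s)
    if (!is.null(s$epimutations)) {
      s$epimutations <- as.list(s$epimutations)
    }
    s
  })
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  cohort <- lapply(lst$cohort, function(s) {
    epi <- if (!is.null(s$epimutations)) unlist(s$epimutations) else NULL
    sample_spec(
      sample_id = s$sample_id, group = s$group, fraction = s$fraction,
      karyotype = s$karyotype, germ_fraction = s$germ_fraction,
      patient_id = s$patient_id, n_reads_per_locus = s$n_reads_per_locus,
      conversion_rate = s$conversion_rate, seq_error_rate = s$seq_error_rate,
      epimutations = epi, purity_gated = s$purity_gated
    )
  })
  lst$cohort <- NULL
  do.call(run_config, c(lst[setdiff(names(lst), "cohort")], list(cohort = cohort)))
}

#' Demo cohort mirroring the study's sample groups
#'
#' Builds a configuration with the study's cohort shape: for euploid men,
#' five SN, four AT, three SCO, five blood and six sperm samples; for
#' Klinefelter (KS) men, seven blood, three SN and three AT samples from men
#' with germ cells (KS+) and three AT samples from men without. The three
#' KS+ patients carry one injected imprinting anomaly each — H19 losing
#' germline methylation, MEG3 gaining it, MEST flattening to the somatic
#' level — while LIT1 stays intact in all of them.
#'
#' @param seed Master seed.
#' @param n_reads_per_locus Reads per locus per sample. Default 500.
#' @param include_blood_sperm Include the blood and sperm control samples
#'   (not needed for the shift assessment itself). Default `TRUE`.
#' @return A [run_config()].
#' @export
make_demo_cohort <- function(seed = 1L, n_reads_per_locus = 500L,
                             include_blood_sperm = TRUE) {
  specs <- list()
  add <- function(...) specs[[length(specs) + 1L]] <<- sample_spec(...)

  # Normal men: supernatant fractions are germ-cell rich after differential
  # plating; attached fractions keep a small germ-cell residue.
  sn_f <- c(0.98, 0.985, 0.975, 0.99, 0.97)
  at_f <- c(0.05, 0.03, 0.06, 0.04)
  for (i in 1:5) {
    add(
      sample_id = sprintf("N%d_SN", i), patient_id = sprintf("N%d", i),
      group = "normal", fraction = "SN", karyotype = "46,XY",
      germ_fraction = sn_f[i], n_reads_per_locus = n_reads_per_locus
    )
  }
  for (i in 1:4) {
    add(
      sample_id = sprintf("N%d_AT", i), patient_id = sprintf("N%d", i),
      group = "normal", fraction = "AT", karyotype = "46,XY",
      germ_fraction = at_f[i], n_reads_per_locus = n_reads_per_locus
    )
  }
  for (i in 1:3) {
    add(
      sample_id = sprintf("SCO%d", i), patient_id = sprintf("SCO%d", i),
      group = "normal", fraction = "SCO", karyotype = "46,XY",
      n_reads_per_locus = n_reads_per_locus
    )
  }
  if (include_blood_sperm) {
    for (i in 1:5) {
      add(
        sample_id = sprintf("B%d", i), patient_id = sprintf("B%d", i),
        group = "normal", fraction = "blood", karyotype = "46,XY",
        n_reads_per_locus = n_reads_per_locus
      )
    }
    for (i in 1:6) {
      add(
        sample_id = sprintf("SP%d", i), patient_id = sprintf("SP%d", i),
        group = "normal", fraction = "sperm", karyotype = "46,XY",
        n_reads_per_locus = n_reads_per_locus
      )
    }
  }

  # KS+ patients: enrichment without complete separation, one distinct
  # imprinting epimutation injected into the germ compartment of each.
  ks_f_sn <- c(0.40, 0.40, 0.50)
  ks_epi <- list(
    c(H19 = -1.0), # germline methylation lost: decreases instead of increasing
    c(MEG3 = +0.8), # germline methylation gained: increases instead of decreasing
    c(MEST = +0.5) # germ compartment at the somatic level: no change
  )
  for (i in 1:3) {
    add(
      sample_id = sprintf("K%d_SN", i), patient_id = sprintf("K%d", i),
      group = "KS", fraction = "SN", karyotype = "47,XXY",
      germ_fraction = ks_f_sn[i], n_reads_per_locus = n_reads_per_locus,
      epimutations = ks_epi[[i]]
    )
    add(
      sample_id = sprintf("K%d_AT", i), patient_id = sprintf("K%d", i),
      group = "KS", fraction = "AT", karyotype = "47,XXY",
      germ_fraction = 0.02, n_reads_per_locus = n_reads_per_locus,
      epimutations = ks_epi[[i]]
    )
  }
  for (i in 1:3) {
    add(
      sample_id = sprintf("KN%d_AT", i), patient_id = sprintf("KN%d", i),
      group = "KS", fraction = "AT", karyotype = "47,XXY",
      germ_fraction = 0, n_reads_per_locus = n_reads_per_locus
    )
  }
  if (include_blood_sperm) {
    for (i in 1:7) {
      add(
        sample_id = sprintf("KB%d", i), patient_id = sprintf("KB%d", i),
        group = "KS", fraction = "blood", karyotype = "47,XXY",
        n_reads_per_locus = n_reads_per_locus
      )
    }
  }
  run_config(seed = seed, cohort = specs)
}

#' Run the full pipeline from a configuration
#'
#' Stages: panel generation, cohort simulation, per-sample calling and
#' filtering, purity gating, germ-cell fraction estimation, shift assessment,
#' group statistics, report. When `config$out_dir` is set, every stage
#' writes its TSV/JSON outputs there together with a manifest carrying the
#' configuration hash; rerunning the same configuration reproduces the files
#' byte-identically.
#'
#' @param config A [run_config()].
#' @return List: `panel`, `sheet`, `truth`, `summaries`, `analysis`,
#'   `report`, `stats`, and `paths` when writing.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  if (length(config$cohort) == 0L) {
    stop("config contains no cohort samples", call. = FALSE)
  }
  out_dir <- config$out_dir
  writing <- !is.null(out_dir)
  if (writing) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0L)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    message(msg)
  }

  stage <- "panel"
  result <- tryCatch(
    {
      say("stage panel: %d loci, %d CpGs, %d bp", nrow(PANEL_DEF),
        config$n_cpgs_per_locus, config$amplicon_length)
      panel <- make_locus_panel(
        config$n_cpgs_per_locus, config$amplicon_length,
        rng_seed = derive_seed(config$seed, "panel")
      )

      stage <- "simulate"
      say("stage simulate: %d samples", length(config$cohort))
      sim <- simulate_cohort(panel, config$cohort,
        rng_seed = derive_seed(config$seed, "cohort"),
        out_dir = if (writing) file.path(out_dir, "reads") else NULL
      )

      stage <- "call"
      say("stage call: aligning and summarizing")
      calls <- lapply(sim$sheet$sample_id, function(id) {
        call_sample(sim$reads[[id]], panel,
          sample_id = id,
          min_conversion = config$min_conversion,
          min_aligned = config$min_aligned,
          read_class_max_minor = config$read_class_max_minor
        )
      })
      names(calls) <- sim$sheet$sample_id
      summaries <- do.call(rbind, c(unname(lapply(calls, `[[`, "summary")),
        list(make.row.names = FALSE)
      ))

      stage <- "mix"
      say("stage mix: gate, estimate, assess")
      analysis <- analyze_cohort(summaries, sim$sheet, panel,
        purity_marker = config$purity_marker,
        purity_threshold = config$purity_threshold,
        tolerance_delta = config$tolerance_delta,
        n_bootstrap = config$n_bootstrap,
        rng_seed = derive_seed(config$seed, "mix")
      )
      report <- cohort_report(analysis, sim$sheet)

      stage <- "stats"
      say("stage stats: group comparisons")
      stats_res <- compare_groups(summaries, sim$sheet)

      list(
        panel = panel, sheet = sim$sheet, truth = sim$truth,
        reads = sim$reads, summaries = summaries, analysis = analysis,
        report = report, stats = stats_res
      )
    },
    error = function(e) {
      stop(sprintf("pipeline failed at stage '%s': %s", stage,
        conditionMessage(e)), call. = FALSE)
    }
  )

  if (writing) {
    cfg_path <- file.path(out_dir, "config.yaml")
    write_config(config, cfg_path)
    cfg_hash <- config_hash(config)
    paths <- list(config = cfg_path)
    paths$summaries <- write_tsv(
      result$summaries, file.path(out_dir, "locus_summaries.tsv")
    )
    paths$estimates <- write_tsv(
      drop_list_cols(result$analysis$estimates),
      file.path(out_dir, "fraction_estimates.tsv")
    )
    if (!is.null(result$analysis$assessments)) {
      paths$assessments <- write_tsv(
        result$analysis$assessments, file.path(out_dir, "assessments.tsv")
      )
    }
    if (!is.null(result$stats$table)) {
      paths$stats <- write_tsv(
        result$stats$table, file.path(out_dir, "group_stats.tsv")
      )
    }
    paths$gate <- write_tsv(
      result$analysis$gate$report, file.path(out_dir, "purity_gate.tsv")
    )
    jsonlite::write_json(
      c(list(config_hash = cfg_hash), result$report["group_counts"],
        list(gate = result$report$gate)),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    paths$report <- file.path(out_dir, "report.json")
    manifest <- data.frame(
      file = basename(unlist(paths)),
      config_hash = cfg_hash,
      stringsAsFactors = FALSE
    )
    paths$manifest <- write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
    result$paths <- paths
  }
  result
}

# Deterministic hash of the serialized configuration (order-stable; paths
# excluded so the hash identifies the scientific run, not its location).
config_hash <- function(config) {
  lst <- unclass(config)
  lst$out_dir <- NULL
  ser <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA,
    null = "null", force = TRUE)
  sum(utf8ToInt(as.character(ser)) * (seq_len(nchar(ser)) %% 97 + 1)) %% 1e9
}
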