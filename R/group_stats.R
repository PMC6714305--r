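# Group comparison machinery: optional log transform toward normality,
# one-way ANOVA, pairwise Welch t tests with Holm correction, and the
# letter-coded significance display used on per-locus box plots.

#' Log-transform group values when normality fails
#'
#' Runs a Shapiro-Wilk test per group (groups with fewer than 3 values are
#' skipped and cannot trigger the transform); if any tested group departs
#' from normality at `alpha_normality`, all groups are transformed
#' `x -> log(x + 0.5)` (the offset handles exact zeros). Reported summaries
#' stay on the untransformed percent scale; the transform only feeds the
#' tests.
#'
#' @param values_by_group Named list of numeric vectors (percents).
#' @param alpha_normality Normality test level. Default 0.05.
#' @return List: `values` (possibly transformed), `log_transformed` flag,
#'   `shapiro_p` per group.
#' @export
maybe_log_transform <- function(values_by_group, alpha_normality = 0.05) {
  p <- vapply(values_by_group, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3L || length(unique(v)) == 1L) {
      return(NA_real_)
    }
    shapiro.test(v)$p.value
  }, numeric(1L))
  fired <- any(!is.na(p) & p < alpha_normality)
  values <- if (fired) {
    lapply(values_by_group, function(v) log(v + 0.5))
  } else {
    values_by_group
  }
  list(values = values, log_transformed = fired, shapiro_p = p)
}

#' One-way ANOVA plus Holm-corrected pairwise t tests
#'
#' Fits a one-way ANOVA across the groups, then runs all pairwise two-sided
#' t tests (Welch by default) and adjusts the pairwise p values by Holm's
#' step-down procedure (the family is the set of pairwise comparisons of the
#' panel at hand).
#'
#' @param values_by_group Named list of numeric vectors (at least 2 groups
#'   with at least 2 values each).
#' @param welch Use Welch (unequal-variance) t tests. Default `TRUE`.
#' @param alpha_normality Passed to [maybe_log_transform()]; set to 0 to
#'   disable the transform.
#' @return List of class `GroupComparison`: `groups` (raw-scale values),
#'   `group_means` (raw scale), `log_transformed`, `anova_p`, `pairwise`
#'   (data.frame: group_i, group_j, p_raw, p_holm).
#' @export
anova_pairwise <- function(values_by_group, welch = TRUE,
                           alpha_normality = 0.05) {
  stopifnot(length(values_by_group) >= 2L)
  if (any(vapply(values_by_group, length, 0L) < 2L)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (all(vapply(values_by_group, sd, 0) == 0)) {
    stop("zero within-group variance in every group: t tests undefined",
      call. = FALSE
    )
  }
  tr <- maybe_log_transform(values_by_group, alpha_normality)
  vals <- tr$values
  df <- data.frame(
    y = unlist(vals, use.names = FALSE),
    g = factor(rep(names(vals), vapply(vals, length, 0L)))
  )
  anova_p <- summary(aov(y ~ g, data = df))[[1L]][["Pr(>F)"]][1L]

  pairs <- combn(names(vals), 2L)
  p_raw <- apply(pairs, 2L, function(p) {
    a <- vals[[p[1L]]]
    b <- vals[[p[2L]]]
    if (sd(a) == 0 && sd(b) == 0) {
      if (mean(a) == mean(b)) {
        return(1)
      }
      return(0)
    }
    t.test(a, b, var.equal = !welch)$p.value
  })
  pairwise <- data.frame(
    group_i = pairs[1L, ], group_j = pairs[2L, ],
    p_raw = p_raw,
    p_holm = p.adjust(p_raw, method = "holm"),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      groups = values_by_group,
      group_means = vapply(values_by_group, mean, 0),
      log_transformed = tr$log_transformed,
      shapiro_p = tr$shapiro_p,
      anova_p = anova_p,
      pairwise = pairwise
    ),
    class = "GroupComparison"
  )
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf(
    "GroupComparison: %d groups, ANOVA p = %.3g%s\n",
    length(x$groups), x$anova_p,
    if (x$log_transformed) " (log-transformed)" else ""
  ))
  print(x$pairwise)
  invisible(x)
}

#' Letter-coded significance against reference groups
#'
#' Each reference group gets one letter (first reference `a`, second `b`,
#' ...). For every group, the reference's letter is appended once, twice or
#' three times when the Holm-adjusted p value of the pairwise comparison is
#' below 0.05, 0.005 or 0.001 respectively, concatenated in reference order
#' (e.g. `"aaab"`: p < 0.001 vs the first reference, p < 0.05 vs the
#' second).
#'
#' @param pairwise Pairwise table from [anova_pairwise()] (columns `group_i`,
#'   `group_j`, `p_holm`).
#' @param reference_groups Ordered reference group labels (at most 26).
#' @return Named character vector: group -> letter code (empty string when
#'   nothing is significant).
#' @export
letter_codes <- function(pairwise, reference_groups) {
  if (length(reference_groups) > length(letters)) {
    stop("more reference groups than available letters", call. = FALSE)
  }
  groups <- unique(c(pairwise$group_i, pairwise$group_j))
  codes <- setNames(rep("", length(groups)), groups)
  for (g in groups) {
    code <- ""
    for (k in seq_along(reference_groups)) {
      ref <- reference_groups[k]
      if (ref == g) next
      sel <- (pairwise$group_i == g & pairwise$group_j == ref) |
        (pairwise$group_i == ref & pairwise$group_j == g)
      if (!any(sel)) next
      p <- pairwise$p_holm[sel][1L]
      reps <- if (p < 0.001) 3L else if (p < 0.005) 2L else if (p < 0.05) 1L else 0L
      code <- paste0(code, strrep(letters[k], reps))
    }
    codes[g] <- code
  }
  codes
}

#' Compare group methylation per locus across a cohort
#'
#' For every locus, collects per-sample mean methylation by group (the
#' grouping column of the sample sheet, by default `fraction`), applies the
#' normality-driven log transform, ANOVA and Holm-corrected pairwise t tests,
#' and attaches letter codes.
#'
#' @param summaries `LocusSummary` data.frame.
#' @param sheet Sample sheet.
#' @param group_col Sheet column holding the group label. Default
#'   `"fraction"`.
#' @param reference_groups Ordered comparator groups for [letter_codes()];
#'   defaults to all groups in sheet order.
#' @param min_group_n Minimum samples per group to include it. Default 2.
#' @param welch See [anova_pairwise()].
#' @return List per locus: the `GroupComparison` plus `letters`; and a tidy
#'   `table` data.frame (locus, group, n, mean, letters, anova_p,
#'   log_transformed).
#' @export
compare_groups <- function(summaries, sheet, group_col = "fraction",
                           reference_groups = NULL, min_group_n = 2L,
                           welch = TRUE) {
  grp <- setNames(sheet[[group_col]], sheet$sample_id)
  res <- list()
  rows <- list()
  for (loc in unique(summaries$locus)) {
    sub <- summaries[summaries$locus == loc &
      summaries$n_reads_pass > 0L, , drop = FALSE]
    values <- split(sub$mean_methylation, grp[sub$sample_id])
    values <- values[vapply(values, length, 0L) >= min_group_n]
    if (length(values) < 2L) next
    refs <- if (is.null(reference_groups)) {
      intersect(unique(grp), names(values))
    } else {
      intersect(reference_groups, names(values))
    }
    cmp <- anova_pairwise(values, welch = welch)
    cmp$letters <- letter_codes(cmp$pairwise, refs)
    res[[loc]] <- cmp
    rows[[loc]] <- data.frame(
      locus = loc,
      group = names(values),
      n = vapply(values, length, 0L),
      mean_methylation = vapply(values, mean, 0),
      letters = unname(cmp$letters[names(values)]),
      anova_p = cmp$anova_p,
      log_transformed = cmp$log_transformed,
      stringsAsFactors = FALSE
    )
  }
  list(
    comparisons = res,
    table = do.call(rbind, c(unname(rows), list(make.row.names = FALSE)))
  )
}
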