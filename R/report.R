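# Pretty (ASCII) reporting names for metric columns.
METRIC_PRETTY <- c(
  extra_acbf = "ExtraACBF (ml/min)", intra_acbf = "IntraACBF (ml/min)",
  extra_vcbf = "ExtraVCBF (ml/min)", intra_vcbf = "IntraVCBF (ml/min)",
  alpha_extra = "alphaExtra", alpha_intra = "alphaIntra",
  extra_blood_sv = "Extra blood SV (ml/cc)",
  intra_blood_sv = "Intra blood SV (ml/cc)",
  spinal_csf_sv = "Spinal CSF SV (ml/cc)",
  aqueductal_csf_sv = "Aqueductal CSF SV (ml/cc)",
  extra_arterial_pi = "Extra arterial PI", intra_arterial_pi = "Intra arterial PI",
  extra_venous_pi = "Extra Venous PI", intra_venous_pi = "Intra Venous PI",
  heart_rate = "Heart rate (beats/min)")

# Extra-vs-intra paired pairs reported within each group.
PAIRED_PAIRS <- list(
  c("extra_acbf", "intra_acbf"), c("extra_vcbf", "intra_vcbf"),
  c("alpha_extra", "alpha_intra"), c("extra_blood_sv", "intra_blood_sv"),
  c("extra_arterial_pi", "intra_arterial_pi"),
  c("extra_venous_pi", "intra_venous_pi"))

# Apply the outlier rule to one metric column of a cohort table, per group.
# Returns the table with outliers set NA plus an exclusion log.
apply_outlier_rule <- function(table, metric, k = 1.5) {
  log <- NULL
  for (g in unique(table$group)) {
    idx <- which(table$group == g)
    vals <- table[[metric]][idx]
    if (sum(!is.na(vals)) < 4L) next
    ex <- exclude_outliers(vals, k = k)
    if (length(ex$excluded)) {
      log <- rbind(log, data.frame(
        subject = table$subject[idx[ex$excluded]], group = g, metric = metric,
        value = vals[ex$excluded],
        lower = ex$bounds[1], upper = ex$bounds[2]))
      table[[metric]][idx[ex$excluded]] <- NA
    }
  }
  list(table = table, log = log)
}

#' Cohort summary report: group statistics, comparisons, correlations
#'
#' Produces the study's summary layer from a per-subject metrics table:
#' per-metric outlier exclusion (mean +/- 1.5 IQR, per group), group
#' mean +/- SD (min-max), between-group independent comparisons,
#' within-group paired extracranial-vs-intracranial comparisons, the
#' correlation panel (aqueductal vs spinal CSF stroke volume; spinal CSF SV
#' vs extra- and intracranial blood SV, per group), and derived ratios
#' (aqueductal/spinal SV in %, venous drainage fractions VCBF/ACBF in %,
#' and the elderly sinus-vs-jugular drainage deficit). No multiple-testing
#' correction is applied (single-threshold p < 0.05 design).
#'
#' @param table `data.frame` with `subject`, `group` and metric columns.
#' @param exclude apply the outlier rule before summarising (default TRUE).
#' @return List of class `cohort_report`: `summary`, `paired`,
#'   `correlations`, `ratios`, `exclusions` data.frames.
#' @export
build_report <- function(table, exclude = TRUE) {
  groups <- unique(table$group)
  if (length(groups) < 1L || nrow(table) == 0L) stop("empty cohort table")
  metrics <- intersect(METRIC_NAMES, names(table))

  exclusions <- NULL
  if (exclude) {
    for (m in metrics) {
      res <- apply_outlier_rule(table, m)
      table <- res$table
      exclusions <- rbind(exclusions, res$log)
    }
  }

  fmt <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return("-")
    sprintf("%.3g +/- %.3g (%.3g-%.3g)", mean(v), stats::sd(v), min(v), max(v))
  }
  two_groups <- length(groups) == 2L
  summary <- NULL
  for (m in metrics) {
    row <- data.frame(parameter = METRIC_PRETTY[[m]], metric = m)
    for (g in groups) {
      v <- table[[m]][table$group == g]
      row[[paste0(g, "_summary")]] <- fmt(v)
      row[[paste0(g, "_mean")]] <- mean(v, na.rm = TRUE)
      row[[paste0(g, "_sd")]] <- stats::sd(v, na.rm = TRUE)
    }
    if (two_groups) {
      cmp <- tryCatch(compare_groups(table, m, "independent"),
                      error = function(e) NULL)
      row$p_between <- if (is.null(cmp)) NA_real_ else cmp$p
      row$test_between <- if (is.null(cmp)) NA_character_ else cmp$test
      row$stars_between <- if (is.null(cmp)) NA_character_ else cmp$stars
    } else {
      row$p_between <- NA_real_
      row$test_between <- "not applicable (single group)"
      row$stars_between <- NA_character_
    }
    summary <- rbind(summary, row)
  }

  paired <- NULL
  for (pp in PAIRED_PAIRS) {
    if (!all(pp %in% metrics)) next
    for (g in groups) {
      cmp <- tryCatch(compare_groups(table, pp[1], "paired", pp[2], group = g),
                      error = function(e) NULL)
      if (is.null(cmp)) next
      paired <- rbind(paired, data.frame(
        group = g, pair = sprintf("%s vs %s", METRIC_PRETTY[[pp[1]]],
                                  METRIC_PRETTY[[pp[2]]]),
        test = cmp$test, p = cmp$p, stars = cmp$stars, n = cmp$n))
    }
  }

  corr_pairs <- list(c("aqueductal_csf_sv", "spinal_csf_sv"),
                     c("spinal_csf_sv", "extra_blood_sv"),
                     c("spinal_csf_sv", "intra_blood_sv"))
  correlations <- NULL
  for (cp in corr_pairs) {
    if (!all(cp %in% metrics)) next
    for (g in groups) {
      cr <- tryCatch(correlate(table, cp[1], cp[2], group = g),
                     error = function(e) NULL)
      if (is.null(cr)) next
      correlations <- rbind(correlations, data.frame(
        group = g, pair = paste(cp[1], "~", cp[2]),
        r = cr$r, p = cr$p, n = cr$n, strength = cr$strength))
    }
  }

  gm <- function(m, g) mean(table[[m]][table$group == g], na.rm = TRUE)
  ratios <- NULL
  for (g in groups) {
    ratios <- rbind(ratios, data.frame(
      group = g,
      ratio = c("aqueductal/spinal CSF SV (%)",
                "sinus drainage IntraVCBF/IntraACBF (%)",
                "jugular drainage ExtraVCBF/ExtraACBF (%)",
                "sinus-vs-jugular deficit (ExtraVCBF-IntraVCBF)/ExtraVCBF (%)"),
      value = c(100 * gm("aqueductal_csf_sv", g) / gm("spinal_csf_sv", g),
                100 * gm("intra_vcbf", g) / gm("intra_acbf", g),
                100 * gm("extra_vcbf", g) / gm("extra_acbf", g),
                100 * (gm("extra_vcbf", g) - gm("intra_vcbf", g)) /
                  gm("extra_vcbf", g))))
  }

  structure(list(summary = summary, paired = paired,
                 correlations = correlations, ratios = ratios,
                 exclusions = exclusions,
                 footer = "p < 0.05 throughout; no multiple-testing correction"),
            class = "cohort_report")
}

#' Write a cohort report to disk
#'
#' Writes `summary.csv`, `paired.csv`, `correlations.csv`, `ratios.csv`,
#' `exclusions.csv` and a human-readable `report.md` under `dir`.
#'
#' @param report a [build_report()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("summary", "paired", "correlations", "ratios", "exclusions")) {
    df <- report[[nm]]
    if (is.null(df)) df <- data.frame()
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  md <- c("# Cohort flow report", "",
          "## Group summaries and between-group tests", "",
          knit_table(report$summary[, setdiff(names(report$summary), "metric")]),
          "", "## Extra vs intra paired comparisons", "",
          knit_table(report$paired),
          "", "## Correlation panel", "",
          knit_table(report$correlations),
          "", "## Derived ratios", "",
          knit_table(report$ratios), "",
          paste0("_", report$footer, "_"))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

# Minimal markdown table writer (no knitr dependency).
knit_table <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return("(none)")
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r)
    paste0("| ", paste(vapply(r, function(x)
      if (is.na(x)) "-" else format(x, digits = 4), ""), collapse = " | "), " |"))
  c(hdr, sep, rows)
}
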