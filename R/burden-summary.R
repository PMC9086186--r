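#' Cohort-level burden summary
#'
#' Derives per-sample rates and class percentages from a per-sample count
#' table, aggregates them into control vs treated group means +/- SD
#' (n - 1), computes the treated/control fold change of the total
#' clean-base mutation rate, and runs the standard group comparisons.
#' This is the single summary layer shared by the full pipeline
#' ([summarize_samples()]) and the published-table fixture path
#' ([summarize_burden_tables()]).
#'
#' @param per_sample Data frame with one row per sample. Required:
#'   `sample_id`, `group` (one of control / treated_large /
#'   treated_normal / treated_small). Count columns used when present:
#'   `n_snp`, `n_transition`, `n_transversion`, `n_exonic`, `n_intronic`,
#'   `n_syn`, `n_nonsyn`, `n_stopgain`, `n_stoploss`, `n_indel`,
#'   `n_indel_cds`, `clean_bases`. Missing columns simply leave the
#'   dependent metrics `NA`.
#' @param compare_metrics Metrics to test with [compare_groups()]
#'   (control vs all treated pooled).
#' @return Object of class `burden_summary`: list with `per_sample`
#'   (augmented with derived metrics), `group_stats`, `fold_change`,
#'   `fold_rounded`, and `comparisons`.
#' @export
burden_summary <- function(per_sample,
                           compare_metrics = c("rate_total", "pct_exonic",
                                               "pct_nonsyn", "pct_syn",
                                               "ts_tv")) {
  stop_if_not(all(c("sample_id", "group") %in% names(per_sample)),
              "per_sample needs sample_id and group columns")
  stop_if_not(all(per_sample$group %in% COHORT_GROUPS),
              "unknown group label(s)")
  ps <- per_sample
  col <- function(nm) if (nm %in% names(ps)) ps[[nm]] else rep(NA_real_, nrow(ps))

  if (!"ts_tv" %in% names(ps)) {
    ps$ts_tv <- ifelse(col("n_transversion") > 0,
                       col("n_transition") / col("n_transversion"), NA_real_)
  }
  cb <- col("clean_bases")
  ps$rate_snp <- ifelse(cb > 0, 100 * col("n_snp") / cb, NA_real_)
  ps$rate_indel <- ifelse(cb > 0, 100 * col("n_indel") / cb, NA_real_)
  ps$rate_total <- ps$rate_snp + ps$rate_indel
  ps$pct_exonic <- class_percentage(col("n_exonic"), col("n_snp"))
  ps$pct_intronic <- class_percentage(col("n_intronic"), col("n_snp"))
  ps$pct_syn <- class_percentage(col("n_syn"), col("n_snp"))
  ps$pct_nonsyn <- class_percentage(col("n_nonsyn"), col("n_snp"))
  ps$pct_stop <- class_percentage(col("n_stopgain") + col("n_stoploss"),
                                  col("n_snp"))
  ps$pct_indel_cds <- class_percentage(col("n_indel_cds"), col("n_indel"))
  ps$treatment <- ifelse(ps$group == "control", "control", "treated")

  metrics <- c("n_snp", "n_transition", "n_transversion", "n_indel",
               "n_indel_cds", "ts_tv", "rate_snp", "rate_indel", "rate_total",
               "pct_exonic", "pct_intronic", "pct_syn", "pct_nonsyn",
               "pct_stop", "pct_indel_cds")
  metrics <- metrics[metrics %in% names(ps)]
  group_stats <- do.call(rbind, lapply(metrics, function(m) {
    group_aggregate(ps[[m]], ps$treatment, metric = m)
  }))

  gm <- function(metric, grp) {
    i <- group_stats$metric == metric & group_stats$group == grp
    if (any(i)) group_stats$mean[i][1] else NA_real_
  }
  fc <- {
    tr <- gm("rate_total", "treated"); ct <- gm("rate_total", "control")
    if (!is.na(tr) && !is.na(ct) && ct > 0) fold_change(tr, ct) else NA_real_
  }

  comparisons <- list()
  for (m in compare_metrics) {
    v <- ps[[m]]
    if (is.null(v) || anyNA(v)) next
    if (length(unique(ps$treatment)) < 2 || any(table(ps$treatment) < 2)) next
    comparisons[[m]] <- compare_groups(v, ps$treatment, metric = m)
  }

  structure(list(per_sample = ps, group_stats = group_stats,
                 fold_change = fc,
                 fold_rounded = if (is.na(fc)) NA else rounded_fold(fc),
                 comparisons = comparisons),
            class = "burden_summary")
}

#' @export
print.burden_summary <- function(x, ...) {
  gs <- x$group_stats
  fmt <- function(metric, digits) {
    i <- gs$metric == metric
    if (!any(i)) return(invisible(NULL))
    rows <- gs[i, ]
    cat(sprintf("  %-14s %s\n", metric,
                paste(sprintf("%s %s +/- %s (n=%d)", rows$group,
                              formatC(rows$mean, format = "f", digits = digits,
                                      big.mark = ","),
                              formatC(rows$sd, format = "f", digits = digits,
                                      big.mark = ","),
                              rows$n), collapse = " | ")))
  }
  cat(sprintf("<burden_summary> %d samples (%d control, %d treated)\n",
              nrow(x$per_sample), sum(x$per_sample$treatment == "control"),
              sum(x$per_sample$treatment == "treated")))
  cat("Group means (sample SD, n-1):\n")
  fmt("n_snp", 0); fmt("n_indel", 0); fmt("ts_tv", 2)
  fmt("rate_snp", 6); fmt("rate_indel", 6); fmt("rate_total", 6)
  fmt("pct_exonic", 2); fmt("pct_syn", 2); fmt("pct_nonsyn", 2)
  fmt("pct_stop", 3); fmt("pct_indel_cds", 2)
  if (!is.na(x$fold_change)) {
    cat(sprintf("Fold change (treated/control total rate): %.4g (~%dx)\n",
                x$fold_change, x$fold_rounded))
  }
  for (cmp in x$comparisons) {
    cat(sprintf("  %s: %s p = %.4g%s\n", cmp$metric, cmp$test, cmp$p_value,
                if (cmp$significant) " *" else ""))
  }
  invisible(x)
}

#' Packaged bay-scallop EMS cohort summary tables
#'
#' Per-sample summary tables from a published whole-genome resequencing
#' screen of EMS-mutagenised bay scallops (4 untreated controls, 12
#' treated animals: 5 largest, 5 normal-sized, 2 smallest), shipped as
#' plain TSVs. They carry, per sample: cohort membership and shell sizes
#' (`samples`), clean-base totals (`sequencing`), raw and
#' control-filtered ("unique") SNP counts with Ts/Tv and region counts
#' (`snp_raw`, `snp_unique`), coding-effect counts (`snp_effects`), and
#' raw / unique InDel counts with CDS splits (`indel_raw`,
#' `indel_unique`).
#'
#' @return Named list of data frames.
#' @export
scallop_cohort_tables <- function() {
  dir <- system.file("extdata", "scallop_cohort", package = "mutburden",
                     mustWork = TRUE)
  rd <- function(f) utils::read.table(file.path(dir, f), header = TRUE,
                                      sep = "\t", stringsAsFactors = FALSE)
  list(samples = rd("samples.tsv"), sequencing = rd("sequencing.tsv"),
       snp_raw = rd("snp_raw.tsv"), snp_unique = rd("snp_unique.tsv"),
       snp_effects = rd("snp_effects.tsv"), indel_raw = rd("indel_raw.tsv"),
       indel_unique = rd("indel_unique.tsv"))
}

#' Burden summary from the packaged cohort tables
#'
#' Rebuilds the per-sample count table from the packaged summary tables
#' (see [scallop_cohort_tables()]) and feeds it through the same
#' [burden_summary()] layer as the full pipeline, so every published
#' group statistic (mean unique SNP/InDel numbers, clean-base mutation
#' rates, the ~9x fold change, exonic and nonsynonymous percentages) is
#' recomputed rather than quoted.
#'
#' @param tables A list as returned by [scallop_cohort_tables()].
#' @return A [burden_summary()] object.
#' @export
summarize_burden_tables <- function(tables = scallop_cohort_tables()) {
  m <- function(df, col) df[[col]][match(ids, df$sample_id)]
  ids <- tables$samples$sample_id
  per_sample <- data.frame(
    sample_id = ids,
    group = tables$samples$group,
    n_snp = m(tables$snp_unique, "snp_number"),
    n_transition = m(tables$snp_unique, "transition"),
    n_transversion = m(tables$snp_unique, "transversion"),
    n_exonic = m(tables$snp_unique, "exonic"),
    n_intronic = m(tables$snp_unique, "intronic"),
    n_syn = m(tables$snp_effects, "synonymous"),
    n_nonsyn = m(tables$snp_effects, "nonsynonymous"),
    n_stopgain = m(tables$snp_effects, "stopgain"),
    n_stoploss = m(tables$snp_effects, "stoploss"),
    n_indel = m(tables$indel_unique, "genome_total"),
    n_indel_cds = m(tables$indel_unique, "cds_total"),
    clean_bases = m(tables$sequencing, "clean_bases"),
    stringsAsFactors = FALSE)
  burden_summary(per_sample)
}
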