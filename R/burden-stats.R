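#' Clean-base-normalized mutation rate
#'
#' The per-sample mutation rate in percent: `100 * n / clean_bases`. The
#' denominator is the sample's total post-QC sequenced bases, so rates
#' are comparable across samples with different sequencing depth.
#'
#' @param n Variant count.
#' @param clean_bases Clean-base total (bp), must be positive.
#' @return Rate in percent.
#' @examples
#' mutation_rate(144157, 10730101234)  # 0.001343...
#' @export
mutation_rate <- function(n, clean_bases) {
  stop_if_not(all(clean_bases > 0), "clean_bases must be > 0")
  100 * n / clean_bases
}

#' Percentage of a variant class
#'
#' `100 * numerator / denominator`; `NA` when the denominator is zero
#' (undefined, not an error, so per-sample tables never crash on empty
#' classes).
#'
#' @param numerator,denominator Counts.
#' @return Percent, or `NA` where `denominator == 0`.
#' @export
class_percentage <- function(numerator, denominator) {
  ifelse(denominator > 0, 100 * numerator / denominator, NA_real_)
}

#' Fold change between group mean rates
#'
#' @param rate_treated,rate_control Group mean rates (same units).
#' @return The plain ratio. `rounded_fold()` gives the nearest integer.
#' @export
fold_change <- function(rate_treated, rate_control) {
  stop_if_not(all(rate_control > 0), "control rate must be > 0")
  rate_treated / rate_control
}

#' @rdname fold_change
#' @param fold A fold change.
#' @export
rounded_fold <- function(fold) round(fold)

#' Per-sample burden summary
#'
#' Tallies one sample's filtered, annotated calls into the per-sample
#' row of the burden tables: SNP/InDel counts, transition/transversion
#' split and Ts/Tv, region counts (over SNPs, as in the published table
#' layout), coding-effect counts, CDS InDel count, and clean-base
#' mutation rates. Ts/Tv is `NA` when there are no transversions.
#'
#' @param sample A [sample_variant_set()] whose calls carry `region` and
#'   `effect` columns ([annotate_variants()]), with `clean_bases` set.
#' @return One-row data frame.
#' @export
sample_summary <- function(sample) {
  stop_if_not(inherits(sample, "sample_variant_set"),
              "sample must be a sample_variant_set")
  calls <- sample$calls
  stop_if_not(all(c("region", "effect") %in% names(calls)),
              "calls must be annotated (region/effect columns)")
  snp <- calls[calls$vtype == "SNP", , drop = FALSE]
  indel <- calls[calls$vtype != "SNP", , drop = FALSE]
  n_ts <- if (nrow(snp)) sum(is_transition(snp$ref, snp$alt)) else 0L
  n_tv <- nrow(snp) - n_ts
  cb <- sample$clean_bases
  data.frame(
    sample_id = sample$sample_id,
    group = sample$group,
    n_snp = nrow(snp),
    n_transition = n_ts,
    n_transversion = n_tv,
    ts_tv = if (n_tv > 0) n_ts / n_tv else NA_real_,
    n_exonic = sum(snp$region == "exonic"),
    n_intronic = sum(snp$region == "intronic"),
    n_upstream = sum(snp$region == "upstream"),
    n_intergenic = sum(snp$region == "intergenic"),
    n_syn = sum(snp$effect %in% "synonymous"),
    n_nonsyn = sum(snp$effect %in% "nonsynonymous"),
    n_stopgain = sum(snp$effect %in% "stopgain"),
    n_stoploss = sum(snp$effect %in% "stoploss"),
    n_indel = nrow(indel),
    n_indel_cds = sum(indel$effect %in% "cds_indel"),
    clean_bases = cb,
    rate_snp = if (is.na(cb)) NA_real_ else mutation_rate(nrow(snp), cb),
    rate_indel = if (is.na(cb)) NA_real_ else mutation_rate(nrow(indel), cb),
    rate_total = if (is.na(cb)) NA_real_ else mutation_rate(nrow(calls), cb),
    stringsAsFactors = FALSE)
}

#' @rdname sample_summary
#' @param cohort Named list of annotated [sample_variant_set()] objects.
#' @export
summarize_samples <- function(cohort) {
  out <- do.call(rbind, lapply(cohort, sample_summary))
  rownames(out) <- NULL
  out
}

#' Group mean and standard deviation of a metric
#'
#' Sample standard deviation (n - 1 denominator) throughout; `sd` is
#' `NA` for singleton groups. No rounding is applied here — presentation
#' rounding happens in print methods only.
#'
#' @param values Numeric vector of per-sample values.
#' @param groups Character/factor vector of group labels, same length.
#' @param metric Metric name recorded in the output.
#' @return Data frame with `group`, `metric`, `mean`, `sd`, `n`.
#' @export
group_aggregate <- function(values, groups, metric = "value") {
  stop_if_not(length(values) == length(groups),
              "values and groups must have equal length")
  keep <- !is.na(values)
  values <- values[keep]; groups <- as.character(groups)[keep]
  gs <- unique(groups)
  out <- do.call(rbind, lapply(gs, function(g) {
    v <- values[groups == g]
    data.frame(group = g, metric = metric, mean = mean(v),
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

safe_p <- function(expr) tryCatch(expr, error = function(e) NA_real_)

normality_p <- function(x) {
  c(shapiro = safe_p(stats::shapiro.test(x)$p.value),
    ks = safe_p(nortest::lillie.test(x)$p.value))
}

#' Compare a metric between groups
#'
#' The statistical workflow used for all group contrasts: per-group
#' normality checks (Shapiro-Wilk and Lilliefors-corrected
#' Kolmogorov-Smirnov), Levene's test for homogeneity of variance
#' (centered at the mean), then for two groups a Student's t test when
#' variances are homogeneous (Levene p > 0.05) or Welch's t otherwise,
#' and for more than two groups one-way ANOVA followed by Tukey's HSD.
#' If normality fails in any group, a square-root and then a natural-log
#' transformation are tried, re-tested, and the transformation actually
#' used is recorded. All tests are two-sided at alpha = 0.05.
#'
#' Degenerate inputs (a group with zero variance) are reported with a
#' `degenerate` flag rather than an error; if every group is constant
#' the p-value is 0 when the means differ and 1 when they coincide.
#'
#' @param values Numeric vector of per-sample values.
#' @param groups Group labels (2 or more levels, each with n >= 2).
#' @param metric Metric name recorded in the result.
#' @param alpha Significance threshold (default 0.05).
#' @return Object of class `group_comparison`.
#' @export
compare_groups <- function(values, groups, metric = "value", alpha = 0.05) {
  groups <- factor(groups)
  stop_if_not(length(values) == length(groups) && !anyNA(values),
              "values must be complete and match groups")
  lv <- levels(groups)
  stop_if_not(length(lv) >= 2, "need at least two groups")
  ns <- table(groups)
  stop_if_not(all(ns >= 2), "each group needs n >= 2")

  sds <- tapply(values, groups, stats::sd)
  degenerate <- any(sds == 0)

  transform_of <- list(none = identity, sqrt = sqrt, log = log)
  applicable <- c(TRUE, all(values >= 0), all(values > 0))
  chosen <- "none"; y <- values
  norm <- NULL
  for (tr in names(transform_of)[applicable]) {
    yt <- transform_of[[tr]](values)
    nt <- do.call(rbind, tapply(yt, groups, normality_p, simplify = FALSE))
    ok <- all(is.na(nt[, "shapiro"]) | nt[, "shapiro"] > alpha)
    if (tr == "none" || ok) { chosen <- tr; y <- yt; norm <- nt }
    if (ok) break
  }
  normality <- data.frame(group = rownames(norm),
                          shapiro_p = norm[, "shapiro"],
                          ks_p = norm[, "ks"], row.names = NULL)

  levene_p <- if (degenerate) NA_real_ else {
    safe_p(car::leveneTest(y ~ groups, center = mean)[1, "Pr(>F)"])
  }

  tukey <- NULL
  if (all(sds == 0)) {
    means <- tapply(y, groups, mean)
    equal <- diff(range(means)) == 0
    test <- "degenerate"; statistic <- NA_real_
    p_value <- if (equal) 1 else 0
  } else if (length(lv) == 2) {
    var_equal <- !is.na(levene_p) && levene_p > alpha
    test <- if (var_equal) "student_t" else "welch_t"
    tt <- stats::t.test(y ~ groups, var.equal = var_equal)
    statistic <- unname(tt$statistic); p_value <- tt$p.value
  } else {
    test <- "anova_tukey"
    fit <- stats::aov(y ~ groups)
    an <- summary(fit)[[1]]
    statistic <- an[1, "F value"]; p_value <- an[1, "Pr(>F)"]
    tukey <- as.data.frame(stats::TukeyHSD(fit)$groups)
    tukey$contrast <- rownames(tukey); rownames(tukey) <- NULL
  }

  structure(list(metric = metric, groups = lv,
                 n = as.integer(ns), means = tapply(values, groups, mean),
                 sds = sds, normality = normality,
                 transformation = chosen, levene_p = levene_p,
                 test = test, statistic = statistic, p_value = p_value,
                 significant = !is.na(p_value) && p_value < alpha,
                 alpha = alpha, degenerate = degenerate, tukey = tukey),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s\n", x$metric,
              paste(sprintf("%s (n=%d, %.4g +/- %.4g)", x$groups, x$n,
                            x$means, x$sds), collapse = " vs ")))
  cat(sprintf("  transformation: %s; Levene p = %.4g\n",
              x$transformation, x$levene_p))
  cat(sprintf("  %s: statistic = %.4g, p = %.4g (%ssignificant at %.2g)\n",
              x$test, x$statistic, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  if (x$degenerate) cat("  warning: zero-variance group(s)\n")
  if (!is.null(x$tukey)) {
    cat("  Tukey HSD:\n")
    print(x$tukey[, c("contrast", "diff", "p adj")], row.names = FALSE)
  }
  invisible(x)
}
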