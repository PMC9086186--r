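test_that("mutation rate reproduces the published per-sample values", {
  expect_equal(round(mutation_rate(144157, 10730101234), 6), 0.001343)
  expect_equal(round(mutation_rate(919124, 10041975926), 6), 0.009153)
  expect_equal(mutation_rate(0, 123), 0)
  expect_error(mutation_rate(1, 0), "clean_bases")
})

test_that("sample summaries tally a hand-countable fixture", {
  # 6 SNPs (4 transitions) + 2 InDels (1 touching CDS)
  calls <- make_calls("c1", c(10, 20, 30, 40, 50, 60, 70, 80),
                      c("A", "C", "G", "T", "A", "C", "A", "AT"),
                      c("G", "T", "A", "C", "C", "G", "AT", "A"))
  calls$region <- c(rep("intergenic", 4), "exonic", "intronic",
                    "intergenic", "intergenic")
  calls$effect <- c(rep(NA, 4), "nonsynonymous", NA, "cds_indel", NA)
  calls$gene_id <- NA_character_
  s <- sample_variant_set(calls, "s1", "control", clean_bases = 1e6)
  sm <- sample_summary(s)
  expect_equal(sm$n_snp, 6L)
  expect_equal(sm$n_transition, 4L)
  expect_equal(sm$ts_tv, 2.0)
  expect_equal(sm$n_indel, 2L)
  expect_equal(sm$n_indel_cds, 1L)
  expect_equal(sm$n_nonsyn, 1L)
  expect_equal(sm$rate_snp, 100 * 6 / 1e6)
  expect_equal(sm$rate_total, sm$rate_snp + sm$rate_indel)
})

test_that("Ts/Tv from the published counts rounds to the printed ratio", {
  expect_equal(round(74612 / 69545, 2), 1.07)
})

test_that("zero transversions give an undefined Ts/Tv, not an error", {
  calls <- make_calls("c1", c(10, 20), c("A", "C"), c("G", "T"))
  calls$region <- "intergenic"; calls$effect <- NA; calls$gene_id <- NA
  sm <- sample_summary(sample_variant_set(calls, "s1", "control", 100))
  expect_true(is.na(sm$ts_tv))
})

test_that("random sample summaries equal a brute-force recount of their table", {
  sim <- the_small_cohort()
  idx <- build_gene_index(sim$models)
  filtered <- filter_shared(sim$cohort)
  for (id in c("Control_2", "Treated_5")) {
    s <- filtered[[id]]
    s$calls <- annotate_variants(s$calls, idx, sim$genome)
    sm <- sample_summary(s)
    tab <- s$calls
    snp <- tab[tab$vtype == "SNP", ]
    expect_equal(sm$n_snp, nrow(snp))
    expect_equal(sm$n_transition,
                 sum(mapply(function(r, a) {
                   (r %in% c("A", "G")) == (a %in% c("A", "G"))
                 }, snp$ref, snp$alt)))
    expect_equal(sm$n_exonic, sum(snp$region == "exonic"))
    expect_equal(sm$n_syn + sm$n_nonsyn + sm$n_stopgain + sm$n_stoploss,
                 sum(!is.na(snp$effect)))
    expect_equal(sm$n_indel_cds, sum(tab$effect %in% "cds_indel"))
  }
})

test_that("group aggregation uses the sample SD and reproduces the printed spread", {
  ctrl <- c(144157, 133641, 140421, 121144)
  ga <- group_aggregate(ctrl, rep("control", 4), "n_snp")
  expect_equal(round(ga$mean), 134841)
  # the printed spread is 10,115; the full-precision sample SD is 10115.53
  expect_lt(abs(ga$sd - 10115), 1)
  # textbook two-pass oracle on random vectors
  set.seed(8)
  for (i in 1:20) {
    v <- rnorm(sample(2:10, 1), 50, 9)
    ga <- group_aggregate(v, rep("g", length(v)))
    mu <- sum(v) / length(v)
    expect_equal(ga$mean, mu)
    expect_equal(ga$sd, sqrt(sum((v - mu)^2) / (length(v) - 1)))
  }
  expect_equal(group_aggregate(c(5, 5, 5), rep("g", 3))$sd, 0)
  expect_true(is.na(group_aggregate(5, "g")$sd))
})

test_that("class percentages and fold changes follow the published arithmetic", {
  expect_equal(round(class_percentage(33221, 919124), 3), 3.614)
  expect_equal(class_percentage(0, 100), 0)
  expect_true(is.na(class_percentage(1, 0)))
  expect_equal(round(fold_change(0.013721, 0.001518), 2), 9.04)
  expect_equal(rounded_fold(fold_change(0.013721, 0.001518)), 9)
  expect_equal(fold_change(0.4, 0.4), 1.0)
  expect_error(fold_change(1, 0), "control rate")
})

test_that("scaling counts and clean bases together leaves rates unchanged", {
  for (f in c(10, 1000)) {
    expect_equal(mutation_rate(144157 * f, 10730101234 * f),
                 mutation_rate(144157, 10730101234))
    expect_equal(class_percentage(33221 * f, 919124 * f),
                 class_percentage(33221, 919124))
  }
})

test_that("identical groups give p = 1 and separated constants are significant", {
  same <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  expect_equal(same$test, "student_t")

  sep <- compare_groups(c(0, 0, 0, 0, 10, 10, 10, 10),
                        rep(c("a", "b"), each = 4))
  expect_true(sep$degenerate)
  expect_lt(sep$p_value, 0.05)
  expect_true(sep$significant)
})

test_that("the two-sample t statistic matches the pooled-variance formula", {
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(5, 10, 2); b <- rnorm(5, 12, 2)
    cmp <- compare_groups(c(a, b), rep(c("a", "b"), each = 5))
    sp2 <- (4 * var(a) + 4 * var(b)) / 8
    t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
    if (cmp$test == "student_t") {
      expect_equal(cmp$statistic, t_manual, tolerance = 1e-10)
      expect_equal(cmp$p_value, 2 * pt(-abs(t_manual), df = 8),
                   tolerance = 1e-10)
    }
  }
})

test_that("three or more groups are compared by ANOVA with Tukey HSD", {
  set.seed(4)
  v <- c(rnorm(5, 10), rnorm(5, 10.5), rnorm(5, 20))
  g <- rep(c("a", "b", "c"), each = 5)
  cmp <- compare_groups(v, g)
  expect_equal(cmp$test, "anova_tukey")
  expect_true(cmp$significant)
  expect_equal(nrow(cmp$tukey), 3)
  # agrees with a direct aov fit
  fit <- summary(aov(v ~ factor(g)))[[1]]
  expect_equal(cmp$statistic, fit[1, "F value"])
  expect_equal(cmp$p_value, fit[1, "Pr(>F)"])
})

test_that("skewed data trigger a recorded transformation", {
  set.seed(77)
  a <- exp(rnorm(12, 0, 1.5)); b <- exp(rnorm(12, 0.3, 1.5))
  cmp <- compare_groups(c(a, b), rep(c("a", "b"), each = 12))
  expect_true(cmp$transformation %in% c("sqrt", "log"))
  expect_equal(nrow(cmp$normality), 2)
})
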