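test_that("genome simulation is byte-deterministic under a fixed seed", {
  cfg <- cohort_config(genome_length = 4e4, n_genes = 8, seed = 7)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$models, s2$models)
  expect_identical(s1$exclusive, s2$exclusive)
  d1 <- tempfile(); d2 <- tempfile()
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(s1$genome), d1)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(s2$genome), d2)
  expect_identical(readLines(d1), readLines(d2))
})

test_that("every simulated CDS translates start-to-stop without internal stops", {
  sim <- the_small_cohort()
  for (m in sim$models) {
    aa <- mutburden:::translate_cds(m, sim$genome)
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("realized GC tracks the requested content", {
  cfg <- cohort_config(genome_length = 3e5, n_chroms = 1, n_genes = 10,
                       gc_content = 0.35, seed = 13)
  sim <- simulate_genome(cfg)
  b <- strsplit(sim$genome[[1]], "")[[1]]
  gc <- mean(b %in% c("G", "C"))
  # gene ORFs perturb composition slightly; 1% absolute is the contract
  expect_lt(abs(gc - 0.35), 0.01)
})

test_that("gene packing fails loudly when the genome is too small", {
  expect_error(simulate_genome(cohort_config(genome_length = 1e4,
                                             n_genes = 50, seed = 1)),
               "infeasible packing")
})

test_that("the shared pool is Poisson-sized, unique-keyed and maskable", {
  cfg <- cohort_config(genome_length = 2e5, n_chroms = 1, n_genes = 10,
                       seed = 23)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(simulate_shared_pool(sim, 0, seed = 1)), 0L)
  rate <- 2e-3
  n <- vapply(1:8, function(s) {
    nrow(simulate_shared_pool(sim, rate, seed = s))
  }, 1)
  lambda <- rate * sum(nchar(sim$genome))
  expect_lt(abs(mean(n) - lambda), 3 * sqrt(lambda / 8))
  pool <- simulate_shared_pool(sim, rate, seed = 99)
  expect_false(anyDuplicated(paste(pool$chrom, pool$pos)) > 0)
  # masked exclusive-gene CDS positions are never polymorphic
  mask <- mutburden:::exclusion_mask(sim)
  for (ch in names(mask)) {
    expect_length(intersect(pool$pos[pool$chrom == ch], mask[[ch]]), 0)
  }
})

test_that("a zero private rate leaves only pool variants, all filterable", {
  sim0 <- simulate_cohort(cohort_config(genome_length = 4e4, n_genes = 8,
                                        shared_pool_rate = 1e-3,
                                        segregating_fraction = 0,
                                        control_spectrum = spectrum_config(0),
                                        treated_spectrum = spectrum_config(0),
                                        n_exclusive_large = 1,
                                        n_exclusive_small = 1, seed = 5))
  filtered <- filter_shared(sim0$cohort)
  for (s in filtered) {
    truth <- attr(sim0$cohort[[s$sample_id]], "truth")
    expect_true(all(truth$origin %in% c("pool", "planted")))
    # with a fully fixed pool every non-planted call is removed
    left <- variant_key(s$calls)
    planted_keys <- truth$key[truth$origin == "planted"]
    expect_true(all(left %in% planted_keys))
  }
})

test_that("the realized transition fraction matches the spectrum", {
  sim <- the_small_cohort()
  ts <- 0L; n <- 0L
  for (s in sim$cohort) {
    tr <- attr(s, "truth")
    i <- s$calls$vtype == "SNP" & tr$origin == "private"
    if (!any(i)) next
    ts <- ts + sum(is_transition(s$calls$ref[i], s$calls$alt[i]))
    n <- n + sum(i)
  }
  p_hat <- ts / n
  expect_lt(abs(p_hat - 0.53), 3 * sqrt(0.53 * 0.47 / n))
})

test_that("planted SNPs sit in their designated genes and nowhere else", {
  sim <- the_small_cohort()
  planted <- sim$truth$planted
  expect_setequal(planted$gene_id[planted$group == "treated_large"],
                  sim$truth$exclusive_large)
  excl <- unlist(sim$truth[c("exclusive_large", "exclusive_small")])
  idx <- build_gene_index(sim$models)
  for (s in sim$cohort) {
    tr <- attr(s, "truth")
    ann <- annotate_variants(s$calls, idx, sim$genome)
    in_excl <- !is.na(ann$gene_id) & ann$gene_id %in% excl &
      ann$effect %in% c("nonsynonymous", "stopgain", "stoploss")
    expect_true(all(tr$origin[in_excl] == "planted"),
                info = s$sample_id)
    if (s$group == "treated_large") {
      expect_setequal(unique(ann$gene_id[in_excl]), sim$truth$exclusive_large)
    }
    if (s$group %in% c("control", "treated_normal")) {
      expect_false(any(in_excl))
    }
  }
})

test_that("whole cohorts are reproducible from the seed alone", {
  cfg <- cohort_config(genome_length = 4e4, n_genes = 8,
                       n_exclusive_large = 1, n_exclusive_small = 1,
                       seed = 99)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  for (id in names(c1$cohort)) {
    expect_identical(c1$cohort[[id]]$calls, c2$cohort[[id]]$calls)
    expect_identical(c1$cohort[[id]]$clean_bases, c2$cohort[[id]]$clean_bases)
  }
})
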