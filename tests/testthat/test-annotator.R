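test_that("gene index answers stabbing queries with inclusive bounds", {
  m <- gene_model("g1", "g1.t1", "c1", "+",
                  exons = data.frame(start = 100, end = 200),
                  cds = data.frame(start = 120, end = 179))
  idx <- build_gene_index(list(m))
  reg <- annotate_region(data.frame(chrom = "c1",
                                    pos = c(150, 250, 100, 200, 99, 201)),
                         idx, upstream_window = 0)
  expect_equal(reg$region,
               c("exonic", "intergenic", "exonic", "exonic", "intergenic",
                 "intergenic"))
  expect_error(build_gene_index(list(m, m)), "duplicate")
})

test_that("region labels follow the exonic>intronic>upstream precedence", {
  m <- gene_model("g1", "g1.t1", "c1", "+",
                  exons = data.frame(start = c(100, 180), end = c(140, 200)),
                  cds = data.frame(start = c(110, 180), end = c(140, 193)))
  idx <- build_gene_index(list(m))
  reg <- annotate_region(data.frame(chrom = "c1", pos = c(120, 160, 50, 20000)),
                         idx, upstream_window = 1000)
  expect_equal(reg$region, c("exonic", "intronic", "upstream", "intergenic"))
  # unknown chromosome falls through to intergenic
  reg2 <- annotate_region(data.frame(chrom = "cX", pos = 120), idx)
  expect_equal(reg2$region, "intergenic")
  # upstream is strand-aware: for a minus-strand gene it sits 3'-ward in
  # genome coordinates
  mm <- gene_model("g2", "g2.t1", "c1", "-",
                   exons = data.frame(start = 5000, end = 5119),
                   cds = data.frame(start = 5010, end = 5111))
  idx2 <- build_gene_index(list(mm))
  reg3 <- annotate_region(data.frame(chrom = "c1", pos = c(4950, 5200)),
                          idx2, upstream_window = 500)
  expect_equal(reg3$region, c("intergenic", "upstream"))
})

test_that("random positions agree with a brute-force region classifier", {
  sim <- the_small_cohort()
  idx <- build_gene_index(sim$models)
  set.seed(5)
  n <- 1000
  chrom <- sample(names(sim$genome), n, TRUE)
  pos <- vapply(chrom, function(ch) sample.int(nchar(sim$genome[[ch]]), 1), 1L)
  got <- annotate_region(data.frame(chrom = chrom, pos = pos), idx,
                         upstream_window = 1000)$region
  brute <- vapply(seq_len(n), function(i) {
    lab <- "intergenic"
    for (m in sim$models) {
      if (m$chrom != chrom[i]) next
      if (any(pos[i] >= m$exons$start & pos[i] <= m$exons$end)) return("exonic")
      if (pos[i] >= m$start && pos[i] <= m$end) lab <- "intronic"
    }
    if (lab == "intronic") return(lab)
    for (m in sim$models) {
      if (m$chrom != chrom[i]) next
      up <- if (m$strand == "+") c(m$start - 1000, m$start - 1)
            else c(m$end + 1, m$end + 1000)
      if (pos[i] >= up[1] && pos[i] <= up[2]) return("upstream")
    }
    "intergenic"
  }, character(1))
  expect_equal(got, unname(brute))
})

test_that("coding effects match the genetic code on constructed codons", {
  # one plus-strand gene whose CDS we control base by base:
  # ATG AAA TGG TAA -> M K W *
  seq <- paste0(strrep("T", 100), "ATGAAATGGTAA", strrep("T", 88))
  genome <- c(c1 = seq)
  m <- gene_model("g1", "g1.t1", "c1", "+",
                  exons = data.frame(start = 95, end = 120),
                  cds = data.frame(start = 101, end = 112))
  expect_equal(coding_effect("c1", 106, "A", "G", m, genome), "synonymous")   # AAA->AAG (K)
  expect_equal(coding_effect("c1", 104, "A", "G", m, genome), "nonsynonymous") # AAA->GAA (K->E)
  expect_equal(coding_effect("c1", 109, "G", "A", m, genome), "stopgain")     # TGG->TGA
  expect_equal(coding_effect("c1", 112, "A", "C", m, genome), "stoploss")     # TAA->TAC (Y)
  expect_error(coding_effect("c1", 95, "T", "A", m, genome), "annotate_region")
})

test_that("minus-strand effects equal their plus-strand mirror construct", {
  plus_seq <- paste0(strrep("T", 100), "ATGAAATGGTAA", strrep("T", 88))
  minus_seq <- mutburden:::rc(plus_seq)
  genome <- c(p = plus_seq, m = minus_seq)
  gp <- gene_model("gp", "gp.t1", "p", "+",
                   exons = data.frame(start = 101, end = 112),
                   cds = data.frame(start = 101, end = 112))
  # position x on p mirrors position 201 - x on m; alleles complemented
  gm <- gene_model("gm", "gm.t1", "m", "-",
                   exons = data.frame(start = 89, end = 100),
                   cds = data.frame(start = 89, end = 100))
  cases <- data.frame(pos = c(106, 104, 109, 112),
                      ref = c("A", "A", "G", "A"),
                      alt = c("G", "G", "A", "C"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(cases))) {
    eff_p <- coding_effect("p", cases$pos[i], cases$ref[i], cases$alt[i],
                           gp, genome)
    eff_m <- coding_effect("m", 201 - cases$pos[i], comp[[cases$ref[i]]],
                           comp[[cases$alt[i]]], gm, genome)
    expect_equal(eff_m, eff_p, info = sprintf("case %d", i))
  }
})

test_that("coding_effect matches the whole-protein diff oracle on random CDS SNPs", {
  sim <- the_small_cohort()
  set.seed(17)
  n_checked <- 0
  models <- sim$models
  for (rep in seq_len(600)) {
    m <- models[[sample.int(length(models), 1)]]
    cds_len <- sum(m$cds$end - m$cds$start + 1)
    cpos <- sample.int(cds_len, 1)
    gpos <- mutburden:::cds_to_genomic(m, cpos)
    ref <- substr(sim$genome[[m$chrom]], gpos, gpos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- coding_effect(m$chrom, gpos, ref, alt, m, sim$genome)
    want <- effect_oracle(m, sim$genome, gpos, alt)
    expect_equal(got, want,
                 info = sprintf("%s %s:%d %s>%s", m$transcript_id, m$chrom,
                                gpos, ref, alt))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 500)
})

test_that("CDS InDel flag is an interval intersection on the ref span", {
  m <- gene_model("g1", "g1.t1", "c1", "+",
                  exons = data.frame(start = 99, end = 140),
                  cds = data.frame(start = 99, end = 140))
  idx <- build_gene_index(list(m))
  expect_true(cds_indel_flag("c1", 139, "AT", idx))   # 139-140 hits CDS
  expect_false(cds_indel_flag("c1", 141, "A", idx))   # insertion anchor only
  expect_true(cds_indel_flag("c1", 95, "AAAAAA", idx)) # spans into CDS
  # brute-force agreement on random InDel intervals
  set.seed(31)
  for (i in 1:200) {
    pos <- sample.int(200, 1); len <- sample.int(6, 1)
    got <- cds_indel_flag("c1", pos, strrep("A", len), idx)
    expect_equal(got, max(pos, 99) <= min(pos + len - 1, 140))
  }
})

test_that("region and effect labels partition the annotated calls", {
  sim <- the_small_cohort()
  idx <- build_gene_index(sim$models)
  filtered <- filter_shared(sim$cohort)
  s <- filtered[["Treated_2"]]
  ann <- annotate_variants(s$calls, idx, sim$genome)
  expect_equal(sum(ann$region %in% c("exonic", "intronic", "upstream",
                                     "intergenic")), nrow(ann))
  snp_cds <- ann$vtype == "SNP" & !is.na(ann$effect)
  expect_true(all(ann$effect[snp_cds] %in%
                    c("synonymous", "nonsynonymous", "stopgain", "stoploss")))
  # every effect-labelled SNP is exonic, and CDS SNP counts partition
  expect_true(all(ann$region[snp_cds] == "exonic"))
})

test_that("gene models with invalid CDS are reported at load", {
  sim <- the_small_cohort()
  d <- tempfile(); dir.create(d)
  gff <- file.path(d, "g.gff3")
  write_gff3(sim$models[1:5], gff)
  models <- read_gene_models(gff, sim$genome)
  expect_length(attr(models, "violations"), 0)
  # corrupt the start codon of one gene
  bad_genome <- sim$genome
  m <- models[[1]]
  p <- if (m$strand == "+") m$cds$start[1] else
    mutburden:::cds_to_genomic(m, 1)
  substr(bad_genome[[m$chrom]], p, p) <- "C"
  expect_message(read_gene_models(gff, bad_genome), "fail CDS translation")
})
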