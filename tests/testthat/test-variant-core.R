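test_that("variant classification partitions SNPs and InDels", {
  expect_equal(classify_variant(c("A", "A", "AT"), c("G", "AT", "A")),
               c("SNP", "insertion", "deletion"))
  expect_error(classify_variant("A", "A"), "differ")
  expect_error(classify_variant("AT", "GC"), "equal-length")
  # every valid normalized pair lands in exactly one class
  pairs <- expand.grid(ref = c("A", "C", "AT", "ATG"),
                       alt = c("G", "T", "AC", "ACGT"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt &
                   !(nchar(pairs$ref) == nchar(pairs$alt) &
                       nchar(pairs$ref) > 1), ]
  v <- classify_variant(pairs$ref, pairs$alt)
  expect_true(all(v %in% c("SNP", "insertion", "deletion")))
})

test_that("exactly 4 of the 12 ordered base pairs are transitions", {
  pairs <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  ts <- is_transition(pairs$ref, pairs$alt)
  expect_equal(sum(ts), 4L)
  expect_true(is_transition("A", "G"))
  expect_true(is_transition("C", "T"))
  expect_false(is_transition("A", "C"))
  expect_error(is_transition("AT", "A"), "SNPs only")
})

test_that("genotype strings canonicalize to the two-class code", {
  expect_equal(canonicalize_geno(c("0/1", "1/0", "0|1", "1|0")),
               rep("het", 4))
  expect_equal(canonicalize_geno(c("1/1", "1|1")), rep("hom_alt", 2))
  expect_equal(canonicalize_geno(c("./.", ".", "0/0")),
               rep(NA_character_, 3))
  expect_equal(canonicalize_geno("1/2"), "het")
})

test_that("normalization trims shared bases and errors on degenerate input", {
  genome <- c(s1 = "TTTTTTTTTCAGTTTTTTTT")  # CA at 10-11, G at 12
  nv <- normalize_variant("s1", 10, "CA", "CG", genome)
  expect_equal(nv[c("pos", "ref", "alt")], list(pos = 11L, ref = "A", alt = "G"))
  expect_error(normalize_variant("s1", 10, "A", "A", genome), "degenerate")
  expect_error(normalize_variant("s1", 10, "G", "T", genome), "REF mismatch")
})

test_that("deletion in a homopolymer left-aligns within the repeat window", {
  genome <- c(s1 = "TAAAC")
  nv <- normalize_variant("s1", 3, "AA", "A", genome)
  expect_equal(nv[c("pos", "ref", "alt")], list(pos = 2L, ref = "AA", alt = "A"))
  # idempotent
  nv2 <- normalize_variant("s1", nv$pos, nv$ref, nv$alt, genome)
  expect_equal(nv, nv2)
})

test_that("normalization preserves the edited haplotype and is idempotent", {
  set.seed(99)
  for (rep in 1:40) {
    seq <- paste(sample(c("A", "C", "G", "T"), 50, TRUE,
                        prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    genome <- c(c1 = seq)
    pos <- sample(5:40, 1)
    kind <- sample(c("snp", "ins", "del"), 1)
    ref <- substr(seq, pos, pos)
    if (kind == "snp") {
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    } else if (kind == "ins") {
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"),
                                      sample(1:3, 1), TRUE), collapse = ""))
    } else {
      dlen <- sample(1:3, 1)
      ref <- substr(seq, pos, pos + dlen)
      alt <- substr(seq, pos, pos)
    }
    nv <- normalize_variant("c1", pos, ref, alt, genome)
    expect_identical(apply_variant(seq, nv$pos, nv$ref, nv$alt),
                     apply_variant(seq, pos, ref, alt),
                     info = sprintf("rep %d: %d %s>%s", rep, pos, ref, alt))
    nv2 <- normalize_variant("c1", nv$pos, nv$ref, nv$alt, genome)
    expect_identical(nv, nv2)
  }
})

test_that("read_vcf maps records, splits multiallelics and skips missing GTs", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampleA",
    "s1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "s1\t150\t.\tA\tG,T\t.\tPASS\t.\tGT\t1/2",
    "s1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t./.",
    "s1\t250\t.\tT\tA\t.\tPASS\t.\tGT\t1|1",
    "s1\t300\t.\tG\tC\t.\tPASS\t.\tGT\t0/0"), vcf)
  s <- read_vcf(vcf)
  expect_equal(attr(s, "n_skipped"), 2L)  # ./. and 0/0
  k <- variant_key(s$calls)
  expect_setequal(k, c("s1:100:A:G:het", "s1:150:A:G:het", "s1:150:A:T:het",
                       "s1:250:T:A:hom_alt"))
  expect_equal(s$calls$vtype, rep("SNP", 4))
  expect_error(read_vcf(vcf, sample = "nope"), "sampleA")
})

test_that("variant tables round-trip the key set through TSV", {
  calls <- make_calls("chr1", c(10, 20, 30), c("A", "C", "GT"),
                      c("G", "CT", "G"),
                      geno = c("het", "hom_alt", "het"))
  f <- tempfile(fileext = ".tsv")
  write_variant_table(calls, f)
  back <- read_variant_table(f)
  expect_setequal(variant_key(back), variant_key(calls))
})

test_that("write_vcf then read_vcf round-trips keys exactly", {
  sim <- the_small_cohort()
  s <- sim$cohort[["Treated_1"]]
  f <- tempfile(fileext = ".vcf")
  write_vcf(s, f, sim$genome)
  back <- read_vcf(f, sample = "Treated_1", genome = sim$genome)
  expect_setequal(variant_key(back$calls), variant_key(s$calls))
})

test_that("duplicate keys within one sample are rejected", {
  calls <- make_calls("chr1", c(5, 5), c("A", "A"), c("G", "G"))
  expect_error(sample_variant_set(calls, "s1"), "duplicate")
})
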