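# In-code fixtures shared across test files.

# apply a variant to its chromosome sequence (independent haplotype oracle)
apply_variant <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1) == ref)
  paste0(substr(seq, 1, pos - 1), alt, substr(seq, pos + nchar(ref), nchar(seq)))
}

make_calls <- function(chrom, pos, ref, alt, geno = "het",
                       sample_id = "s1") {
  data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, geno = geno,
             vtype = classify_variant(ref, alt), stringsAsFactors = FALSE)
}

# a sample_variant_set from bare key strings "chrom:pos:ref:alt:geno"
svs_from_keys <- function(keys, sample_id, group = NA_character_,
                          clean_bases = 1e6) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  calls <- do.call(rbind, lapply(parts, function(p) {
    make_calls(p[1], as.integer(p[2]), p[3], p[4], p[5], sample_id)
  }))
  if (is.null(calls)) calls <- mutburden:::empty_calls()
  sample_variant_set(calls, sample_id, group, clean_bases)
}

# tiny two-gene annotation fixture used by annotator and screen tests:
# chr1 (plus strand) gene with two CDS exons, chr1 minus-strand mirror gene.
# Returns list(genome, models, index).
toy_annotation <- function() {
  # gA (+): exons 101-160 and 221-280; CDS 121-160, 221-260 (total 80+... )
  # CDS length must be divisible by 3: 40 + 41 -> use 121-160 (40) and
  # 221-264 (44) = 84 bp = 28 codons.
  set.seed(42)
  orfA <- paste(c("ATG", sample(mutburden:::SENSE_CODONS, 26, TRUE), "TAA"),
                collapse = "")
  chr1 <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  substr(chr1, 121, 160) <- substr(orfA, 1, 40)
  substr(chr1, 221, 264) <- substr(orfA, 41, 84)
  gA <- gene_model("gA", "gA.t1", "chr1", "+",
                   exons = data.frame(start = c(101, 221), end = c(160, 280)),
                   cds = data.frame(start = c(121, 221), end = c(160, 264)))
  # gB (-): single-exon gene on the minus strand at 401-520, CDS 421-504
  orfB <- paste(c("ATG", sample(mutburden:::SENSE_CODONS, 26, TRUE), "TGA"),
                collapse = "")
  substr(chr1, 421, 504) <- mutburden:::rc(orfB)
  gB <- gene_model("gB", "gB.t1", "chr1", "-",
                   exons = data.frame(start = 401, end = 520),
                   cds = data.frame(start = 421, end = 504))
  genome <- c(chr1 = chr1)
  models <- list(gA.t1 = gA, gB.t1 = gB)
  list(genome = genome, models = models, index = build_gene_index(models))
}

# whole-protein diff oracle for coding effects
effect_oracle <- function(model, genome, pos, alt) {
  ref_aa <- mutburden:::translate_cds(model, genome)
  mut_genome <- genome
  ref <- substr(genome[[model$chrom]], pos, pos)
  mut_genome[[model$chrom]] <- apply_variant(genome[[model$chrom]], pos, ref, alt)
  alt_aa <- mutburden:::translate_cds(model, mut_genome)
  r <- strsplit(ref_aa, "")[[1]]; a <- strsplit(alt_aa, "")[[1]]
  d <- which(r != a)
  if (length(d) == 0) return("synonymous")
  stopifnot(length(d) == 1)
  if (r[d] == "*") "stoploss" else if (a[d] == "*") "stopgain"
  else "nonsynonymous"
}

# small, fast synthetic cohort reused by several test files (built once)
small_cohort_config <- function(seed = 303) {
  cohort_config(genome_length = 1.2e5, n_chroms = 2, n_genes = 24,
                shared_pool_rate = 5e-4,
                control_spectrum = spectrum_config(6e-5, gc_at_bias = 0.35),
                treated_spectrum = spectrum_config(5.4e-4, gc_at_bias = 0.8),
                n_exclusive_large = 3, n_exclusive_small = 2, seed = seed)
}

the_small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(small_cohort_config())
    cache
  }
})

# default-scale (1 Mb) cohort + full pipeline run, built once and shared
# by the end-to-end recovery checks
the_default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_cohort(cohort_config(seed = 1))
      d <- tempfile()
      paths <- write_cohort(sim, d)
      run <- suppressMessages(
        run_pipeline(paths$vcfs, paths$fasta, paths$gff3, paths$cohort))
      cache <<- list(sim = sim, run = run)
    }
    cache
  }
})
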