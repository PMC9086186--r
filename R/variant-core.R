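#' Variant-type classification
#'
#' Classifies normalized allele pairs into the three mutation classes used
#' throughout the package: single-base substitutions (`"SNP"`), insertions
#' (ALT longer than REF) and deletions (REF longer than ALT).
#'
#' @param ref,alt Character vectors of reference / alternate alleles over
#'   `{A,C,G,T}`, already normalized (see [normalize_variants()]).
#' @return Character vector in `c("SNP", "insertion", "deletion")`.
#' @examples
#' classify_variant(c("A", "A", "AT"), c("G", "AT", "A"))
#' @export
classify_variant <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  stop_if_not(length(ref) == length(alt), "ref and alt must have equal length")
  stop_if_not(all(is_dna_string(ref)) && all(is_dna_string(alt)),
              "alleles must be non-empty strings over {A,C,G,T}")
  stop_if_not(!any(ref == alt), "ref and alt must differ (found ref == alt)")
  lr <- nchar(ref); la <- nchar(alt)
  bad <- lr == la & lr > 1L
  stop_if_not(!any(bad),
              "equal-length multi-base substitution not supported: %s>%s",
              ref[which(bad)[1]], alt[which(bad)[1]])
  ifelse(lr == la, "SNP", ifelse(la > lr, "insertion", "deletion"))
}

#' Transition or transversion?
#'
#' A transition exchanges nucleotides of the same chemical class
#' (purine with purine, A<->G, or pyrimidine with pyrimidine, C<->T); the
#' remaining eight ordered base pairs are transversions.
#'
#' @inheritParams classify_variant
#' @return Logical vector: `TRUE` for transitions.
#' @examples
#' is_transition("A", "G")  # TRUE
#' is_transition("A", "C")  # FALSE
#' @export
is_transition <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- nchar(ref) == 1L & nchar(alt) == 1L & ref != alt &
    ref %in% DNA_BASES & alt %in% DNA_BASES
  stop_if_not(all(ok), "is_transition is defined for SNPs only")
  purine <- c("A", "G")
  (ref %in% purine) == (alt %in% purine)
}

#' Canonicalize a VCF genotype string
#'
#' Collapses diploid GT strings into the two-class genotype code used in
#' variant keys: heterozygous (`"het"`) or homozygous-alternate
#' (`"hom_alt"`). Phase separators are ignored. Genotypes that carry no
#' alternate allele, or with any missing allele, return `NA`.
#'
#' @param gt Character vector of GT fields (e.g. `"0/1"`, `"1|1"`, `"./."`).
#' @return Character vector in `c("het", "hom_alt", NA)`.
#' @export
canonicalize_geno <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) {
    if (length(p) == 0L || any(p == ".") || any(!grepl("^[0-9]+$", p))) {
      return(NA_character_)
    }
    a <- as.integer(p)
    if (all(a == 0L)) return(NA_character_)
    nz <- unique(a[a > 0L])
    if (length(nz) == 1L && all(a == nz[1])) "hom_alt" else "het"
  }, character(1))
}

#' Five-field variant keys
#'
#' Builds the `(CHROM, POS, REF, ALT, GENO)` identity string under which
#' mutation *types* are matched between samples. Two calls are the "same
#' type" of mutation exactly when their keys are equal; shared-type
#' filtering ([group_specific_variants()]) operates on these keys.
#'
#' @param calls Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `geno` (a variant table, see [read_vcf()]).
#' @param ignore_geno If `TRUE`, drop the genotype class from the key so
#'   that het and hom-alt calls at the same site/alleles match.
#' @return Character vector of keys, one per row.
#' @export
variant_key <- function(calls, ignore_geno = FALSE) {
  if (ignore_geno) {
    paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  } else {
    paste(calls$chrom, calls$pos, calls$ref, calls$alt, calls$geno, sep = ":")
  }
}

empty_calls <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), geno = character(),
             vtype = character(), stringsAsFactors = FALSE)
}

validate_calls <- function(calls) {
  need <- c("sample_id", "chrom", "pos", "ref", "alt", "geno", "vtype")
  stop_if_not(all(need %in% names(calls)),
              "variant table must have columns: %s", paste(need, collapse = ", "))
  stop_if_not(all(calls$pos >= 1L), "positions must be 1-based (>= 1)")
  stop_if_not(all(calls$geno %in% c("het", "hom_alt")),
              "geno must be 'het' or 'hom_alt'")
  stop_if_not(all(calls$vtype %in% c("SNP", "insertion", "deletion")),
              "vtype must be SNP/insertion/deletion")
  invisible(calls)
}

#' One sample's variant calls
#'
#' Container pairing a sample's variant table with its cohort metadata:
#' the phenotype group and the clean-base total that serves as the
#' denominator of its mutation rate.
#'
#' @param calls Variant table (data frame) for one sample.
#' @param sample_id Sample identifier; stamped into the `sample_id` column.
#' @param group One of `"control"`, `"treated_large"`, `"treated_normal"`,
#'   `"treated_small"`, or `NA` if not yet known.
#' @param clean_bases Total post-QC sequenced bases (bp) for the sample,
#'   or `NA` if attached later from a cohort configuration.
#' @return An object of class `sample_variant_set`.
#' @export
sample_variant_set <- function(calls, sample_id, group = NA_character_,
                               clean_bases = NA_real_) {
  if (nrow(calls) > 0) calls$sample_id <- sample_id
  validate_calls(calls)
  stop_if_not(is.na(clean_bases) || clean_bases > 0, "clean_bases must be > 0")
  if (!is.na(group)) {
    stop_if_not(group %in% COHORT_GROUPS, "unknown group '%s'", group)
  }
  keys <- variant_key(calls)
  stop_if_not(!anyDuplicated(keys), "duplicate variant keys within sample %s",
              sample_id)
  structure(list(sample_id = sample_id, group = group,
                 clean_bases = clean_bases, calls = calls),
            class = "sample_variant_set")
}

COHORT_GROUPS <- c("control", "treated_large", "treated_normal", "treated_small")

#' @export
print.sample_variant_set <- function(x, ...) {
  cat(sprintf("<sample_variant_set> %s (%s)\n", x$sample_id,
              ifelse(is.na(x$group), "group unset", x$group)))
  tab <- table(factor(x$calls$vtype, c("SNP", "insertion", "deletion")))
  cat(sprintf("  %d calls: %d SNP, %d insertion, %d deletion\n",
              nrow(x$calls), tab[["SNP"]], tab[["insertion"]], tab[["deletion"]]))
  cat(sprintf("  clean_bases: %s\n", format(x$clean_bases, big.mark = ",")))
  invisible(x)
}

#' Read one sample's calls from a VCF
#'
#' Ingests a VCF v4.x file (plain or bgzipped) and extracts the biallelic
#' non-reference calls of one sample. Multiallelic records are split into
#' one call per alternate allele before keying; records whose genotype is
#' missing, reference-homozygous, or whose alleles are not plain
#' `{A,C,G,T}` strings are skipped and counted.
#'
#' @param path Path to the VCF file.
#' @param sample Sample name to extract. May be omitted for single-sample
#'   VCFs. An unknown name errors, listing the samples present.
#' @param genome Optional reference (named character vector or
#'   `DNAStringSet`); when supplied, calls are normalized with
#'   [normalize_variants()].
#' @return A [sample_variant_set()] (group and clean_bases unset) with an
#'   attribute `n_skipped` giving the skipped-record count.
#' @export
read_vcf <- function(path, sample = NULL, genome = NULL) {
  stop_if_not(file.exists(path), "VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- v@gt
  stop_if_not(!is.null(gt) && ncol(gt) >= 2, "VCF has no genotype columns")
  samples <- colnames(gt)[-1]
  if (is.null(sample)) {
    stop_if_not(length(samples) == 1,
                "multi-sample VCF: pass `sample` (one of: %s)",
                paste(samples, collapse = ", "))
    sample <- samples[1]
  }
  stop_if_not(sample %in% samples, "sample '%s' not in VCF (available: %s)",
              sample, paste(samples, collapse = ", "))

  gt_str <- vapply(seq_len(nrow(gt)), function(i) {
    fmt <- strsplit(gt[i, 1], ":", fixed = TRUE)[[1]]
    val <- strsplit(gt[i, sample], ":", fixed = TRUE)[[1]]
    j <- match("GT", fmt)
    if (is.na(j) || j > length(val)) "." else val[j]
  }, character(1))

  n_skip <- 0L
  add <- list(chrom = list(), pos = list(), ref = list(), alt = list(),
              geno = list())
  for (i in seq_len(nrow(gt))) {
    ref <- toupper(fix[i, "REF"])
    alts <- toupper(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
    al <- strsplit(gt_str[i], "[/|]")[[1]]
    if (length(al) == 0L || any(al == ".") || any(!grepl("^[0-9]+$", al))) {
      n_skip <- n_skip + 1L
      next
    }
    a <- as.integer(al)
    nz <- sort(unique(a[a > 0L]))
    if (length(nz) == 0L) { n_skip <- n_skip + 1L; next }  # hom-ref
    for (k in nz) {
      if (k > length(alts)) {
        stop(sprintf("malformed record at %s:%s (line %d): GT allele %d but %d ALT allele(s)",
                     fix[i, "CHROM"], fix[i, "POS"], i, k, length(alts)), call. = FALSE)
      }
      alt_k <- alts[k]
      if (!is_dna_string(ref) || !is_dna_string(alt_k)) { n_skip <- n_skip + 1L; next }
      j <- length(add$chrom) + 1L
      add$chrom[[j]] <- fix[i, "CHROM"]
      add$pos[[j]] <- as.integer(fix[i, "POS"])
      add$ref[[j]] <- ref
      add$alt[[j]] <- alt_k
      add$geno[[j]] <- if (all(a == k)) "hom_alt" else "het"
    }
  }
  calls <- if (length(add$chrom) == 0L) empty_calls() else data.frame(
    sample_id = sample,
    chrom = unlist(add$chrom), pos = unlist(add$pos),
    ref = unlist(add$ref), alt = unlist(add$alt),
    geno = unlist(add$geno), vtype = NA_character_,
    stringsAsFactors = FALSE)
  if (nrow(calls) > 0) {
    calls$vtype <- classify_variant(calls$ref, calls$alt)
    if (!is.null(genome)) calls <- normalize_variants(calls, genome)
    calls <- calls[!duplicated(variant_key(calls)), , drop = FALSE]
    rownames(calls) <- NULL
  }
  out <- sample_variant_set(calls, sample_id = sample)
  attr(out, "n_skipped") <- n_skip
  out
}

#' Normalize variant representations
#'
#' Canonicalizes allele representations so that five-field keys are
#' comparable across callers: shared trailing then leading bases are
#' trimmed (an anchor base is kept for InDels), and InDels are
#' left-shifted through a repeat context one base at a time while the
#' reference base immediately 5' of the window equals the shared last
#' base of both alleles (i.e. while the preceding base can be cycled into
#' the window). The operation is idempotent and preserves the edited
#' haplotype.
#'
#' @param calls Variant table with `chrom`, `pos`, `ref`, `alt` columns.
#' @param genome Reference sequences (named character vector or
#'   `DNAStringSet`). Alleles must match the reference at their position.
#' @return The table with `pos`, `ref`, `alt` (and `vtype`, if present)
#'   rewritten to canonical form.
#' @export
normalize_variants <- function(calls, genome) {
  genome <- as_genome_chr(genome)
  n <- nrow(calls)
  if (n == 0L) return(calls)
  for (i in seq_len(n)) {
    nv <- normalize_one(calls$chrom[i], calls$pos[i],
                        calls$ref[i], calls$alt[i], genome)
    calls$pos[i] <- nv$pos; calls$ref[i] <- nv$ref; calls$alt[i] <- nv$alt
  }
  if ("vtype" %in% names(calls)) {
    calls$vtype <- classify_variant(calls$ref, calls$alt)
  }
  calls
}

#' @rdname normalize_variants
#' @param chrom,pos,ref,alt A single variant (1-based position).
#' @export
normalize_variant <- function(chrom, pos, ref, alt, genome) {
  normalize_one(chrom, pos, ref, alt, as_genome_chr(genome))
}

# core algorithm; `genome` must already be an uppercase named character vector
normalize_one <- function(chrom, pos, ref, alt, genome) {
  ref <- toupper(ref); alt <- toupper(alt)
  stop_if_not(is_dna_string(ref) && is_dna_string(alt),
              "alleles must be non-empty {A,C,G,T} strings")
  stop_if_not(ref != alt, "degenerate variant: ref == alt ('%s') at %s:%d",
              ref, chrom, pos)
  stop_if_not(chrom %in% names(genome), "sequence '%s' not in genome", chrom)
  stop_if_not(pos >= 1 && pos + nchar(ref) - 1 <= nchar(genome[[chrom]]),
              "position %d out of range on %s", pos, chrom)
  obs <- genome_sub(genome, chrom, pos, pos + nchar(ref) - 1L)
  stop_if_not(obs == ref, "REF mismatch at %s:%d: VCF '%s' vs genome '%s'",
              chrom, pos, ref, obs)

  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  # right-trim shared suffix, keeping >=1 base per allele
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  # left-trim shared prefix
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  # left-align InDels through the repeat context
  if (length(r) != length(a)) {
    repeat {
      last <- r[length(r)]
      if (pos <= 1L || last != a[length(a)]) break
      prev <- genome_sub(genome, chrom, pos - 1L, pos - 1L)
      if (prev != last) break
      r <- c(prev, r[-length(r)]); a <- c(prev, a[-length(a)])
      pos <- pos - 1L
    }
  }
  list(chrom = chrom, pos = as.integer(pos),
       ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Read/write the variant-table TSV dialect
#'
#' The on-disk interchange format used between pipeline stages: one row
#' per call, tab-separated with a header, columns `sample_id, chrom, pos,
#' ref, alt, geno, vtype` plus any annotation columns already added
#' (`region`, `effect`, `gene_id`).
#'
#' @param calls Variant table (possibly covering several samples).
#' @param path File path.
#' @return `read_variant_table()` returns the data frame;
#'   `write_variant_table()` returns `path` invisibly.
#' @export
write_variant_table <- function(calls, path) {
  validate_calls(calls)
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  stop_if_not(file.exists(path), "variant table not found: %s", path)
  calls <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = "character",
                             stringsAsFactors = FALSE)
  calls$pos <- as.integer(calls$pos)
  validate_calls(calls)
  calls
}
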