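#' Mutational spectrum configuration
#'
#' Parameters of the per-sample private-mutation process. Defaults for
#' the treated spectrum are calibrated to an EMS screen: per-base rate
#' about nine times the spontaneous rate, a transition fraction of 0.53
#' (giving Ts/Tv near 1.12), a G:C origin bias for transitions
#' (alkylation chemistry), a small InDel share, and a mild depletion of
#' events inside coding sequence (survivor selection / repair).
#'
#' @param per_base_rate Expected private mutations per genome bp.
#' @param transition_fraction Probability a simulated SNP is a
#'   transition.
#' @param gc_at_bias Probability a transition originates at a G:C pair.
#' @param indel_fraction Share of events that are InDels.
#' @param indel_size_geometric_p Geometric parameter for InDel size
#'   (size = 1 + Geom(p)).
#' @param coding_depletion Multiplicative retention factor (< 1 depletes)
#'   for events falling inside CDS.
#' @param het_fraction Probability a private mutation is called
#'   heterozygous.
#' @return Object of class `spectrum_config`.
#' @export
spectrum_config <- function(per_base_rate, transition_fraction = 0.53,
                            gc_at_bias = 0.5, indel_fraction = 0.166,
                            indel_size_geometric_p = 0.5,
                            coding_depletion = 0.95, het_fraction = 0.9) {
  probs <- c(transition_fraction, gc_at_bias, indel_fraction,
             indel_size_geometric_p, coding_depletion, het_fraction)
  stop_if_not(all(probs >= 0 & probs <= 1), "probabilities must be in [0,1]")
  stop_if_not(per_base_rate >= 0, "per_base_rate must be >= 0")
  structure(list(per_base_rate = per_base_rate,
                 transition_fraction = transition_fraction,
                 gc_at_bias = gc_at_bias, indel_fraction = indel_fraction,
                 indel_size_geometric_p = indel_size_geometric_p,
                 coding_depletion = coding_depletion,
                 het_fraction = het_fraction),
            class = "spectrum_config")
}

#' Synthetic cohort configuration
#'
#' Study-design parameters of the synthetic EMS cohort: a 1 Mb two-
#' chromosome genome at 35% GC, 4 untreated controls and 12 treated
#' animals (5 large, 5 normal, 2 small), a standing polymorphism pool
#' shared through the population, control and treated private spectra
#' whose per-base rates stand in a ~9:1 ratio, clean-base totals around
#' 11.2x the genome size with ~9% spread, and a handful of designated
#' genes that carry planted phenotype-exclusive nonsynonymous SNPs.
#'
#' @param genome_length Total genome size (bp).
#' @param n_chroms Number of chromosomes (genome split evenly).
#' @param gc_content Genome GC fraction.
#' @param n_genes,exons_per_gene Gene-model layout.
#' @param control_n,treated_large_n,treated_normal_n,treated_small_n
#'   Cohort sizes.
#' @param shared_pool_rate Shared (population) variant sites per bp.
#' @param segregating_fraction Fraction of pool sites that segregate at
#'   intermediate frequency; the rest are fixed differences against the
#'   reference (alternate-allele frequency 1, homozygous in everyone).
#'   Segregating sites can evade the control filter when a sample's
#'   genotype class is absent from the panel, leaving residual "unique"
#'   calls in every sample as in real screens.
#' @param control_spectrum,treated_spectrum [spectrum_config()] objects.
#' @param clean_bases_mean,clean_bases_sd Normal draw (clipped positive)
#'   for per-sample clean-base totals.
#' @param n_exclusive_large,n_exclusive_small Number of genes reserved
#'   for planted group-exclusive nonsynonymous SNPs.
#' @param seed Integer seed; every random choice derives from it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(genome_length = 1e6, n_chroms = 2,
                          gc_content = 0.35, n_genes = 120,
                          exons_per_gene = 4, control_n = 4,
                          treated_large_n = 5, treated_normal_n = 5,
                          treated_small_n = 2, shared_pool_rate = 1e-3,
                          segregating_fraction = 0.02,
                          control_spectrum = spectrum_config(1.55e-5,
                                                             gc_at_bias = 0.35),
                          treated_spectrum = spectrum_config(1.4e-4,
                                                             gc_at_bias = 0.8),
                          clean_bases_mean = 11.2 * genome_length,
                          clean_bases_sd = 0.09 * clean_bases_mean,
                          n_exclusive_large = 3, n_exclusive_small = 2,
                          seed = 1L) {
  stop_if_not(genome_length >= 1e4, "genome_length must be >= 10 kb")
  stop_if_not(gc_content > 0 && gc_content < 1, "gc_content must be in (0,1)")
  stop_if_not(control_n >= 1, "need at least one control")
  structure(as.list(environment()), class = "cohort_config")
}

rand_seq <- function(len, gc) {
  paste(sample(DNA_BASES, len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE != "*"], character(0))
STOP_CODONS <- names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE == "*"]

#' Simulate a genome with valid gene models
#'
#' Draws random chromosome sequences at the requested GC content and
#' packs non-overlapping multi-exon genes onto both strands. Each CDS is
#' written into the genome as a valid open reading frame (ATG start, no
#' internal stop, terminal stop in transcript orientation), flanked by
#' short untranslated exon ends. Deterministic under `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List with `genome` (named character vector), `models` (list
#'   of [gene_model()]), `exclusive` (designated large/small gene ids)
#'   and `config`.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  chrom_len <- floor(config$genome_length / config$n_chroms)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  genome <- stats::setNames(
    vapply(chroms, function(ch) rand_seq(chrom_len, config$gc_content),
           character(1)), chroms)

  # layout bookkeeping: place genes sequentially with randomized gaps
  models <- vector("list", config$n_genes)
  cursor <- stats::setNames(rep(1500L, config$n_chroms), chroms)
  gi <- 0L
  for (g in seq_len(config$n_genes)) {
    ch <- chroms[(g - 1L) %% config$n_chroms + 1L]
    n_ex <- config$exons_per_gene
    ex_len <- sample(120:300, n_ex, replace = TRUE)
    ex_len <- ex_len - (ex_len %% 3)          # keep codon arithmetic simple
    in_len <- sample(60:200, max(n_ex - 1, 0), replace = TRUE)
    utr5 <- 3 * sample(4:12, 1); utr3 <- 3 * sample(4:12, 1)
    start <- cursor[[ch]] + sample(800:2500, 1)
    ex_start <- start + c(0, cumsum(ex_len[-n_ex] + in_len))
    ex_end <- ex_start + ex_len - 1L
    if (ex_end[n_ex] + 1500L > nchar(genome[[ch]])) {
      stop(sprintf("infeasible packing: cannot place %d genes in %d bp",
                   config$n_genes, config$genome_length), call. = FALSE)
    }
    cursor[[ch]] <- ex_end[n_ex]
    strand <- sample(c("+", "-"), 1)
    exons <- data.frame(start = ex_start, end = ex_end)
    cds <- exons
    if (strand == "+") {
      cds$start[1] <- cds$start[1] + utr5
      cds$end[n_ex] <- cds$end[n_ex] - utr3
    } else {
      cds$start[1] <- cds$start[1] + utr3
      cds$end[n_ex] <- cds$end[n_ex] - utr5
    }
    gi <- gi + 1L
    gene_id <- sprintf("gene%03d", gi)
    m <- gene_model(gene_id, paste0(gene_id, ".t1"), ch, strand, exons, cds)

    # write a clean ORF into the genome at the CDS positions
    cds_len <- sum(cds$end - cds$start + 1)
    n_codon <- cds_len / 3
    orf <- paste(c("ATG", sample(SENSE_CODONS, n_codon - 2, replace = TRUE),
                   sample(STOP_CODONS, 1)), collapse = "")
    if (strand == "-") orf <- rc(orf)
    off <- 0L
    for (s in seq_len(nrow(cds))) {
      w <- cds$end[s] - cds$start[s] + 1L
      substr(genome[[ch]], cds$start[s], cds$end[s]) <-
        substr(orf, off + 1L, off + w)
      off <- off + w
    }
    models[[g]] <- m
  }
  names(models) <- vapply(models, `[[`, character(1), "transcript_id")

  gene_ids <- vapply(models, `[[`, character(1), "gene_id")
  n_excl <- config$n_exclusive_large + config$n_exclusive_small
  stop_if_not(config$n_genes > n_excl, "too few genes for exclusive set")
  excl <- sample(gene_ids, n_excl)
  list(genome = genome, models = models,
       exclusive = list(
         large = sort(excl[seq_len(config$n_exclusive_large)]),
         small = sort(excl[config$n_exclusive_large + seq_len(config$n_exclusive_small)])),
       config = config)
}

# positions (per chrom) belonging to the CDS of the designated exclusive
# genes; both the shared pool and random private events avoid them so the
# planted signal is group-exclusive by construction.
exclusion_mask <- function(sim) {
  excl <- unlist(sim$exclusive, use.names = FALSE)
  out <- lapply(names(sim$genome), function(ch) integer(0))
  names(out) <- names(sim$genome)
  for (m in sim$models) {
    if (!(m$gene_id %in% excl)) next
    pos <- unlist(lapply(seq_len(nrow(m$cds)), function(i) {
      seq.int(m$cds$start[i], m$cds$end[i])
    }))
    out[[m$chrom]] <- c(out[[m$chrom]], pos)
  }
  out
}

mutate_base <- function(ref, transition) {
  partner <- c(A = "G", G = "A", C = "T", T = "C")
  if (transition) return(partner[[ref]])
  sample(setdiff(DNA_BASES, c(ref, partner[[ref]])), 1)
}

#' Simulate the shared polymorphism pool
#'
#' Standing variation segregating in the base population: Poisson-many
#' polymorphic sites (SNPs plus a small InDel share), each with a
#' population alternate-allele frequency. Individuals later draw
#' genotypes from these frequencies under Hardy-Weinberg proportions, so
#' most pool variants become "shared types" removed by the control
#' filter.
#'
#' @param sim A [simulate_genome()] result.
#' @param rate Polymorphic sites per bp.
#' @param seed Integer seed.
#' @param segregating_fraction Share of sites given an intermediate
#'   population frequency (uniform on 0.1-0.9); the rest are fixed
#'   against the reference (frequency 1).
#' @return Data frame `chrom, pos, ref, alt, vtype, freq`.
#' @export
simulate_shared_pool <- function(sim, rate, seed, segregating_fraction = 0.02) {
  set.seed(seed)
  stop_if_not(rate >= 0, "rate must be >= 0")
  mask <- exclusion_mask(sim)
  rows <- list()
  for (ch in names(sim$genome)) {
    len <- nchar(sim$genome[[ch]])
    n <- stats::rpois(1, rate * len)
    if (n == 0) next
    pos <- sample(setdiff(seq_len(len - 10L), mask[[ch]]), n)
    pos <- sort(pos)
    ref1 <- substring(sim$genome[[ch]], pos, pos)
    is_indel <- stats::runif(n) < 0.1
    df <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (!is_indel[i]) {
        alt <- mutate_base(ref1[i], stats::runif(1) < 0.53)
        data.frame(chrom = ch, pos = pos[i], ref = ref1[i], alt = alt,
                   vtype = "SNP", stringsAsFactors = FALSE)
      } else if (stats::runif(1) < 0.5) {
        ins <- paste(sample(DNA_BASES, 1 + stats::rgeom(1, 0.5), TRUE),
                     collapse = "")
        data.frame(chrom = ch, pos = pos[i], ref = ref1[i],
                   alt = paste0(ref1[i], ins), vtype = "insertion",
                   stringsAsFactors = FALSE)
      } else {
        dlen <- 1 + stats::rgeom(1, 0.5)
        data.frame(chrom = ch, pos = pos[i],
                   ref = substring(sim$genome[[ch]], pos[i], pos[i] + dlen),
                   alt = ref1[i], vtype = "deletion", stringsAsFactors = FALSE)
      }
    }))
    rows[[ch]] <- df
  }
  pool <- do.call(rbind, rows)
  if (is.null(pool)) {
    pool <- data.frame(chrom = character(), pos = integer(), ref = character(),
                       alt = character(), vtype = character(),
                       freq = numeric(), stringsAsFactors = FALSE)
    return(pool)
  }
  seg <- stats::runif(nrow(pool)) < segregating_fraction
  pool$freq <- ifelse(seg, stats::runif(nrow(pool), 0.1, 0.9), 1)
  pool <- pool[!duplicated(paste(pool$chrom, pool$pos)), , drop = FALSE]
  rownames(pool) <- NULL
  pool
}

base_class_index <- function(sim) {
  lapply(sim$genome, function(s) {
    b <- strsplit(s, "")[[1]]
    list(gc = which(b %in% c("G", "C")), at = which(b %in% c("A", "T")))
  })
}

#' Simulate one individual's variant calls
#'
#' An individual carries (a) genotypes drawn from the shared pool under
#' Hardy-Weinberg proportions and (b) private mutations from its group's
#' spectrum: Poisson-many events, SNP or InDel by `indel_fraction`,
#' transitions with `transition_fraction` (transition sites drawn from
#' G:C pairs with probability `gc_at_bias`), events inside CDS thinned
#' by `coding_depletion`, genotype heterozygous with `het_fraction`.
#' Calls are normalized and key-deduplicated; a truth table recording
#' each call's origin (`pool` / `private` / `planted`) is attached as
#' attribute `"truth"`.
#'
#' @param sim A [simulate_genome()] result.
#' @param pool A [simulate_shared_pool()] data frame.
#' @param spectrum A [spectrum_config()].
#' @param sample_id,group Sample identity.
#' @param seed Integer seed.
#' @param clean_bases Clean-base total for the sample.
#' @param planted Optional data frame of planted SNPs
#'   (`chrom, pos, ref, alt`), appended as heterozygous calls.
#' @param bases Optional precomputed [base_class_index] (internal reuse).
#' @return A [sample_variant_set()].
#' @export
simulate_sample <- function(sim, pool, spectrum, sample_id, group, seed,
                            clean_bases, planted = NULL, bases = NULL) {
  set.seed(seed)
  if (is.null(bases)) bases <- base_class_index(sim)
  mask <- exclusion_mask(sim)
  cds_pos <- lapply(names(sim$genome), function(ch) {
    unlist(lapply(sim$models, function(m) {
      if (m$chrom != ch) return(integer(0))
      unlist(lapply(seq_len(nrow(m$cds)), function(i) {
        seq.int(m$cds$start[i], m$cds$end[i])
      }))
    }), use.names = FALSE)
  })
  names(cds_pos) <- names(sim$genome)

  rows <- list(); origin <- list()

  # (a) pool genotypes under HWE
  if (nrow(pool) > 0) {
    u <- stats::runif(nrow(pool))
    hom <- u < pool$freq^2
    het <- !hom & u < pool$freq^2 + 2 * pool$freq * (1 - pool$freq)
    drawn <- pool[hom | het, , drop = FALSE]
    if (nrow(drawn) > 0) {
      drawn$geno <- ifelse(hom[hom | het], "hom_alt", "het")
      rows$pool <- data.frame(sample_id = sample_id, chrom = drawn$chrom,
                              pos = drawn$pos, ref = drawn$ref,
                              alt = drawn$alt, geno = drawn$geno,
                              vtype = drawn$vtype, stringsAsFactors = FALSE)
      origin$pool <- rep("pool", nrow(drawn))
    }
  }

  # (b) private mutations
  total_len <- sum(nchar(sim$genome))
  n_events <- stats::rpois(1, spectrum$per_base_rate * total_len)
  if (n_events > 0) {
    ev <- vector("list", n_events)
    chrom_probs <- nchar(sim$genome) / total_len
    for (i in seq_len(n_events)) {
      is_indel <- stats::runif(1) < spectrum$indel_fraction
      is_ts <- !is_indel && stats::runif(1) < spectrum$transition_fraction
      repeat {
        ch <- sample(names(sim$genome), 1, prob = chrom_probs)
        if (is_ts) {
          from_gc <- stats::runif(1) < spectrum$gc_at_bias
          cand <- if (from_gc) bases[[ch]]$gc else bases[[ch]]$at
          p <- cand[sample.int(length(cand), 1)]
        } else {
          p <- sample.int(nchar(sim$genome[[ch]]) - 10L, 1)
        }
        if (p %in% mask[[ch]]) next
        in_cds <- p %in% cds_pos[[ch]]
        if (in_cds && stats::runif(1) > spectrum$coding_depletion) next
        break
      }
      ref1 <- substring(sim$genome[[ch]], p, p)
      if (!is_indel) {
        alt <- mutate_base(ref1, is_ts)
        ev[[i]] <- data.frame(chrom = ch, pos = p, ref = ref1, alt = alt,
                              vtype = "SNP", stringsAsFactors = FALSE)
      } else if (stats::runif(1) < 0.5) {
        ins <- paste(sample(DNA_BASES,
                            1 + stats::rgeom(1, spectrum$indel_size_geometric_p),
                            TRUE), collapse = "")
        ev[[i]] <- data.frame(chrom = ch, pos = p, ref = ref1,
                              alt = paste0(ref1, ins), vtype = "insertion",
                              stringsAsFactors = FALSE)
      } else {
        dlen <- 1 + stats::rgeom(1, spectrum$indel_size_geometric_p)
        ev[[i]] <- data.frame(chrom = ch, pos = p,
                              ref = substring(sim$genome[[ch]], p, p + dlen),
                              alt = ref1, vtype = "deletion",
                              stringsAsFactors = FALSE)
      }
    }
    priv <- do.call(rbind, ev)
    priv$sample_id <- sample_id
    priv$geno <- ifelse(stats::runif(nrow(priv)) < spectrum$het_fraction,
                        "het", "hom_alt")
    rows$private <- priv[, c("sample_id", "chrom", "pos", "ref", "alt",
                             "geno", "vtype")]
    origin$private <- rep("private", nrow(priv))
  }

  if (!is.null(planted) && nrow(planted) > 0) {
    rows$planted <- data.frame(sample_id = sample_id, chrom = planted$chrom,
                               pos = planted$pos, ref = planted$ref,
                               alt = planted$alt, geno = "het", vtype = "SNP",
                               stringsAsFactors = FALSE)
    origin$planted <- rep("planted", nrow(planted))
  }

  calls <- do.call(rbind, rows)
  if (is.null(calls)) calls <- empty_calls()
  org <- unlist(origin, use.names = FALSE)
  if (nrow(calls) > 0) {
    calls <- normalize_variants(calls, sim$genome)
    keep <- !duplicated(variant_key(calls))
    calls <- calls[keep, , drop = FALSE]
    org <- org[keep]
    o <- order(calls$chrom, calls$pos, calls$ref, calls$alt)
    calls <- calls[o, , drop = FALSE]
    org <- org[o]
    rownames(calls) <- NULL
  }
  out <- sample_variant_set(calls, sample_id, group, clean_bases)
  attr(out, "truth") <- data.frame(key = variant_key(calls), origin = org,
                                   stringsAsFactors = FALSE)
  out
}

cds_to_genomic <- function(model, cds_pos) {
  widths <- model$cds$end - model$cds$start + 1
  n_seg <- nrow(model$cds)
  if (model$strand == "+") {
    before <- 0L
    for (s in seq_len(n_seg)) {
      if (cds_pos <= before + widths[s]) {
        return(model$cds$start[s] + (cds_pos - before - 1L))
      }
      before <- before + widths[s]
    }
  } else {
    after <- 0L
    for (s in rev(seq_len(n_seg))) {
      if (cds_pos <= after + widths[s]) {
        return(model$cds$end[s] - (cds_pos - after - 1L))
      }
      after <- after + widths[s]
    }
  }
  stop("cds_pos out of range", call. = FALSE)
}

# deterministic nonsynonymous site inside a gene: the second base of a
# mid-CDS codon, with the first substitution that changes the amino acid
plant_nonsyn_site <- function(model, genome) {
  cds_len <- sum(model$cds$end - model$cds$start + 1)
  codon_i <- floor(cds_len / 6)  # a middle codon, 0-based
  cds_pos <- codon_i * 3 + 2
  gpos <- cds_to_genomic(model, cds_pos)
  ref <- genome_sub(genome, model$chrom, gpos, gpos)
  partner <- c(A = "G", G = "A", C = "T", T = "C")[[ref]]
  for (alt in c(partner, setdiff(DNA_BASES, c(ref, partner)))) {
    eff <- coding_effect(model$chrom, gpos, ref, alt, model, genome)
    if (eff == "nonsynonymous") {
      return(data.frame(gene_id = model$gene_id, chrom = model$chrom,
                        pos = gpos, ref = ref, alt = alt,
                        stringsAsFactors = FALSE))
    }
  }
  stop(sprintf("no nonsynonymous substitution found in %s", model$gene_id),
       call. = FALSE)
}

#' Simulate a complete truth-annotated cohort
#'
#' Generates genome + gene models, the shared polymorphism pool, and one
#' variant set per individual (controls under the control spectrum, all
#' treated groups under the treated spectrum), planting one
#' nonsynonymous SNP per designated exclusive gene in every sample of
#' the matching phenotype group and nowhere else. All randomness derives
#' from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: list with `genome`,
#'   `models`, `pool`, `cohort` (named list of [sample_variant_set()]),
#'   `truth` (exclusive gene ids, planted sites, per-sample origins) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  sim <- simulate_genome(config)
  pool <- simulate_shared_pool(sim, config$shared_pool_rate,
                               seed = config$seed + 1L,
                               segregating_fraction = config$segregating_fraction)
  bases <- base_class_index(sim)

  by_gene <- stats::setNames(sim$models,
                             vapply(sim$models, `[[`, character(1), "gene_id"))
  planted_large <- do.call(rbind, lapply(sim$exclusive$large, function(g) {
    plant_nonsyn_site(by_gene[[g]], sim$genome)
  }))
  planted_small <- do.call(rbind, lapply(sim$exclusive$small, function(g) {
    plant_nonsyn_site(by_gene[[g]], sim$genome)
  }))

  groups <- c(rep("control", config$control_n),
              rep("treated_large", config$treated_large_n),
              rep("treated_normal", config$treated_normal_n),
              rep("treated_small", config$treated_small_n))
  ids <- c(paste0("Control_", seq_len(config$control_n)),
           paste0("Treated_", seq_len(length(groups) - config$control_n)))

  set.seed(config$seed + 2L)
  cb <- pmax(stats::rnorm(length(ids), config$clean_bases_mean,
                          config$clean_bases_sd),
             0.5 * config$clean_bases_mean)

  cohort <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    spectrum <- if (groups[i] == "control") config$control_spectrum
                else config$treated_spectrum
    planted <- switch(groups[i], treated_large = planted_large,
                      treated_small = planted_small, NULL)
    cohort[[i]] <- simulate_sample(sim, pool, spectrum, ids[i], groups[i],
                                   seed = config$seed + 10L + i,
                                   clean_bases = cb[i], planted = planted,
                                   bases = bases)
  }
  names(cohort) <- ids

  structure(list(
    genome = sim$genome, models = sim$models, pool = pool, cohort = cohort,
    truth = list(exclusive_large = sim$exclusive$large,
                 exclusive_small = sim$exclusive$small,
                 planted = rbind(
                   cbind(planted_large, group = "treated_large"),
                   cbind(planted_small, group = "treated_small")),
                 origins = lapply(cohort, attr, "truth")),
    config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d bp genome, %d gene(s), %d pool site(s), %d sample(s)\n",
              sum(nchar(x$genome)), length(x$models), nrow(x$pool),
              length(x$cohort)))
  cat(sprintf("  exclusive genes: large = %s; small = %s\n",
              paste(x$truth$exclusive_large, collapse = ","),
              paste(x$truth$exclusive_small, collapse = ",")))
  invisible(x)
}
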