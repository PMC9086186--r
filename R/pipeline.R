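#' Run the full screening pipeline
#'
#' Orchestrates the stages end to end: read the reference, gene models,
#' cohort table and per-sample VCFs; remove mutation types shared with
#' the control panel; annotate regions and coding effects; compute
#' per-sample and group burden statistics with group comparisons; run
#' term enrichment of the treated nonsynonymous gene set (when a term
#' map is given); build the nonsynonymous presence matrix and the
#' phenotype-exclusive gene lists; and write the report bundle plus a
#' JSON manifest with input checksums. The pipeline is deterministic:
#' rerunning on identical inputs reproduces every output byte for byte.
#'
#' @param vcfs Named character vector of per-sample VCF paths (names =
#'   sample ids matching the cohort table).
#' @param fasta Reference genome FASTA.
#' @param gff3 Gene models GFF3.
#' @param cohort_tsv Cohort table TSV with `sample_id`, `group`,
#'   `clean_bases`.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param term_map_tsv Optional gene-to-term TSV (see [read_term_map()]).
#' @param policy Shared-set policy (see [group_specific_variants()]).
#' @param upstream_window Upstream window in bp for region labels.
#' @param ignore_geno Match keys without the genotype class.
#' @param min_target_samples Passed to [exclusive_genes()].
#' @return Object of class `mutburden_run`: list with `cohort`
#'   (filtered + annotated sample sets), `summary` (a
#'   [burden_summary()]), `enrichment`, `presence`, `exclusive`
#'   (large/small gene lists) and `paths` of written artifacts.
#' @export
run_pipeline <- function(vcfs, fasta, gff3, cohort_tsv, out_dir = NULL,
                         term_map_tsv = NULL, policy = "leave_one_out",
                         upstream_window = 1000L, ignore_geno = FALSE,
                         min_target_samples = 1L) {
  for (f in c(vcfs, fasta, gff3, cohort_tsv, term_map_tsv)) {
    stop_if_not(file.exists(f), "input not found: %s", f)
  }
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome <- as_genome_chr(genome)
  models <- read_gene_models(gff3, genome)
  index <- build_gene_index(models)
  cohort_tab <- utils::read.table(cohort_tsv, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  stop_if_not(all(c("sample_id", "group", "clean_bases") %in% names(cohort_tab)),
              "cohort table needs sample_id, group, clean_bases")
  stop_if_not(all(names(vcfs) %in% cohort_tab$sample_id),
              "VCF sample ids missing from the cohort table")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("read", {
    out <- lapply(names(vcfs), function(id) {
      s <- read_vcf(vcfs[[id]], sample = id, genome = genome)
      i <- match(id, cohort_tab$sample_id)
      sample_variant_set(s$calls, id, cohort_tab$group[i],
                         cohort_tab$clean_bases[i])
    })
    names(out) <- names(vcfs)
    out
  })
  message(sprintf("read: %d sample(s), %s calls",
                  length(cohort),
                  format(sum(vapply(cohort, function(s) nrow(s$calls), 0)),
                         big.mark = ",")))

  filtered <- stage("filter", filter_shared(cohort, policy = policy,
                                            ignore_geno = ignore_geno))
  message(sprintf("filter: %s group-specific calls retained",
                  format(sum(vapply(filtered, function(s) nrow(s$calls), 0)),
                         big.mark = ",")))

  annotated <- stage("annotate", lapply(filtered, function(s) {
    s$calls <- annotate_variants(s$calls, index, genome, upstream_window)
    s
  }))

  summary <- stage("stats", burden_summary(summarize_samples(annotated)))

  universe <- sort(unique(vapply(models, `[[`, character(1), "gene_id")))
  enr <- NULL
  if (!is.null(term_map_tsv)) {
    enr <- stage("enrich", {
      tm <- read_term_map(term_map_tsv)
      treated <- annotated[vapply(annotated, `[[`, character(1), "group") !=
                             "control"]
      query <- sort(unique(unlist(lapply(treated, function(s) {
        s$calls$gene_id[s$calls$effect %in%
                          c("nonsynonymous", "stopgain", "stoploss")]
      }))))
      enrich(query, tm, universe)
    })
  }

  presence <- stage("screen", build_presence_matrix(annotated))
  excl <- list(
    large = exclusive_genes(presence, "treated_large",
                            min_target_samples = min_target_samples),
    small = exclusive_genes(presence, "treated_small",
                            min_target_samples = min_target_samples))

  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- stage("report", write_run_bundle(
      annotated, summary, enr, presence, excl, out_dir,
      inputs = c(vcfs, fasta = fasta, gff3 = gff3, cohort = cohort_tsv),
      config = list(policy = policy, upstream_window = upstream_window,
                    ignore_geno = ignore_geno,
                    min_target_samples = min_target_samples)))
  }

  structure(list(cohort = annotated, summary = summary, enrichment = enr,
                 presence = presence, exclusive = excl, paths = paths),
            class = "mutburden_run")
}

#' @export
print.mutburden_run <- function(x, ...) {
  cat("<mutburden_run>\n")
  print(x$summary)
  cat(sprintf("Exclusive genes: large = %s; small = %s\n",
              paste(x$exclusive$large, collapse = ",") %||% "",
              paste(x$exclusive$small, collapse = ",") %||% ""))
  invisible(x)
}

comparisons_table <- function(summary) {
  if (length(summary$comparisons) == 0) {
    return(data.frame(metric = character(), test = character(),
                      transformation = character(), levene_p = numeric(),
                      statistic = numeric(), p_value = numeric(),
                      significant = logical()))
  }
  do.call(rbind, lapply(summary$comparisons, function(cmp) {
    data.frame(metric = cmp$metric, test = cmp$test,
               transformation = cmp$transformation, levene_p = cmp$levene_p,
               statistic = cmp$statistic, p_value = cmp$p_value,
               significant = cmp$significant, stringsAsFactors = FALSE)
  }))
}

write_run_bundle <- function(annotated, summary, enr, presence, excl,
                             out_dir, inputs, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(
    annotated = file.path(out_dir, "annotated_variants.tsv"),
    per_sample = file.path(out_dir, "per_sample_summary.tsv"),
    group = file.path(out_dir, "group_summary.tsv"),
    comparisons = file.path(out_dir, "comparisons.tsv"),
    enrichment = file.path(out_dir, "enrichment.tsv"),
    presence = file.path(out_dir, "presence_matrix.tsv"),
    exclusive_large = file.path(out_dir, "exclusive_genes_large.tsv"),
    exclusive_small = file.path(out_dir, "exclusive_genes_small.tsv"),
    manifest = file.path(out_dir, "manifest.json"))
  wt <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  all_calls <- do.call(rbind, lapply(annotated, `[[`, "calls"))
  rownames(all_calls) <- NULL
  wt(all_calls, p$annotated)
  wt(summary$per_sample, p$per_sample)
  wt(summary$group_stats, p$group)
  wt(comparisons_table(summary), p$comparisons)
  if (is.null(enr)) {
    enr <- data.frame(term_id = character(), category = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), p_value = numeric(), fdr = numeric())
  }
  wt(enr, p$enrichment)
  pm <- data.frame(gene_id = rownames(presence),
                   unclass(presence) * 1L, check.names = FALSE)
  wt(pm, p$presence)
  wt(data.frame(gene_id = excl$large), p$exclusive_large)
  wt(data.frame(gene_id = excl$small), p$exclusive_small)
  jsonlite::write_json(
    list(tool = "mutburden",
         version = as.character(utils::packageVersion("mutburden")),
         config = config,
         inputs = as.list(stats::setNames(unname(tools::md5sum(unname(inputs))),
                                          basename(unname(inputs))))),
    p$manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  p
}
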