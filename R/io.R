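#' Write synthetic-cohort inputs to disk
#'
#' Materialises a [simulate_cohort()] result as the standard file
#' formats the pipeline consumes: reference FASTA, gene-model GFF3, one
#' VCF v4.2 per sample, a cohort TSV (`sample_id, group, clean_bases`),
#' truth TSVs (pool, planted sites, per-call origins) and a JSON run
#' manifest holding the full configuration and seed.
#'
#' @param sim A `synthetic_cohort` object.
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(
    fasta = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "genes.gff3"),
    cohort = file.path(dir, "cohort.tsv"),
    pool = file.path(dir, "truth_pool.tsv"),
    planted = file.path(dir, "truth_planted.tsv"),
    origins = file.path(dir, "truth_origins.tsv"),
    manifest = file.path(dir, "manifest.json"))

  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome), p$fasta)
  write_gff3(sim$models, p$gff3)

  vcfs <- character(0)
  for (s in sim$cohort) {
    f <- file.path(dir, paste0(s$sample_id, ".vcf"))
    write_vcf(s, f, sim$genome)
    vcfs[s$sample_id] <- f
  }
  p$vcfs <- vcfs

  cohort_tab <- data.frame(
    sample_id = vapply(sim$cohort, `[[`, character(1), "sample_id"),
    group = vapply(sim$cohort, `[[`, character(1), "group"),
    clean_bases = vapply(sim$cohort, `[[`, numeric(1), "clean_bases"))
  utils::write.table(cohort_tab, p$cohort, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$pool, p$pool, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth$planted, p$planted, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  origins <- do.call(rbind, lapply(names(sim$truth$origins), function(id) {
    o <- sim$truth$origins[[id]]
    if (nrow(o) == 0) return(NULL)
    cbind(sample_id = id, o)
  }))
  utils::write.table(origins, p$origins, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cfg <- sim$config
  cfg$control_spectrum <- unclass(cfg$control_spectrum)
  cfg$treated_spectrum <- unclass(cfg$treated_spectrum)
  jsonlite::write_json(list(tool = "mutburden",
                            version = as.character(utils::packageVersion("mutburden")),
                            config = unclass(cfg)),
                       p$manifest, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(p)
}

#' Write gene models as GFF3
#'
#' @param models List of [gene_model()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  rows <- list()
  for (m in models) {
    widths <- m$cds$end - m$cds$start + 1
    seg_order <- if (m$strand == "+") seq_len(nrow(m$cds)) else rev(seq_len(nrow(m$cds)))
    phase <- integer(nrow(m$cds))
    before <- 0L
    for (s in seg_order) {
      phase[s] <- (3L - before %% 3L) %% 3L
      before <- before + widths[s]
    }
    add <- function(type, start, end, id, parent, ph = NA_integer_) {
      data.frame(chrom = m$chrom, start = start, end = end, type = type,
                 id = id, parent = parent, strand = m$strand, phase = ph,
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- rbind(
      add("gene", m$start, m$end, m$gene_id, NA_character_),
      add("mRNA", m$start, m$end, m$transcript_id, m$gene_id),
      add("exon", m$exons$start, m$exons$end,
          paste0(m$transcript_id, ".exon", seq_len(nrow(m$exons))),
          m$transcript_id),
      add("CDS", m$cds$start, m$cds$end,
          paste0(m$transcript_id, ".cds", seq_len(nrow(m$cds))),
          m$transcript_id, phase))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$source <- "mutburden"
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$id
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$parent), "", df$parent)
  S4Vectors::mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a sample's calls as VCF v4.2
#'
#' Minimal single-sample VCF with GT genotypes (`0/1` for het, `1/1`
#' for hom-alt), sorted by chromosome and position.
#'
#' @param sample A [sample_variant_set()].
#' @param path Output file.
#' @param genome Reference sequences (for contig header lines).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sample, path, genome = NULL) {
  calls <- sample$calls
  calls <- calls[order(calls$chrom, calls$pos, calls$ref, calls$alt), ,
                 drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2", "##source=mutburden")
  if (!is.null(genome)) {
    genome <- as_genome_chr(genome)
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(genome),
                          nchar(genome)))
  }
  hdr <- c(hdr,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample$sample_id), collapse = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                  calls$chrom, calls$pos, calls$ref, calls$alt,
                  ifelse(calls$geno == "hom_alt", "1/1", "0/1"))
  writeLines(c(hdr, body), path)
  invisible(path)
}
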