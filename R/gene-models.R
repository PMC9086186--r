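#' Construct a gene model
#'
#' A gene model is one transcript of one gene: strand, ordered exons and
#' CDS segments in 1-based inclusive genomic coordinates. CDS segments
#' must lie inside exons and total a multiple of three.
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds Data frames (or 2-column matrices) with `start`,
#'   `end` columns, 1-based inclusive.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand, exons, cds) {
  exons <- as.data.frame(exons); cds <- as.data.frame(cds)
  names(exons)[1:2] <- names(cds)[1:2] <- c("start", "end")
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  stop_if_not(strand %in% c("+", "-"), "strand must be '+' or '-'")
  stop_if_not(all(exons$end >= exons$start), "exon end < start")
  if (nrow(exons) > 1) {
    stop_if_not(all(exons$start[-1] > exons$end[-nrow(exons)]),
                "exons of %s overlap or are unsorted", transcript_id)
  }
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
    stop_if_not(inside, "CDS segment of %s outside exons", transcript_id)
  }
  cds_len <- sum(cds$end - cds$start + 1)
  stop_if_not(cds_len %% 3 == 0,
              "CDS length of %s (%d) is not a multiple of 3", transcript_id, cds_len)
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds,
                 start = min(exons$start), end = max(exons$end)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s / %s  %s:%d-%d (%s)  %d exon(s), CDS %d bp\n",
              x$gene_id, x$transcript_id, x$chrom, x$start, x$end, x$strand,
              nrow(x$exons), sum(x$cds$end - x$cds$start + 1)))
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Parses `gene` / `mRNA` (or `transcript`) / `exon` / `CDS` features
#' linked by `Parent` attributes into a list of [gene_model()] objects.
#' When a reference genome is supplied, each CDS is translated and models
#' that do not run from a start codon to a stop codon without internal
#' stops are reported (attribute `"violations"`) but kept.
#'
#' @param path GFF3 file.
#' @param genome Optional reference (named character vector or
#'   `DNAStringSet`) for translation validation.
#' @return List of `gene_model` objects named by transcript id.
#' @export
read_gene_models <- function(path, genome = NULL) {
  stop_if_not(file.exists(path), "GFF3 not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  feat <- data.frame(
    type = as.character(gr$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = as.character(gr$ID),
    parent = sub(",.*$", "", S4Vectors::unstrsplit(gr$Parent, ",")),
    stringsAsFactors = FALSE)
  tx <- feat[feat$type %in% c("mRNA", "transcript"), , drop = FALSE]
  stop_if_not(nrow(tx) > 0, "no mRNA/transcript features in %s", path)
  ex <- feat[feat$type == "exon", , drop = FALSE]
  cd <- feat[feat$type == "CDS", , drop = FALSE]

  models <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    tid <- tx$id[i]
    e <- ex[ex$parent == tid, , drop = FALSE]
    k <- cd[cd$parent == tid, , drop = FALSE]
    stop_if_not(nrow(e) > 0 && nrow(k) > 0,
                "transcript %s lacks exon or CDS features", tid)
    gene <- tx$parent[i]
    models[[i]] <- gene_model(
      gene_id = if (is.na(gene) || gene == "") tid else gene,
      transcript_id = tid, chrom = tx$chrom[i], strand = tx$strand[i],
      exons = data.frame(start = e$start, end = e$end),
      cds = data.frame(start = k$start, end = k$end))
  }
  names(models) <- vapply(models, `[[`, character(1), "transcript_id")

  if (!is.null(genome)) {
    genome <- as_genome_chr(genome)
    bad <- character(0)
    for (m in models) {
      aa <- translate_cds(m, genome)
      if (substr(aa, 1, 1) != "M" ||
          substr(aa, nchar(aa), nchar(aa)) != "*" ||
          grepl("\\*", substr(aa, 1, nchar(aa) - 1))) {
        bad <- c(bad, m$transcript_id)
      }
    }
    if (length(bad)) {
      message(sprintf("%d gene model(s) fail CDS translation checks: %s",
                      length(bad), paste(utils::head(bad, 5), collapse = ", ")))
    }
    attr(models, "violations") <- bad
  }
  models
}

rc <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# spliced CDS in transcript orientation
spliced_cds <- function(model, genome) {
  segs <- vapply(seq_len(nrow(model$cds)), function(i) {
    genome_sub(genome, model$chrom, model$cds$start[i], model$cds$end[i])
  }, character(1))
  s <- paste(segs, collapse = "")
  if (model$strand == "-") rc(s) else s
}

translate_cds <- function(model, genome) {
  s <- spliced_cds(model, genome)
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     no.init.codon = TRUE))
}
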