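#' Build an interval index over gene models
#'
#' Packs gene spans, exons and CDS segments into `GRanges` so that region
#' and coding-effect queries are overlap lookups rather than linear scans.
#'
#' @param models List of [gene_model()] objects (e.g. from
#'   [read_gene_models()]). Transcript ids must be unique.
#' @return Object of class `gene_index`.
#' @export
build_gene_index <- function(models) {
  stop_if_not(length(models) > 0, "no gene models supplied")
  tids <- vapply(models, `[[`, character(1), "transcript_id")
  stop_if_not(!anyDuplicated(tids), "duplicate transcript ids: %s",
              paste(unique(tids[duplicated(tids)]), collapse = ", "))
  names(models) <- tids

  all_chroms <- unique(vapply(models, `[[`, character(1), "chrom"))
  span <- gather_granges(lapply(models, function(m) {
    list(chrom = m$chrom, start = m$start, end = m$end,
         tid = m$transcript_id)
  }), all_chroms)
  exon <- gather_granges(lapply(models, function(m) {
    list(chrom = rep(m$chrom, nrow(m$exons)), start = m$exons$start,
         end = m$exons$end, tid = rep(m$transcript_id, nrow(m$exons)))
  }), all_chroms)
  cds <- gather_granges(lapply(models, function(m) {
    if (nrow(m$cds) == 0) return(NULL)
    list(chrom = rep(m$chrom, nrow(m$cds)), start = m$cds$start,
         end = m$cds$end, tid = rep(m$transcript_id, nrow(m$cds)))
  }), all_chroms)
  structure(list(models = models, chroms = all_chroms,
                 span = span, exon = exon, cds = cds),
            class = "gene_index")
}

#' @export
print.gene_index <- function(x, ...) {
  cat(sprintf("<gene_index> %d transcript(s), %d exon(s), %d CDS segment(s)\n",
              length(x$models), length(x$exon), length(x$cds)))
  invisible(x)
}

# build one GRanges from a list of {chrom,start,end,tid} chunks with a
# common seqlevel universe (avoids pairwise c() over many objects)
gather_granges <- function(chunks, seqlevels) {
  chunks <- Filter(Negate(is.null), unname(chunks))
  chrom <- unlist(lapply(chunks, `[[`, "chrom"), use.names = FALSE)
  start <- unlist(lapply(chunks, `[[`, "start"), use.names = FALSE)
  end <- unlist(lapply(chunks, `[[`, "end"), use.names = FALSE)
  tid <- unlist(lapply(chunks, `[[`, "tid"), use.names = FALSE)
  if (length(chrom) == 0) {
    g <- GenomicRanges::GRanges(seqlengths = stats::setNames(
      rep(NA_integer_, length(seqlevels)), seqlevels))
    S4Vectors::mcols(g)$tid <- character(0)
    return(g)
  }
  GenomicRanges::GRanges(factor(chrom, levels = seqlevels),
                         IRanges::IRanges(start, end), tid = tid)
}

index_upstream <- function(index, window) {
  gather_granges(lapply(index$models, function(m) {
    if (m$strand == "+") {
      s <- max(1L, m$start - window); e <- m$start - 1L
    } else {
      s <- m$end + 1L; e <- m$end + window
    }
    if (e < s) return(NULL)
    list(chrom = m$chrom, start = s, end = e, tid = m$transcript_id)
  }), index$chroms)
}

# query ranges on the index's seqlevel universe (chroms absent from the
# index keep their own level, so they simply never overlap)
query_granges <- function(chrom, start, end, index) {
  lv <- union(index$chroms, unique(chrom))
  GenomicRanges::GRanges(factor(chrom, levels = lv),
                         IRanges::IRanges(start, end))
}

hit_tids <- function(query, subject) {
  ov <- GenomicRanges::findOverlaps(query, subject, ignore.strand = TRUE)
  split(subject$tid[S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov))
}

#' Assign region labels to variant positions
#'
#' Labels each call `exonic`, `intronic`, `upstream` or `intergenic` by
#' its position, with precedence exonic > intronic > upstream >
#' intergenic across overlapping genes. "Upstream" means within
#' `upstream_window` bp 5' of a gene's strand-aware start. Positions on
#' sequences absent from the index are intergenic.
#'
#' @param calls Variant table (`chrom`, `pos` columns).
#' @param index A [build_gene_index()] object.
#' @param upstream_window Width of the upstream window in bp (default
#'   1000, the usual annotator convention).
#' @return List with `region` (character vector) and `gene_id`
#'   (identifier of the gene justifying the label; `NA` for intergenic).
#' @export
annotate_region <- function(calls, index, upstream_window = 1000L) {
  n <- nrow(calls)
  q <- query_granges(calls$chrom, calls$pos, calls$pos, index)
  region <- rep("intergenic", n)
  gene <- rep(NA_character_, n)

  pick <- function(hits, rows, label) {
    for (i in names(hits)) {
      r <- as.integer(i)
      if (region[r] == "intergenic") {
        region[r] <<- label
        tid <- sort(unique(hits[[i]]))[1]  # deterministic tie-break
        gene[r] <<- index$models[[tid]]$gene_id
      }
    }
  }
  pick(hit_tids(q, index$exon), calls, "exonic")
  pick(hit_tids(q, index$span), calls, "intronic")  # in-span, not exonic
  up <- index_upstream(index, as.integer(upstream_window))
  if (length(up)) pick(hit_tids(q, up), calls, "upstream")
  list(region = region, gene_id = gene)
}

effect_severity <- c(synonymous = 1, nonsynonymous = 2, stoploss = 3, stopgain = 4)

#' Coding effect of a SNP under one gene model
#'
#' Rebuilds the codon containing the site in transcript orientation
#' (reverse-complementing for minus-strand models), substitutes the
#' alternate base and translates with the standard genetic code.
#'
#' @param chrom,pos,ref,alt A single SNP (genome forward strand).
#' @param model A [gene_model()] whose CDS contains `pos`.
#' @param genome Reference sequences.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"stopgain"`,
#'   `"stoploss"` (stop codon kept / amino acid unchanged count as
#'   synonymous).
#' @export
coding_effect <- function(chrom, pos, ref, alt, model, genome) {
  coding_effect_impl(chrom, pos, ref, alt, model, as_genome_chr(genome))
}

coding_effect_impl <- function(chrom, pos, ref, alt, model, genome) {
  stop_if_not(nchar(ref) == 1 && nchar(alt) == 1 && ref != alt,
              "coding_effect is defined for SNPs")
  stop_if_not(identical(chrom, model$chrom), "chromosome mismatch with model")
  seg <- which(model$cds$start <= pos & model$cds$end >= pos)
  stop_if_not(length(seg) == 1,
              "position %d is not in the CDS of %s; use annotate_region() first",
              pos, model$transcript_id)
  obs <- genome_sub(genome, chrom, pos, pos)
  stop_if_not(obs == ref, "REF mismatch at %s:%d ('%s' vs genome '%s')",
              chrom, pos, ref, obs)

  widths <- model$cds$end - model$cds$start + 1
  if (model$strand == "+") {
    cds_pos <- sum(widths[seq_len(seg - 1)]) + (pos - model$cds$start[seg] + 1)
    alt_tx <- alt
  } else {
    after <- if (seg < nrow(model$cds)) sum(widths[(seg + 1):nrow(model$cds)]) else 0
    cds_pos <- after + (model$cds$end[seg] - pos + 1)
    alt_tx <- chartr("ACGT", "TGCA", alt)
  }
  cds_seq <- spliced_cds(model, genome)
  codon_i <- (cds_pos - 1) %/% 3
  offset <- (cds_pos - 1) %% 3
  codon <- substr(cds_seq, codon_i * 3 + 1, codon_i * 3 + 3)
  mut <- codon
  substr(mut, offset + 1, offset + 1) <- alt_tx
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[mut]]
  if (aa_ref == "*" && aa_alt == "*") "synonymous"
  else if (aa_ref == "*") "stoploss"
  else if (aa_alt == "*") "stopgain"
  else if (aa_ref == aa_alt) "synonymous"
  else "nonsynonymous"
}

#' Does an InDel touch coding sequence?
#'
#' `TRUE` iff the affected reference interval `[pos, pos + nchar(ref) - 1]`
#' intersects any CDS segment. For a normalized insertion the affected
#' interval is the single anchor base.
#'
#' @param chrom,pos,ref A single normalized InDel.
#' @param index A [build_gene_index()] object.
#' @return Logical scalar.
#' @export
cds_indel_flag <- function(chrom, pos, ref, index) {
  q <- query_granges(chrom, pos, pos + nchar(ref) - 1L, index)
  length(GenomicRanges::findOverlaps(q, index$cds, ignore.strand = TRUE)) > 0
}

#' Annotate a variant table
#'
#' Adds `region`, `effect` and `gene_id` columns. Effects are computed
#' for SNPs lying in CDS only (exon positions outside CDS stay exonic
#' with `effect = NA`); when a SNP hits the CDS of several transcripts
#' the most severe effect is kept (stopgain > stoploss > nonsynonymous >
#' synonymous). For InDels, `effect` is `"cds_indel"` when the call
#' touches coding sequence, else `NA`.
#'
#' @param calls Variant table.
#' @param index A [build_gene_index()] object.
#' @param genome Reference sequences.
#' @param upstream_window Passed to [annotate_region()].
#' @return The table with `region`, `effect`, `gene_id` columns added.
#' @export
annotate_variants <- function(calls, index, genome, upstream_window = 1000L) {
  genome <- as_genome_chr(genome)
  n <- nrow(calls)
  if (n == 0L) {
    calls$region <- character(0); calls$effect <- character(0)
    calls$gene_id <- character(0)
    return(calls)
  }
  reg <- annotate_region(calls, index, upstream_window)
  calls$region <- reg$region
  calls$effect <- NA_character_
  calls$gene_id <- reg$gene_id

  q <- query_granges(calls$chrom, calls$pos, calls$pos, index)
  cds_hits <- hit_tids(q, index$cds)
  snp_rows <- which(calls$vtype == "SNP")
  for (r in intersect(snp_rows, as.integer(names(cds_hits)))) {
    best <- NULL; best_tid <- NULL
    for (tid in sort(unique(cds_hits[[as.character(r)]]))) {
      eff <- coding_effect_impl(calls$chrom[r], calls$pos[r], calls$ref[r],
                                calls$alt[r], index$models[[tid]], genome)
      if (is.null(best) || effect_severity[[eff]] > effect_severity[[best]]) {
        best <- eff; best_tid <- tid
      }
    }
    calls$effect[r] <- best
    calls$gene_id[r] <- index$models[[best_tid]]$gene_id
  }
  indel_rows <- which(calls$vtype != "SNP")
  for (r in indel_rows) {
    if (cds_indel_flag(calls$chrom[r], calls$pos[r], calls$ref[r], index)) {
      calls$effect[r] <- "cds_indel"
    }
  }
  calls
}
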