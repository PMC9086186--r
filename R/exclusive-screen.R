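#' Gene x sample nonsynonymous-presence matrix
#'
#' Builds the screening matrix behind the phenotype-exclusive gene
#' search: rows are the genes carrying at least one amino-acid-changing
#' SNP in at least one sample, columns are samples, cells record whether
#' that sample's group-specific variant set contains such a SNP in that
#' gene.
#'
#' @param cohort Named list of filtered, annotated
#'   [sample_variant_set()] objects.
#' @param effects Effect labels that count as presence. Stopgain and
#'   stoploss change the protein and are counted by default; set
#'   `effects = "nonsynonymous"` to restrict to missense only.
#' @return Object of class `presence_matrix`: logical matrix (genes x
#'   samples) with a `groups` attribute mapping sample to group.
#' @export
build_presence_matrix <- function(cohort,
                                  effects = c("nonsynonymous", "stopgain",
                                              "stoploss")) {
  sample_ids <- vapply(cohort, `[[`, character(1), "sample_id")
  groups <- vapply(cohort, `[[`, character(1), "group")
  hits <- lapply(cohort, function(s) {
    calls <- s$calls
    stop_if_not(all(c("effect", "gene_id") %in% names(calls)),
                "calls must be annotated before screening")
    unique(calls$gene_id[calls$vtype == "SNP" & calls$effect %in% effects &
                           !is.na(calls$gene_id)])
  })
  genes <- sort(unique(unlist(hits, use.names = FALSE)))
  mat <- matrix(FALSE, nrow = length(genes), ncol = length(cohort),
                dimnames = list(genes, sample_ids))
  for (j in seq_along(cohort)) mat[hits[[j]], j] <- TRUE
  structure(mat, groups = stats::setNames(groups, sample_ids),
            class = c("presence_matrix", class(mat)))
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix> %d gene(s) x %d sample(s)\n",
              nrow(x), ncol(x)))
  if (nrow(x)) print(utils::head(unclass(x), 10))
  invisible(x)
}

#' Phenotype-exclusive mutated genes
#'
#' Genes whose amino-acid-changing SNPs occur in at least
#' `min_target_samples` samples of the target group and in no sample of
#' any excluded group — the screen used to nominate growth-related
#' candidates from the largest and smallest animals.
#'
#' @param matrix A [build_presence_matrix()] result.
#' @param target_group Group whose private genes are sought.
#' @param excluded_groups Groups in which any presence disqualifies a
#'   gene; defaults to every other group in the matrix.
#' @param min_target_samples Minimum number of target-group samples that
#'   must carry the gene (default 1, i.e. "any").
#' @return Sorted character vector of gene ids.
#' @export
exclusive_genes <- function(matrix, target_group, excluded_groups = NULL,
                            min_target_samples = 1L) {
  groups <- attr(matrix, "groups")
  known <- unique(groups)
  stop_if_not(target_group %in% known, "unknown target group '%s'",
              target_group)
  if (is.null(excluded_groups)) excluded_groups <- setdiff(known, target_group)
  stop_if_not(all(excluded_groups %in% known), "unknown excluded group(s): %s",
              paste(setdiff(excluded_groups, known), collapse = ", "))
  if (nrow(matrix) == 0) return(character(0))
  tgt <- matrix[, groups[colnames(matrix)] == target_group, drop = FALSE]
  exc <- matrix[, groups[colnames(matrix)] %in% excluded_groups, drop = FALSE]
  keep <- rowSums(tgt) >= min_target_samples & rowSums(exc) == 0
  sort(rownames(matrix)[keep])
}
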