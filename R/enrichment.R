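#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance that a random
#' draw of `n` genes from a universe of `N`, of which `K` belong to the
#' term, contains at least `k` term genes. Evaluated in log space via
#' the distribution's survival function for numerical stability.
#'
#' @param N Universe size.
#' @param K Term genes in the universe.
#' @param n Query set size.
#' @param k Overlap between query and term.
#' @return The p-value (exactly 1 when `k == 0`).
#' @examples
#' hypergeom_upper_tail(10, 5, 4, 3)  # 55/210
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  stop_if_not(all(K >= 0 & K <= N) && all(n >= 0 & n <= N),
              "need 0 <= K, n <= N")
  stop_if_not(all(k >= 0 & k <= pmin(K, n)), "need 0 <= k <= min(K, n)")
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: with p-values sorted ascending,
#' `q_i = min_{j >= i} p_j * m / j`, clipped at 1, returned in the input
#' order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(p) {
  stop_if_not(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Read a gene-to-term map
#'
#' Three-column TSV: `term_id`, `category` (`BP`, `CC`, `MF` or
#' `pathway`), `gene_id`, one gene per row.
#'
#' @param path TSV file.
#' @return Data frame with those columns.
#' @export
read_term_map <- function(path) {
  tm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stop_if_not(all(c("term_id", "category", "gene_id") %in% names(tm)),
              "term map needs columns term_id, category, gene_id")
  tm
}

#' Hypergeometric over-representation test of a gene set
#'
#' Tests each annotation term for over-representation of the query genes
#' within a finite universe, with BH-FDR correction applied within each
#' term category (mirroring how GO namespaces are usually treated), or
#' globally.
#'
#' @param query Character vector of query gene ids. Genes outside the
#'   universe are dropped with a message.
#' @param term_map Data frame with `term_id`, `category`, `gene_id`
#'   columns (one gene per row, see [read_term_map()]).
#' @param universe Character vector of background gene ids (e.g. all
#'   genes of the annotation).
#' @param fdr_scope `"category"` (default) or `"global"`.
#' @return Data frame with one row per term present in the universe:
#'   `term_id`, `category`, `N`, `K`, `n`, `k`, `p_value`, `fdr`, sorted
#'   by p-value.
#' @export
enrich <- function(query, term_map, universe,
                   fdr_scope = c("category", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  universe <- unique(universe)
  stop_if_not(length(universe) > 0, "empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    message(sprintf("%d query gene(s) outside the universe dropped",
                    length(outside)))
    query <- intersect(query, universe)
  }
  tm <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  terms <- unique(tm[, c("term_id", "category")])
  N <- length(universe); n <- length(query)
  res <- do.call(rbind, lapply(seq_len(nrow(terms)), function(i) {
    genes <- unique(tm$gene_id[tm$term_id == terms$term_id[i]])
    K <- length(genes); k <- length(intersect(genes, query))
    data.frame(term_id = terms$term_id[i], category = terms$category[i],
               N = N, K = K, n = n, k = k,
               p_value = hypergeom_upper_tail(N, K, n, k),
               stringsAsFactors = FALSE)
  }))
  if (is.null(res)) {
    return(data.frame(term_id = character(), category = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), p_value = numeric(), fdr = numeric()))
  }
  res$fdr <- NA_real_
  if (fdr_scope == "category") {
    for (cat in unique(res$category)) {
      i <- res$category == cat
      res$fdr[i] <- bh_adjust(res$p_value[i])
    }
  } else {
    res$fdr <- bh_adjust(res$p_value)
  }
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
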