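#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

DNA_BASES <- c("A", "C", "G", "T")

stop_if_not <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = call.)
}

is_dna_string <- function(x) {
  nzchar(x) & !grepl("[^ACGT]", x)
}

# genome: named character vector of uppercase sequences, or a
# Biostrings::DNAStringSet; always coerced to the character form internally.
as_genome_chr <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- toupper(as.character(genome))
    names(out) <- names(genome)
    return(out)
  }
  stop_if_not(is.character(genome) && !is.null(names(genome)),
              "genome must be a named character vector or DNAStringSet")
  toupper(genome)
}

genome_sub <- function(genome, chrom, start, end) {
  stop_if_not(chrom %in% names(genome), "sequence '%s' not in genome", chrom)
  substr(genome[[chrom]], start, end)
}
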