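#' Count k-mers in a genome
#'
#' Counts overlapping k-length windows (step 1) on the forward strand, per
#' contig: no window spans a contig junction, and any window containing a
#' non-ACGT character is skipped entirely. Counting is sparse, so large k
#' (up to 26) on megabase genomes is cheap.
#'
#' @param genome A [genome_seq()] object or a character vector of contigs.
#' @param k Word length, 1..26.
#' @return An object of class `kmer_table` with elements `k`, `codes`
#'   (2-bit packed numeric codes, ascending), `counts`, `total_windows`
#'   and `distinct`.
#' @export
count_kmers <- function(genome, k) {
  if (is.character(genome)) genome <- genome_seq(genome)
  stopifnot(inherits(genome, "genome_seq"))
  k <- as.integer(k)
  if (k < 1 || k > 26) stop("k must be between 1 and 26")
  res <- .count_kmers_cpp(genome$contigs, k)
  if (res$total_windows == 0) {
    if (all(nchar(genome$contigs) < k))
      stop("k = ", k, " exceeds the length of every contig: empty k-mer table")
    stop("no ambiguity-free window of length ", k, ": empty k-mer table")
  }
  structure(
    list(k = k, codes = res$codes, counts = res$counts,
         total_windows = res$total_windows, distinct = length(res$counts)),
    class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("<kmer_table> k=%d: %d distinct words over %.0f windows\n",
              x$k, x$distinct, x$total_windows))
  invisible(x)
}

#' Decode a k-mer table's codes into words
#'
#' @param table A [count_kmers()] result.
#' @return Character vector of k-mer strings, parallel to `table$counts`.
#' @export
kmer_strings <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  .decode_kmers_cpp(table$codes, table$k)
}

#' Named k-mer count vector
#'
#' Convenience accessor returning counts named by their k-mer strings.
#'
#' @inheritParams kmer_strings
#' @return Named numeric vector.
#' @export
kmer_counts <- function(table) {
  setNames(table$counts, kmer_strings(table))
}

#' Write a k-mer frequency table as TSV
#'
#' @inheritParams kmer_strings
#' @param path Output path; columns `kmer`, `count`.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(table, path) {
  df <- data.frame(kmer = kmer_strings(table), count = table$counts)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Empirical k-mer entropy in bits
#'
#' Shannon entropy of the empirical k-mer distribution,
#' \eqn{-\sum_i p_i \log_2 p_i} with \eqn{p_i = n_i / \sum_j n_j}.
#'
#' @param table A [count_kmers()] result.
#' @return Entropy in bits (0 for a single distinct word).
#' @export
kmer_entropy <- function(table) {
  stopifnot(inherits(table, "kmer_table"), table$total_windows >= 1)
  p <- table$counts / table$total_windows
  -sum(p * log2(p))
}

#' Hapax statistics of a k-mer table
#'
#' A hapax is a k-mer with absolute frequency exactly 1 in the frequency
#' table. The percentage is taken relative to the number of distinct
#' k-mers in the table, on a 0-100 scale.
#'
#' @param table A [count_kmers()] result.
#' @return A list of class `hapax_stats` with `n_hapax`, `distinct` and
#'   `hapax_percentage`.
#' @export
hapax_stats <- function(table) {
  stopifnot(inherits(table, "kmer_table"), table$distinct >= 1)
  n1 <- sum(table$counts == 1)
  structure(
    list(k = table$k, n_hapax = n1, distinct = table$distinct,
         hapax_percentage = 100 * n1 / table$distinct),
    class = "hapax_stats")
}

#' @export
print.hapax_stats <- function(x, ...) {
  cat(sprintf("<hapax_stats> k=%d: %d hapaxes of %d distinct (%.2f%%)\n",
              x$k, x$n_hapax, x$distinct, x$hapax_percentage))
  invisible(x)
}
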