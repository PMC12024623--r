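#' Expected occurrence per possible k-mer
#'
#' Under a uniform model every one of the \eqn{4^k} possible words is
#' expected \eqn{EV = \sum_j n_j / 4^k} times.
#'
#' @param table A [count_kmers()] result.
#' @return EV, a single number.
#' @export
expected_value <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  table$total_windows / 4^table$k
}

#' Per-k genomic signature component
#'
#' Mean absolute deviation of the k-mer counts from their uniform
#' expectation, normalized by the window total:
#' \eqn{GS_k = \frac{1}{\sum_j n_j}\sum_{i=1}^{4^k} |n_i - EV|}, with
#' \eqn{n_i = 0} for words absent from the genome. The mass of absent words
#' is evaluated in closed form as \eqn{(4^k - d)\,EV}, never by dense
#' enumeration, so k up to 26 is safe.
#'
#' @param table A [count_kmers()] result.
#' @return The GS_k value, in \eqn{[0, 2(1 - 4^{-k})]}.
#' @export
gs_k <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  ev <- expected_value(table)
  (sum(abs(table$counts - ev)) + (4^table$k - table$distinct) * ev) /
    table$total_windows
}

#' Composition-preserving genome randomization
#'
#' Returns a seeded per-contig permutation (shuffle) of the bases: length
#' and base composition are preserved exactly, contig boundaries are kept.
#'
#' @param genome A [genome_seq()] object.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return A shuffled [genome_seq()].
#' @export
randomize_genome <- function(genome, seed = NULL) {
  stopifnot(inherits(genome, "genome_seq"))
  shuffled <- with_seed(seed, {
    vapply(genome$contigs, function(s) {
      r <- charToRaw(s)
      rawToChar(r[sample.int(length(r))])
    }, "", USE.NAMES = FALSE)
  })
  genome_seq(shuffled, id = paste0(genome$id, "_shuffled"))
}

#' Genomic Signature (GS) of a genome
#'
#' For each word length k in `k_min:k_max`, computes the per-k signature
#' on the genome (`gs_g`) and on a seeded composition-preserving shuffle
#' (`gs_r`, averaged over `replicates` independent shuffles), and their
#' difference `gs_p = gs_g - gs_r`, which removes the part of the deviation
#' explained by base composition alone. The genome's GS is the maximum
#' `gs_p` across k; ties go to the smallest k.
#'
#' @param genome A [genome_seq()] object.
#' @param k_min,k_max Word-length scan range (defaults 2 and 16).
#' @param seed Integer seed for the shuffle baseline.
#' @param replicates Number of independent shuffles averaged into `gs_r`.
#' @return An object of class `gs_result`: `gs` (the metric), `k_opt`
#'   (smallest maximizing k), `per_k` (data frame with k, ev, gs_g, gs_r,
#'   gs_p), `seed`, `replicates`.
#' @export
genomic_signature <- function(genome, k_min = 2, k_max = 16, seed = NULL,
                              replicates = 1) {
  stopifnot(inherits(genome, "genome_seq"),
            k_min >= 1, k_min <= k_max, k_max <= 26, replicates >= 1)
  if (genome$effective_length <= k_max)
    stop("genome effective length (", genome$effective_length,
         ") must exceed k_max; use a smaller k_max")
  shuffles <- lapply(seq_len(replicates), function(r)
    randomize_genome(genome, seed = derive_seed(seed, r)))
  ks <- k_min:k_max
  per_k <- data.frame(k = ks, ev = NA_real_, gs_g = NA_real_,
                      gs_r = NA_real_, gs_p = NA_real_)
  for (i in seq_along(ks)) {
    tab_g <- count_kmers(genome, ks[i])
    per_k$ev[i] <- expected_value(tab_g)
    per_k$gs_g[i] <- gs_k(tab_g)
    per_k$gs_r[i] <- mean(vapply(shuffles, function(s)
      gs_k(count_kmers(s, ks[i])), 0))
  }
  per_k$gs_p <- per_k$gs_g - per_k$gs_r
  i_opt <- which.max(per_k$gs_p)  # which.max returns the first (smallest k) tie
  structure(
    list(gs = per_k$gs_p[i_opt], k_opt = ks[i_opt], per_k = per_k,
         seed = seed, replicates = replicates, id = genome$id),
    class = "gs_result")
}

#' @export
print.gs_result <- function(x, ...) {
  cat(sprintf("<gs_result> %s: GS = %.6g at k = %d (scan %d..%d)\n",
              x$id, x$gs, x$k_opt, min(x$per_k$k), max(x$per_k$k)))
  invisible(x)
}

# The nonlinear entropy/anti-entropy combination behind Biobit.
# L: log4 genome length; A: anti-entropic component; x = A/L.
bb_combine <- function(L, A, variant = c("plain", "squared")) {
  variant <- match.arg(variant)
  x <- A / L
  core <- switch(variant,
                 plain = x * (1 - 2 * x),
                 squared = x * (1 - 2 * x)^2)
  L * pmax(core, 0)^(1 / 3)
}

#' Biobit (BB) of a genome
#'
#' Measures how a genome's k-mer entropy balances between the minimum
#' \eqn{L(G) = \log_4 G} and the maximum \eqn{2L(G)} attained by a random
#' equifrequent genome of the same length G (the effective, unambiguous
#' length). The empirical entropy \eqn{E_{2L}} is computed at the single
#' word length \eqn{k_{BB} = \mathrm{round}(2L)}, where the entropy of a
#' random genome saturates, and clamped into \eqn{[L, 2L]}. The entropic
#' component is \eqn{E = E_{2L} - L}, the anti-entropic component
#' \eqn{A = 2L - E_{2L}} (so \eqn{E + A = L}), and with \eqn{x = A/L}
#'
#' \deqn{BB = L\,(x(1 - 2x))^{1/3}}
#'
#' for the default `"plain"` variant, or \eqn{L\,(x(1-2x)^2)^{1/3}} for
#' `"squared"`; the inner product is clamped at 0 before the cube root.
#'
#' @param genome A [genome_seq()] object with effective length >= 16.
#' @param variant `"plain"` (default) or `"squared"`.
#' @return An object of class `bb_result`: `bb`, `G`, `L`, `k_bb`,
#'   `E2L` (clamped), `E2L_raw`, `E_comp`, `A_comp`, `variant`.
#' @export
biobit <- function(genome, variant = c("plain", "squared")) {
  stopifnot(inherits(genome, "genome_seq"))
  variant <- match.arg(variant)
  G <- genome$effective_length
  if (G < 16) stop("effective genome length must be at least 16")
  L <- log(G, base = 4)
  k_bb <- as.integer(round(2 * L))
  tab <- count_kmers(genome, k_bb)
  e_raw <- kmer_entropy(tab)
  e2l <- min(max(e_raw, L), 2 * L)
  A <- 2 * L - e2l
  structure(
    list(bb = bb_combine(L, A, variant), G = G, L = L, k_bb = k_bb,
         E2L = e2l, E2L_raw = e_raw, E_comp = e2l - L, A_comp = A,
         variant = variant, id = genome$id),
    class = "bb_result")
}

#' @export
print.bb_result <- function(x, ...) {
  cat(sprintf(
    "<bb_result> %s: BB = %.6g (%s)  L = %.4f, k_bb = %d, E2L = %.4f, A = %.4g\n",
    x$id, x$bb, x$variant, x$L, x$k_bb, x$E2L, x$A_comp))
  invisible(x)
}
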