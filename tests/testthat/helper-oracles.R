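# Independent brute-force oracles the implementation is tested against.

# Dictionary-scan k-mer counter: substring every window, per contig,
# skipping windows with non-ACGT characters.
oracle_count_kmers <- function(contigs, k) {
  counts <- new.env(parent = emptyenv())
  total <- 0
  for (s in toupper(contigs)) {
    n <- nchar(s)
    if (n < k) next
    for (i in 1:(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      counts[[w]] <- (counts[[w]] %||% 0) + 1
      total <- total + 1
    }
  }
  lst <- as.list(counts)
  list(counts = unlist(lst[order(names(lst))]), total = total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Dense GS_k: enumerate all 4^k possible words explicitly.
oracle_gs_k_dense <- function(named_counts, k, total) {
  words <- apply(do.call(expand.grid,
                         rep(list(c("A", "C", "G", "T")), k)),
                 1, paste, collapse = "")
  n <- setNames(rep(0, length(words)), words)
  n[names(named_counts)] <- named_counts
  ev <- total / 4^k
  sum(abs(n - ev)) / total
}

# Literal step-down Holm adjustment.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    adj_sorted[i] <- running
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Star tree with unit branch lengths (Brownian covariance = identity).
star_tree <- function(n) {
  parse_newick(paste0("(", paste0("s", seq_len(n), ":1", collapse = ","), ");"))
}
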