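test_that("expected value is windows over 4^k", {
  g <- genome_seq(random_dna(65))          # 64 dimer windows
  expect_equal(expected_value(count_kmers(g, 2)), 4)
  g2 <- genome_seq(random_dna(17))         # 16 windows
  expect_equal(expected_value(count_kmers(g2, 2)), 1)
  g3 <- genome_seq(random_dna(102))        # 100 trimer windows
  expect_equal(expected_value(count_kmers(g3, 3)), 1.5625)
})

test_that("GS_k matches hand-worked and dense-enumeration values", {
  # homopolymer A x 17: counts {AA:16}, EV = 1 -> (15 + 15)/16
  expect_equal(gs_k(count_kmers(strrep("A", 17), 2)), 1.875)
  # every dimer with count 4: n_i = EV everywhere
  dimers <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T")),
                  1, paste0, collapse = "")
  uniform <- genome_seq(rep(dimers, each = 4))
  expect_equal(gs_k(count_kmers(uniform, 2)), 0)
  # counts {AC:2, GT:2}, EV = 0.25: (2 x 1.75 + 14 x 0.25)/4 = 7/4
  expect_equal(gs_k(count_kmers(genome_seq(c("AC", "AC", "GT", "GT")), 2)),
               1.75)
})

test_that("GS_k equals the dense 4^k oracle and respects its bounds", {
  set.seed(404)
  for (k in 2:6) {
    g <- genome_seq(random_dna(2000, gc = runif(1, 0.2, 0.8)))
    tab <- count_kmers(g, k)
    expect_equal(gs_k(tab),
                 oracle_gs_k_dense(kmer_counts(tab), k, tab$total_windows),
                 tolerance = 1e-12)
    expect_gte(gs_k(tab), 0)
    expect_lte(gs_k(tab), 2 * (1 - 4^-k))
  }
})

test_that("deviations from EV sum to zero over all words (absolute value is essential)", {
  set.seed(505)
  for (k in 1:4) {
    tab <- count_kmers(random_dna(300), k)
    ev <- expected_value(tab)
    signed_sum <- sum(tab$counts - ev) - (4^k - tab$distinct) * ev
    expect_equal(signed_sum, 0, tolerance = 1e-9)
  }
})

test_that("genome randomization is an exact seeded permutation", {
  g <- genome_seq(c(random_dna(200), "ACGTNNGT"))
  r1 <- randomize_genome(g, seed = 3)
  r2 <- randomize_genome(g, seed = 3)
  expect_identical(r1$contigs, r2$contigs)
  expect_false(identical(r1$contigs, randomize_genome(g, seed = 4)$contigs))
  for (i in seq_along(g$contigs)) {
    expect_equal(nchar(r1$contigs[i]), nchar(g$contigs[i]))
    expect_equal(sort(strsplit(r1$contigs[i], "")[[1]]),
                 sort(strsplit(g$contigs[i], "")[[1]]))
  }
  expect_equal(randomize_genome(genome_seq("AAAA"), seed = 1)$contigs[[1]],
               "AAAA")
})

test_that("GS of structureless genomes is near zero and exactly zero for homopolymers", {
  hp <- genomic_signature(genome_seq(strrep("A", 300)), k_min = 2, k_max = 8,
                          seed = 1)
  expect_equal(hp$gs, 0)
  expect_equal(hp$k_opt, 2)  # ties resolve to the smallest k

  for (s in 1:3) {
    g <- generate_iid_genome(1e5, 0.5, seed = 100 + s)
    fit <- genomic_signature(g, k_min = 2, k_max = 10, seed = 200 + s)
    expect_lt(abs(fit$gs), 0.01)
  }
})

test_that("GS is exactly invariant under the A<->T, C<->G relabeling", {
  g <- generate_iid_genome(5000, 0.35, seed = 8)
  g_swap <- genome_seq(chartr("ATCG", "TAGC", g$contigs), id = "swap")
  f1 <- genomic_signature(g, 2, 6, seed = 77)
  f2 <- genomic_signature(g_swap, 2, 6, seed = 77)
  expect_equal(f1$per_k$gs_p, f2$per_k$gs_p, tolerance = 1e-12)
  expect_equal(f1$gs, f2$gs, tolerance = 1e-12)
})

test_that("GS errors when the genome is too short for the scan", {
  expect_error(genomic_signature(genome_seq("ACGTACGT"), k_min = 2, k_max = 16),
               "smaller k_max")
})

test_that("Biobit combination reproduces hand-evaluated cases", {
  combine <- gsbb:::bb_combine
  # G = 65536: L = 8; E2L = 14 -> A = 2, x = 0.25 -> plain 8 x (0.125)^(1/3)
  expect_equal(combine(8, 2, "plain"), 4)
  expect_equal(combine(8, 2, "squared"), 8 * (0.25 * 0.25)^(1 / 3))
  # E2L = 12 -> A = 4, x = 0.5 -> zero factor
  expect_equal(combine(8, 4, "plain"), 0)
  expect_equal(combine(8, 4, "squared"), 0)
  # fully random limit A = 0
  expect_equal(combine(8, 0, "plain"), 0)
  # x(1-2x) clamped at zero below
  expect_equal(combine(8, 8, "plain"), 0)
})

test_that("entropic and anti-entropic components decompose L exactly", {
  set.seed(909)
  genomes <- list(genome_seq(random_dna(5000, 0.5)),
                  genome_seq(random_dna(300, 0.2)),
                  genome_seq(strrep("AC", 200)),
                  genome_seq(strrep("A", 100)))
  for (g in genomes) {
    fit <- biobit(g)
    expect_equal(fit$E_comp + fit$A_comp, fit$L, tolerance = 1e-12)
    expect_gte(fit$A_comp, 0)
    expect_lte(fit$A_comp, fit$L + 1e-12)
    expect_gte(fit$bb, 0)
    expect_lte(fit$bb, fit$L / 2 + 1e-12)  # max of x(1-2x) is 1/8 at x = 1/4
  }
  # degenerate single-word genome: clamping, not an error
  expect_equal(biobit(genome_seq(strrep("A", 100)))$bb, 0)
})

test_that("random genomes are nearly all hapaxes with small Biobit", {
  g <- generate_iid_genome(1e5, 0.5, seed = 606)
  fit <- biobit(g)
  hap <- hapax_stats(count_kmers(g, fit$k_bb))
  expect_gt(hap$hapax_percentage, 99)
  expect_lt(fit$bb, 0.05 * fit$L)
})

test_that("repeat proliferation monotonically lowers hapax percentage and raises Biobit", {
  base <- generate_iid_genome(1e5, 0.5, seed = 42)
  copies <- c(0, 2, 4, 8)
  hap <- bb <- numeric(length(copies))
  for (i in seq_along(copies)) {
    g <- insert_repeats(base, element_length = 500, copies = copies[i],
                        seed = 99)
    fit <- biobit(g)
    bb[i] <- fit$bb
    hap[i] <- hapax_stats(count_kmers(g, fit$k_bb))$hapax_percentage
  }
  expect_true(all(diff(hap) < 0))
  expect_true(all(diff(bb) > 0))
})
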