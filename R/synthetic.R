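#' Generate an i.i.d. random genome at a given GC content
#'
#' Bases are drawn independently with strand-symmetric composition
#' P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2.
#'
#' @param length Genome length in bases (>= 1).
#' @param gc Target GC fraction in (0, 1).
#' @param seed Integer seed.
#' @param id Genome identifier.
#' @return A single-contig [genome_seq()].
#' @export
generate_iid_genome <- function(length, gc = 0.5, seed = NULL, id = "iid") {
  stopifnot(length >= 1, gc > 0, gc < 1)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- with_seed(seed,
                   paste(sample(names(probs), length, replace = TRUE, prob = probs),
                         collapse = ""))
  genome_seq(seq, id = id)
}

#' Overwrite a genome with repeated copies of one random element
#'
#' Draws a single random element from the genome's own base composition and
#' writes it over `copies` non-overlapping positions, emulating the
#' proliferation of insertion-sequence-like mobile elements. Total length
#' is preserved.
#'
#' @param genome A single- or multi-contig [genome_seq()]; copies are placed
#'   in the first contig.
#' @param element_length Element length in bases.
#' @param copies Number of copies (0 returns the genome unchanged).
#' @param seed Integer seed.
#' @return A [genome_seq()] of identical length.
#' @export
insert_repeats <- function(genome, element_length = 500, copies = 2,
                           seed = NULL) {
  stopifnot(inherits(genome, "genome_seq"), element_length >= 1, copies >= 0)
  if (copies == 0) return(genome)
  target <- genome$contigs[1]
  n <- nchar(target)
  n_slots <- n %/% element_length
  if (copies * element_length >= n || copies > n_slots)
    stop("not enough room for ", copies, " copies of ", element_length,
         " bp in a ", n, " bp contig")
  bc <- genome$base_counts[c("A", "C", "G", "T")]
  new <- with_seed(seed, {
    elem <- paste(sample(names(bc), element_length, replace = TRUE,
                         prob = bc / sum(bc)), collapse = "")
    slots <- sort(sample.int(n_slots, copies))
    s <- target
    for (sl in slots) {
      start <- (sl - 1) * element_length + 1
      substr(s, start, start + element_length - 1) <- elem
    }
    s
  })
  contigs <- genome$contigs
  contigs[1] <- new
  genome_seq(contigs, id = genome$id)
}

#' Degrade a genome by AT-biased substitution and block deletion
#'
#' Emulates endosymbiont genome erosion: each G or C flips to A or T
#' (equiprobably) with probability `at_bias`, then a fraction
#' `deletion_fraction` of the positions is removed as contiguous random
#' blocks. The result is never longer and never more GC-rich than the
#' input.
#'
#' @param genome A [genome_seq()] object.
#' @param at_bias Per-base G/C -> A/T substitution probability in \[0, 1\].
#' @param deletion_fraction Fraction of positions removed, in \[0, 1).
#' @param block_length Mean deleted block length in bases.
#' @param seed Integer seed.
#' @return A degraded [genome_seq()].
#' @export
degrade_genome <- function(genome, at_bias = 0, deletion_fraction = 0,
                           block_length = 1000, seed = NULL) {
  stopifnot(inherits(genome, "genome_seq"),
            at_bias >= 0, at_bias <= 1,
            deletion_fraction >= 0, deletion_fraction < 1)
  if (at_bias == 0 && deletion_fraction == 0) return(genome)
  contigs <- with_seed(seed, {
    vapply(genome$contigs, function(s) {
      v <- strsplit(s, "", fixed = TRUE)[[1]]
      if (at_bias > 0) {
        gc_pos <- which(v %in% c("G", "C"))
        flip <- gc_pos[runif(length(gc_pos)) < at_bias]
        if (length(flip))
          v[flip] <- sample(c("A", "T"), length(flip), replace = TRUE)
      }
      if (deletion_fraction > 0) {
        n <- length(v)
        n_del <- floor(deletion_fraction * n)
        keep <- rep(TRUE, n)
        attempts <- 0L
        while (n_del > 0 && attempts < 10000L) {
          attempts <- attempts + 1L
          len <- min(n_del, max(1, ceiling(block_length * runif(1) * 2)))
          start <- sample.int(n - len + 1, 1)
          span <- start:(start + len - 1)
          fresh <- span[keep[span]]
          keep[fresh] <- FALSE
          n_del <- n_del - length(fresh)
        }
        if (n_del > 0) keep[which(keep)[seq_len(n_del)]] <- FALSE
        v <- v[keep]
      }
      paste(v, collapse = "")
    }, "", USE.NAMES = FALSE)
  })
  contigs <- contigs[nzchar(contigs)]
  genome_seq(contigs, id = genome$id)
}

#' Simulate an ultrametric Yule (pure-birth) tree
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Integer seed.
#' @param labels Optional tip labels; defaults to `t1..tn`.
#' @return An ultrametric `phylo` object.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL, labels = NULL) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  tr$tip.label <- labels %||% paste0("t", seq_len(n_tips))
  tr
}

#' Specification of a synthetic endosymbiosis dataset
#'
#' Bundles the generator settings for [make_fixture_dataset()]. Defaults
#' give a desk-scale stand-in for a two-lifestyle genome panel: equal-sized
#' free-living and endosymbiont clades, 100 kb genomes, free-living GC at
#' 0.5, endosymbionts eroded toward GC 0.25 with 30% of the ancestral
#' sequence deleted, and one "transitional" endosymbiont carrying
#' insertion-sequence-like repeats.
#'
#' @param n_free_living,n_endosymbiont Genomes per lifestyle.
#' @param genome_length Ancestral genome length in bases.
#' @param gc_free GC fraction of free-living genomes.
#' @param gc_endo Target GC fraction of endosymbionts (must be < `gc_free`).
#' @param deletion_fraction Fraction of the ancestor deleted per
#'   endosymbiont.
#' @param repeat_copies Baseline repeat copies carried by every genome
#'   (free-living genomes get their own element; endosymbionts inherit and
#'   erode the ancestor's). 0 produces pure i.i.d. genomes.
#' @param transitional_copies Fresh repeat copies added to the first
#'   endosymbiont, emulating a recent insertion-sequence expansion in a
#'   transitional genome (0 disables it).
#' @param repeat_length Repeat element length in bases.
#' @param tree_birth_rate Yule speciation rate for the clade trees.
#' @param seed Root seed; all randomness derives from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_free_living = 10, n_endosymbiont = 10,
                           genome_length = 1e5, gc_free = 0.5,
                           gc_endo = 0.25, deletion_fraction = 0.3,
                           repeat_copies = 8, transitional_copies = 20,
                           repeat_length = 500,
                           tree_birth_rate = 1, seed = 42) {
  stopifnot(n_free_living >= 2, n_endosymbiont >= 2, genome_length >= 1000,
            gc_free > 0, gc_free < 1, gc_endo > 0, gc_endo < gc_free,
            deletion_fraction >= 0, deletion_fraction < 1,
            repeat_copies >= 0, transitional_copies >= 0, repeat_length >= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic endosymbiosis dataset on disk
#'
#' Writes a complete, reproducible stand-in for a two-lifestyle bacterial
#' genome panel: free-living genomes drawn i.i.d. at `gc_free`, each
#' carrying its own baseline complement of repeated elements (real genomes
#' are never structureless), endosymbiont genomes derived from a single
#' shared repeat-bearing ancestor by AT-biased erosion and block deletion
#' (so the habitat signal is clade-structured and inherited repeats decay),
#' one optional transitional endosymbiont enriched in fresh repeats, an
#' ultrametric two-clade tree matching the habitats, GFF stubs whose gene
#' complements shrink with the genomes, and a habitat sample sheet.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `fasta` (named paths), `gff`, `tree_file`,
#'   `sample_sheet`, `tree` (`phylo`), `genomes` (list of [genome_seq()]),
#'   and `habitat` (named character vector).
#' @export
make_fixture_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nf <- spec$n_free_living
  ne <- spec$n_endosymbiont
  ids <- c(paste0("fl_", seq_len(nf)), paste0("en_", seq_len(ne)))
  habitat <- setNames(rep(c("free-living", "endosymbiont"), c(nf, ne)), ids)

  # two-clade ultrametric tree: each habitat is a Yule clade of depth 1,
  # joined by a root edge of length 1
  tr_f <- simulate_tree(nf, spec$tree_birth_rate,
                        seed = derive_seed(spec$seed, 1), labels = ids[1:nf])
  tr_e <- simulate_tree(ne, spec$tree_birth_rate,
                        seed = derive_seed(spec$seed, 2),
                        labels = ids[(nf + 1):(nf + ne)])
  scale_depth <- function(tr) {
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
    tr
  }
  nwk <- paste0("(",
                sub(";$", "", ape::write.tree(scale_depth(tr_f))), ":1,",
                sub(";$", "", ape::write.tree(scale_depth(tr_e))), ":1);")
  tree <- parse_newick(nwk)

  at_bias <- 1 - spec$gc_endo / spec$gc_free
  # per-genome size and erosion jitter so no trait collapses onto two
  # habitat-determined values
  jitter <- with_seed(derive_seed(spec$seed, 5),
                      list(len = round(spec$genome_length *
                                         runif(nf, 0.9, 1.1)),
                           del = pmin(0.95, spec$deletion_fraction *
                                        runif(ne, 0.85, 1.15))))
  ancestor <- generate_iid_genome(spec$genome_length, spec$gc_free,
                                  seed = derive_seed(spec$seed, 3))
  if (spec$repeat_copies > 0)
    ancestor <- insert_repeats(ancestor, spec$repeat_length,
                               spec$repeat_copies,
                               seed = derive_seed(spec$seed, 4))
  genomes <- vector("list", nf + ne)
  names(genomes) <- ids
  for (i in seq_len(nf)) {
    g <- generate_iid_genome(jitter$len[i], spec$gc_free,
                             seed = derive_seed(spec$seed, 10 + i), id = ids[i])
    if (spec$repeat_copies > 0)
      g <- insert_repeats(g, spec$repeat_length, spec$repeat_copies,
                          seed = derive_seed(spec$seed, 50 + i))
    genomes[[i]] <- g
  }
  for (j in seq_len(ne)) {
    id <- ids[nf + j]
    g <- degrade_genome(ancestor, at_bias = at_bias,
                        deletion_fraction = jitter$del[j],
                        seed = derive_seed(spec$seed, 100 + j))
    g$id <- id
    if (j == 1 && spec$transitional_copies > 0)
      g <- insert_repeats(g, spec$repeat_length, spec$transitional_copies,
                          seed = derive_seed(spec$seed, 200))
    genomes[[nf + j]] <- g
  }

  fasta <- setNames(file.path(dir, paste0(ids, ".fasta")), ids)
  gff <- setNames(file.path(dir, paste0(ids, ".gff")), ids)
  for (id in ids) {
    write_fasta(genomes[[id]], fasta[[id]])
    write_gff_stub(genomes[[id]], gff[[id]],
                   seed = derive_seed(spec$seed, 300 + match(id, ids)))
  }
  tree_file <- file.path(dir, "tree.nwk")
  ape::write.tree(tree, tree_file)
  sheet <- file.path(dir, "samples.tsv")
  write.table(data.frame(genome_id = ids, habitat = unname(habitat)),
              sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta, gff = gff, tree_file = tree_file,
                 sample_sheet = sheet, tree = tree, genomes = genomes,
                 habitat = habitat))
}

# GFF3 stub with gene/CDS/rRNA features: roughly one gene per kb with
# variable gene lengths, so eroded (shorter) genomes carry proportionally
# fewer genes; a fraction of genes lack a CDS (pseudogene-like), keeping
# gene and CDS counts correlated but not identical.
write_gff_stub <- function(genome, path, seed = NULL) {
  n <- nchar(genome$contigs[1])
  n_genes <- max(2L, as.integer(n %/% 1000))
  pitch <- n %/% n_genes
  starts <- (seq_len(n_genes) - 1L) * pitch + 1L
  stub <- with_seed(seed, list(
    glen = pmin(pitch - 10L, sample(500:1200, n_genes, replace = TRUE)),
    coding = runif(n_genes) > 0.15,
    n_rrna = sample(1:3, 1)))
  seqid <- names(genome$contigs)[1] %||% genome$id
  if (is.na(seqid) || !nzchar(seqid)) seqid <- genome$id
  rows <- c("##gff-version 3",
            unlist(lapply(seq_len(n_genes), function(i) {
              gid <- sprintf("%s_g%04d", genome$id, i)
              out <- paste(seqid, "synthetic", "gene", starts[i],
                           starts[i] + stub$glen[i] - 1, ".", "+", ".",
                           paste0("ID=", gid), sep = "\t")
              if (stub$coding[i])
                out <- c(out, paste(seqid, "synthetic", "CDS", starts[i],
                                    starts[i] + stub$glen[i] - 1, ".", "+",
                                    "0", paste0("ID=", gid, "_cds;Parent=",
                                                gid), sep = "\t"))
              out
            })),
            vapply(seq_len(stub$n_rrna), function(i)
              paste(seqid, "synthetic", "rRNA",
                    starts[i] + 2, starts[i] + 99, ".", "+", ".",
                    paste0("ID=", genome$id, "_rrna", i), sep = "\t"), ""))
  writeLines(rows, path)
  invisible(path)
}

#' GS profile across a GC-content gradient
#'
#' Generates genomes along a GC gradient and computes their Genomic
#' Signature. Each genome carries the same fixed complement of repeated
#' elements (default 8 copies of a 500 bp element, the insertion-sequence
#' scale used throughout the package), so sequence structure is held
#' constant while base composition is the only variable: GS then measures
#' how visible that structure is against the compositional background,
#' which is what separates a genome from its composition-matched shuffle.
#' With `repeat_copies = 0` the genomes are pure i.i.d. sequences, which
#' are statistically exchangeable with their shuffles, and the profile is
#' flat noise around zero.
#'
#' @param gc_levels GC fractions to scan.
#' @param n_per_level Genomes (seeds) per level.
#' @param genome_length Genome length in bases.
#' @param k_min,k_max GS word-length scan range.
#' @param repeat_copies,repeat_length Structure held constant across levels.
#' @param seed Root seed.
#' @return A data frame with one row per genome: `gc`, `replicate`, `gs`,
#'   `k_opt`.
#' @export
gs_gc_profile <- function(gc_levels = seq(0.1, 0.9, by = 0.1),
                          n_per_level = 5, genome_length = 1e5,
                          k_min = 2, k_max = 12,
                          repeat_copies = 8, repeat_length = 500,
                          seed = NULL) {
  grid <- expand.grid(replicate = seq_len(n_per_level), gc = gc_levels)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    s <- derive_seed(seed, i)
    g <- generate_iid_genome(genome_length, grid$gc[i], seed = s)
    if (repeat_copies > 0)
      g <- insert_repeats(g, repeat_length, repeat_copies,
                          seed = derive_seed(s, 1))
    fit <- genomic_signature(g, k_min = k_min, k_max = k_max,
                             seed = derive_seed(s, 2))
    data.frame(gc = grid$gc[i], replicate = grid$replicate[i],
               gs = fit$gs, k_opt = fit$k_opt)
  })
  do.call(rbind, res)
}
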