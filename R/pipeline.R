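#' Pipeline run configuration
#'
#' @param fasta Named character vector of FASTA paths (names become genome
#'   ids), or a directory containing `.fasta`/`.fa`/`.fna` files.
#' @param gff Optional named vector of GFF3 paths or a directory; matched to
#'   genomes by file stem.
#' @param tree Optional Newick tree path (needed by [run_compare()]).
#' @param sample_sheet Optional TSV with columns `genome_id` and `habitat`.
#' @param out_dir Output directory.
#' @param k_min,k_max GS word-length scan range (2..26).
#' @param bb_variant Biobit combination variant, `"plain"` or `"squared"`.
#' @param hapax_k Word length for hapax statistics; `NULL` uses each
#'   genome's Biobit word length `k_bb`.
#' @param replicates Shuffle replicates averaged into the GS baseline.
#' @param n_sim Brownian simulations for the phylogenetic ANOVA.
#' @param n_perm Tip permutations for Blomberg's K.
#' @param seed Root seed; all per-genome and per-test streams derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(fasta, gff = NULL, tree = NULL, sample_sheet = NULL,
                       out_dir = tempfile("gsbb_run_"), k_min = 2, k_max = 16,
                       bb_variant = "plain", hapax_k = NULL, replicates = 1,
                       n_sim = 1000, n_perm = 1000, seed = 42) {
  expand_dir <- function(paths, exts) {
    if (length(paths) == 1 && dir.exists(paths)) {
      found <- list.files(paths, pattern = paste0("\\.(", exts, ")$"),
                          full.names = TRUE)
      names(found) <- sub("\\.[^.]+$", "", basename(found))
      found
    } else {
      if (is.null(names(paths)))
        names(paths) <- sub("\\.[^.]+$", "", basename(paths))
      paths
    }
  }
  fasta <- expand_dir(fasta, "fasta|fa|fna")
  if (length(fasta) < 1) stop("no FASTA inputs found")
  if (!is.null(gff)) gff <- expand_dir(gff, "gff3?|gff")
  stopifnot(k_min >= 2, k_min <= k_max, k_max <= 26, replicates >= 1)
  bb_variant <- match.arg(bb_variant, c("plain", "squared"))
  structure(list(fasta = fasta, gff = gff, tree = tree,
                 sample_sheet = sample_sheet, out_dir = out_dir,
                 k_min = k_min, k_max = k_max, bb_variant = bb_variant,
                 hapax_k = hapax_k, replicates = replicates,
                 n_sim = n_sim, n_perm = n_perm, seed = seed),
            class = "run_config")
}

trait_columns <- c("gs", "gs_k_opt", "bb", "E2L", "A", "hapax_pct", "n_cds",
                   "n_genes", "n_rrna", "gene_mean_length", "genome_length",
                   "gc_content")

# The nine analysis traits carried into the comparative stage.
analysis_traits <- c("gs", "bb", "hapax_pct", "n_cds", "n_genes", "n_rrna",
                     "gene_mean_length", "genome_length", "gc_content")

#' Compute the per-genome trait table
#'
#' Runs both complexity metrics, the hapax percentage and the six genome
#' parameters for every input genome and writes `traits.tsv` into the
#' output directory. Per-genome failures are logged as warnings and the
#' run continues; a genome without a GFF keeps `NA` in the
#' annotation-derived columns.
#'
#' @param config A [run_config()].
#' @return A data frame (one row per genome; column `genome_id`, the trait
#'   columns, and `habitat` when a sample sheet was given), invisibly also
#'   written to `<out_dir>/traits.tsv`.
#' @export
run_compute <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(config$fasta)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    row <- as.list(setNames(rep(NA_real_, length(trait_columns)),
                            trait_columns))
    ok <- tryCatch({
      g <- read_fasta(config$fasta[[id]], id = id)
      gs_fit <- genomic_signature(g, config$k_min, config$k_max,
                                  seed = derive_seed(config$seed, i),
                                  replicates = config$replicates)
      bb_fit <- biobit(g, variant = config$bb_variant)
      hk <- config$hapax_k %||% bb_fit$k_bb
      hap <- hapax_stats(count_kmers(g, hk))
      ann <- NULL
      if (!is.null(config$gff) && id %in% names(config$gff) &&
          file.exists(config$gff[[id]])) {
        ann <- read_gff(config$gff[[id]])
      } else if (!is.null(config$gff)) {
        warning("no GFF for genome ", id,
                "; annotation-derived parameters set to NA")
      }
      par <- compute_genome_parameters(g, ann)
      row <- list(gs = gs_fit$gs, gs_k_opt = gs_fit$k_opt, bb = bb_fit$bb,
                  E2L = bb_fit$E2L, A = bb_fit$A_comp,
                  hapax_pct = hap$hapax_percentage,
                  n_cds = par$n_cds, n_genes = par$n_genes,
                  n_rrna = par$n_rrna,
                  gene_mean_length = par$gene_mean_length,
                  genome_length = par$genome_length,
                  gc_content = par$gc_content)
      TRUE
    }, error = function(e) {
      warning("genome ", id, " failed: ", conditionMessage(e))
      FALSE
    })
    rows[[i]] <- c(list(genome_id = id), row, list(.ok = ok))
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (!any(df$.ok)) stop("zero readable genomes: all ", nrow(df), " failed")
  df$.ok <- NULL
  if (!is.null(config$sample_sheet)) {
    sheet <- read.delim(config$sample_sheet, stringsAsFactors = FALSE)
    df$habitat <- sheet$habitat[match(df$genome_id, sheet$genome_id)]
  }
  path <- file.path(config$out_dir, "traits.tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Phylogenetically informed comparison report
#'
#' Consumes a trait table and a tree and writes, into the output
#' directory: `correlations.tsv` (all analysis-trait pairs with fitted
#' lambda, GLS correlation, t, raw and Holm-adjusted p, plus the plain
#' Pearson correlation), `anova.tsv` (phylogenetic ANOVA of each trait
#' against habitat), `signal.tsv` (Blomberg's K per trait),
#' `pca_loadings.tsv` / `pca_scores.tsv`, and `run.log` with the seeds and
#' lambda estimates used.
#'
#' @param config A [run_config()] whose `tree` is set.
#' @param traits Trait data frame from [run_compute()]; by default read
#'   from `<out_dir>/traits.tsv`.
#' @param exclude_outliers Character vector of genome ids dropped before
#'   all contrasts (the outlier-removal reanalysis).
#' @return Invisibly, a list with elements `correlations`, `anova`,
#'   `signal`, `pca`, `lambda_matrix`.
#' @export
run_compare <- function(config, traits = NULL, exclude_outliers = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$tree)) stop("run_compare needs a tree in the config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(traits)) {
    path <- file.path(config$out_dir, "traits.tsv")
    if (!file.exists(path)) stop("no trait table: run run_compute() first")
    traits <- read.delim(path, stringsAsFactors = FALSE)
  }
  tree <- if (inherits(config$tree, "phylo")) config$tree
          else read_newick(config$tree)
  if (!is.null(exclude_outliers))
    traits <- traits[!traits$genome_id %in% exclude_outliers, , drop = FALSE]
  traits <- traits[complete.cases(traits[, analysis_traits]), , drop = FALSE]
  X <- as.matrix(traits[, analysis_traits])
  rownames(X) <- traits$genome_id
  missing <- setdiff(rownames(X), tree$tip.label)
  if (length(missing))
    stop("trait table has genomes absent from the tree: ",
         paste(missing, collapse = ", "))
  if (length(setdiff(tree$tip.label, rownames(X))))
    tree <- ape::keep.tip(tree, rownames(X))  # deliberate exclusions
  # drop zero-variance traits up front (constant traits carry no signal)
  variable <- apply(X, 2, function(v) var(v) > 0)
  X <- X[, variable, drop = FALSE]
  log_lines <- c(sprintf("seed: %s", config$seed),
                 sprintf("n genomes: %d", nrow(X)),
                 sprintf("traits: %s", paste(colnames(X), collapse = ", ")))

  pairs <- utils::combn(colnames(X), 2)
  cors <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ct <- phylo_correlation(X[, a], X[, b], tree)
    data.frame(trait_a = a, trait_b = b, r = ct$r, lambda = ct$lambda,
               n = ct$n, t = ct$t, p = ct$p, pearson_r = ct$pearson_r)
  })
  cors <- do.call(rbind, cors)
  cors$p_adj <- holm_bonferroni(cors$p)
  write.table(cors, file.path(config$out_dir, "correlations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  anv <- sig <- NULL
  if ("habitat" %in% names(traits)) {
    habitat <- setNames(traits$habitat, traits$genome_id)[rownames(X)]
    anv <- do.call(rbind, lapply(seq_len(ncol(X)), function(j) {
      a <- phyl_anova(X[, j], habitat, tree, n_sim = config$n_sim,
                      seed = derive_seed(config$seed, 500 + j))
      data.frame(trait = colnames(X)[j], F = a$F, p_sim = a$p_sim,
                 n_sim = a$n_sim)
    }))
    write.table(anv, file.path(config$out_dir, "anova.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sig <- do.call(rbind, lapply(seq_len(ncol(X)), function(j) {
    s <- blomberg_k(X[, j], tree, n_perm = config$n_perm,
                    seed = derive_seed(config$seed, 600 + j))
    data.frame(trait = colnames(X)[j], K = s$K, p = s$p, n_perm = s$n_perm)
  }))
  write.table(sig, file.path(config$out_dir, "signal.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  pca <- NULL
  if (nrow(X) > ncol(X)) {
    pca <- phylo_pca(X, tree)
    write.table(data.frame(trait = rownames(pca$loadings), pca$loadings),
                file.path(config$out_dir, "pca_loadings.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(genome_id = rownames(pca$scores), pca$scores),
                file.path(config$out_dir, "pca_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_lines <- c(log_lines, sprintf("pca lambda: %.6f", pca$lambda))
  } else {
    warning("PCA skipped: needs more genomes than traits")
    log_lines <- c(log_lines, "pca: skipped (too few genomes)")
  }
  log_lines <- c(log_lines,
                 sprintf("pairwise lambda range: %.6f .. %.6f",
                         min(cors$lambda), max(cors$lambda)))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(correlations = cors, anova = anv, signal = sig, pca = pca))
}
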