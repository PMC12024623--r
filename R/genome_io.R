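#' Construct a genome sequence object
#'
#' A `genome_seq` holds the contigs of one genome as upper-case character
#' strings over the DNA alphabet (ambiguity codes such as N are kept but
#' excluded from the effective length). All metrics in the package consume
#' this object.
#'
#' @param contigs Character vector of contig sequences (any case).
#' @param id Genome identifier.
#' @return An object of class `genome_seq` with elements `id`, `contigs`,
#'   `length` (total bases including ambiguity codes) and `effective_length`
#'   (unambiguous A/C/G/T bases only).
#' @export
genome_seq <- function(contigs, id = "genome") {
  if (!is.character(contigs) || length(contigs) == 0 || any(!nzchar(contigs)))
    stop("contigs must be a non-empty character vector of non-empty sequences")
  contigs <- toupper(contigs)
  bc <- .base_counts_cpp(contigs)
  structure(
    list(id = as.character(id),
         contigs = contigs,
         length = sum(nchar(contigs)),
         effective_length = unname(sum(bc[c("A", "C", "G", "T")])),
         base_counts = bc),
    class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %d contig(s), %d bp (%d unambiguous)\n",
              x$id, length(x$contigs), x$length, x$effective_length))
  invisible(x)
}

#' Read a (multi-)FASTA file into a genome sequence
#'
#' All records in the file become contigs of a single genome; lower-case
#' bases are upper-cased on ingest.
#'
#' @param path Path to a FASTA file.
#' @param id Genome identifier; defaults to the file name without extension.
#' @return A [genome_seq()] object.
#' @export
read_fasta <- function(path, id = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e)
                    stop("not a readable FASTA file: ", path, " (", conditionMessage(e), ")"))
  if (length(set) == 0 || sum(Biostrings::width(set)) == 0)
    stop("no sequence records in FASTA file: ", path)
  contigs <- as.character(set)
  names(contigs) <- sub("\\s.*$", "", names(set))
  id <- id %||% sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  genome_seq(contigs, id = id)
}

#' Write a genome sequence to a FASTA file
#'
#' @param genome A [genome_seq()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_seq"))
  set <- Biostrings::DNAStringSet(genome$contigs)
  if (is.null(names(genome$contigs)))
    names(set) <- if (length(set) == 1) genome$id else
      paste0(genome$id, "_contig", seq_along(set))
  else names(set) <- names(genome$contigs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a GFF3 annotation file
#'
#' Parses feature rows into a data frame with 1-based inclusive coordinates
#' and an attribute list column. Comment lines are skipped and everything
#' after a `##FASTA` directive is ignored. Malformed coordinates are
#' reported with their line number.
#'
#' @param path Path to a GFF3 file.
#' @return A data frame of class `annotation_set` with columns `seqid`,
#'   `source`, `type`, `start`, `end`, `score`, `strand`, `phase` and a list
#'   column `attributes` of named character vectors.
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("GFF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  fasta_at <- which(startsWith(lines, "##FASTA"))
  if (length(fasta_at)) lines <- lines[seq_len(fasta_at[1] - 1L)]
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  rows <- which(keep)
  if (!length(rows)) return(empty_annotation_set())
  fields <- strsplit(lines[rows], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8))
    stop("GFF format error at line ", rows[which(nf < 8)[1]],
         ": expected 9 tab-separated columns")
  starts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  bad <- which(!is.finite(starts) | !is.finite(ends) |
                 starts != floor(starts) | ends != floor(ends))
  if (length(bad))
    stop("GFF format error at line ", rows[bad[1]],
         ": non-integer coordinates")
  rev <- which(starts > ends)
  if (length(rev))
    stop("GFF format error at line ", rows[rev[1]],
         ": start > end")
  attrs <- lapply(fields, function(f) {
    if (length(f) < 9L || !nzchar(f[9L]) || f[9L] == ".")
      return(character(0))
    kv <- strsplit(strsplit(f[9L], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    vals <- vapply(kv, function(p) if (length(p) > 1) p[2] else "", "")
    names(vals) <- trimws(vapply(kv, `[[`, "", 1L))
    vals
  })
  out <- data.frame(
    seqid = vapply(fields, `[[`, "", 1L),
    source = vapply(fields, `[[`, "", 2L),
    type = vapply(fields, `[[`, "", 3L),
    start = as.integer(starts),
    end = as.integer(ends),
    score = vapply(fields, `[[`, "", 6L),
    strand = vapply(fields, function(f) if (length(f) >= 7) f[7L] else ".", ""),
    phase = vapply(fields, function(f) if (length(f) >= 8) f[8L] else ".", ""),
    stringsAsFactors = FALSE)
  out$attributes <- attrs
  class(out) <- c("annotation_set", "data.frame")
  out
}

empty_annotation_set <- function() {
  out <- data.frame(seqid = character(0), source = character(0),
                    type = character(0), start = integer(0), end = integer(0),
                    score = character(0), strand = character(0),
                    phase = character(0), stringsAsFactors = FALSE)
  out$attributes <- list()
  class(out) <- c("annotation_set", "data.frame")
  out
}

attr_value <- function(attributes, key) {
  vapply(attributes, function(a) if (key %in% names(a)) a[[key]] else NA_character_,
         NA_character_)
}

#' Six annotation- and sequence-derived genome parameters
#'
#' Computes the number of CDSs (multi-row CDS features sharing an `ID`
#' attribute count once), number of genes, number of rRNAs, mean gene length
#' (end - start + 1 over `gene` features, 0 when there are none), total
#' genome length (all bases, including ambiguity codes) and GC content
#' (G+C over unambiguous bases only). Strand is ignored throughout.
#'
#' @param genome A [genome_seq()] object.
#' @param annotations An `annotation_set` from [read_gff()], or `NULL` for
#'   sequence-only parameters (annotation counts become `NA`).
#' @return A list of class `genome_parameters` with elements `n_cds`,
#'   `n_genes`, `n_rrna`, `gene_mean_length`, `genome_length`, `gc_content`.
#' @export
compute_genome_parameters <- function(genome, annotations = NULL) {
  stopifnot(inherits(genome, "genome_seq"))
  if (genome$effective_length == 0)
    stop("GC content undefined: genome has no unambiguous A/C/G/T bases")
  bc <- genome$base_counts
  gc <- unname((bc[["G"]] + bc[["C"]]) / genome$effective_length)
  if (is.null(annotations)) {
    n_cds <- n_genes <- n_rrna <- NA_integer_
    gml <- NA_real_
  } else {
    stopifnot(inherits(annotations, "annotation_set"))
    gene <- annotations$type == "gene"
    n_genes <- sum(gene)
    n_rrna <- sum(annotations$type == "rRNA")
    cds <- annotations[annotations$type == "CDS", , drop = FALSE]
    if (nrow(cds)) {
      ids <- attr_value(cds$attributes, "ID")
      n_cds <- length(unique(ids[!is.na(ids)])) + sum(is.na(ids))
    } else n_cds <- 0L
    gml <- if (n_genes > 0)
      mean(annotations$end[gene] - annotations$start[gene] + 1) else 0
  }
  structure(
    list(n_cds = n_cds, n_genes = n_genes, n_rrna = n_rrna,
         gene_mean_length = gml, genome_length = genome$length,
         gc_content = gc),
    class = "genome_parameters")
}

#' @export
print.genome_parameters <- function(x, ...) {
  cat("<genome_parameters>\n")
  cat(sprintf("  genes: %s  CDS: %s  rRNA: %s\n", x$n_genes, x$n_cds, x$n_rrna))
  cat(sprintf("  gene mean length: %.1f bp  genome: %d bp  GC: %.4f\n",
              x$gene_mean_length, x$genome_length, x$gc_content))
  invisible(x)
}
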