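# Toy exome construction and indexing.
#
# The toy genome stands in for a reference exome: a handful of chromosomes,
# each a concatenation of intergenic spacers and single-exon genes.  Gene
# models are stored with 1-based inclusive coordinates (the VCF convention);
# `gene_ranges0()` exposes the 0-based half-open view used internally for
# arithmetic.

GENES_PER_CHROM <- 25L

#' Build a toy exome
#'
#' Generates a random reference genome of single-exon protein-coding genes
#' separated by intergenic spacers, for use with the cohort simulator and as
#' the coordinate space of all downstream analyses.  Coding sequences are
#' drawn codon-by-codon from the 61 sense codons so no gene carries an
#' internal stop; strands are assigned at random and minus-strand genes are
#' embedded as the reverse complement of their coding sequence.
#'
#' @param n_genes number of genes (at least 1).
#' @param mean_cds_length mean coding-sequence length in bases; must be at
#'   least 30 and divisible by 3.  Individual gene lengths vary around the
#'   mean (Poisson on the codon count, floored at 10 codons).
#' @param seed integer seed; the genome is a deterministic function of the
#'   arguments.
#' @param spacer_length length of the intergenic spacer separating genes and
#'   padding chromosome ends, so every genic position has defined 5' and 3'
#'   neighbours.
#' @return an object of class `toy_genome`: a list with `genes` (data frame
#'   with columns `gene_id`, `chrom`, `start`, `end`, `strand`, `cds`;
#'   coordinates 1-based inclusive) and `chromosomes` (named character vector
#'   of chromosome sequences).
#' @examples
#' g <- build_toy_exome(n_genes = 5, mean_cds_length = 90, seed = 1)
#' g$genes[, c("gene_id", "chrom", "start", "end", "strand")]
#' @export
build_toy_exome <- function(n_genes, mean_cds_length, seed,
                            spacer_length = 50L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1 ||
      n_genes != round(n_genes)) {
    stop("'n_genes' must be a single integer >= 1")
  }
  if (!is.numeric(mean_cds_length) || length(mean_cds_length) != 1L ||
      mean_cds_length < 30 || mean_cds_length %% 3 != 0) {
    stop("'mean_cds_length' must be >= 30 and divisible by 3")
  }
  if (!is.numeric(spacer_length) || spacer_length < 2) {
    stop("'spacer_length' must be >= 2")
  }
  n_genes <- as.integer(n_genes)
  spacer_length <- as.integer(spacer_length)

  with_seed(seed, {
    n_codons <- pmax(10L, stats::rpois(n_genes, mean_cds_length / 3))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    cds <- vapply(n_codons, function(k) {
      paste(sample(SENSE_CODONS, k, replace = TRUE), collapse = "")
    }, character(1))
    chrom_of <- paste0("chr", (seq_len(n_genes) - 1L) %/% GENES_PER_CHROM + 1L)

    genes <- vector("list", n_genes)
    chroms <- character(0)
    for (ch in unique(chrom_of)) {
      idx <- which(chrom_of == ch)
      pieces <- character(0)
      pos <- 0L
      for (i in idx) {
        spacer <- paste(sample(BASES, spacer_length, replace = TRUE),
                        collapse = "")
        pieces <- c(pieces, spacer)
        pos <- pos + spacer_length
        gseq <- if (strand[i] == "+") cds[i] else revcomp(cds[i])
        start <- pos + 1L
        end <- pos + nchar(gseq)
        genes[[i]] <- data.frame(
          gene_id = sprintf("g%03d", i), chrom = ch,
          start = start, end = end, strand = strand[i], cds = cds[i],
          stringsAsFactors = FALSE)
        pieces <- c(pieces, gseq)
        pos <- end
      }
      tail_spacer <- paste(sample(BASES, spacer_length, replace = TRUE),
                           collapse = "")
      chroms[ch] <- paste(c(pieces, tail_spacer), collapse = "")
    }
    genome <- list(genes = do.call(rbind, genes), chromosomes = chroms,
                   cache = new.env(parent = emptyenv()))
    class(genome) <- "toy_genome"
    genome
  })
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("Toy exome:", nrow(x$genes), "genes on", length(x$chromosomes),
      "chromosome(s);", sum(nchar(x$genes$cds)), "coding bases of",
      sum(nchar(x$chromosomes)), "total\n")
  invisible(x)
}

#' 0-based half-open view of the gene table
#'
#' @param genome a `toy_genome`.
#' @return data frame with `start0` (0-based) and `end0` (exclusive) columns.
#' @export
gene_ranges0 <- function(genome) {
  g <- genome$genes
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start0 = g$start - 1L, end0 = g$end, strand = g$strand,
             stringsAsFactors = FALSE)
}

#' Enumerate every possible single-base substitution of a toy genome
#'
#' The site table is the mutation opportunity space: one row per (position,
#' alternate allele), with the 96-context class of the substitution and, for
#' coding positions, the coding consequence derived from the standard genetic
#' code.  Chromosome-edge positions (no defined flank) are excluded.  The
#' result is cached on the genome object, as it is reused heavily by the
#' simulator and the dN/dS opportunity counter.
#'
#' @param genome a `toy_genome`.
#' @param coding_only if `TRUE`, restrict to positions inside genes.
#' @return data frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `gene_id` (`NA` for intergenic), `class96` (integer 1..96), `cons`
#'   (`"syn"`, `"mis"`, `"non"` or `NA` for intergenic).
#' @export
site_index <- function(genome, coding_only = FALSE) {
  stopifnot(inherits(genome, "toy_genome"))
  key <- if (coding_only) "sites_coding" else "sites_all"
  if (!is.null(genome$cache[[key]])) return(genome$cache[[key]])

  per_chrom <- lapply(names(genome$chromosomes), function(ch) {
    s <- seq_chars(genome$chromosomes[[ch]])
    L <- length(s)
    pos <- 2:(L - 1L)
    ref <- s[pos]
    five <- s[pos - 1L]
    three <- s[pos + 1L]
    alts <- lapply(BASES, function(b) b)
    df <- data.frame(
      chrom = ch,
      pos = rep(pos, times = 3L),
      ref = rep(ref, times = 3L),
      alt = unlist(lapply(ref, function(r) setdiff(BASES, r)), use.names = FALSE),
      five = rep(five, times = 3L),
      three = rep(three, times = 3L),
      stringsAsFactors = FALSE)
    # unlist(lapply(...)) above interleaves by position-major order when the
    # three alts of each position are contiguous; rebuild pos/ref/flanks to
    # match that layout.
    df$pos <- rep(pos, each = 3L)
    df$ref <- rep(ref, each = 3L)
    df$five <- rep(five, each = 3L)
    df$three <- rep(three, each = 3L)
    df
  })
  sites <- do.call(rbind, per_chrom)
  sites$class96 <- unname(context96_index(sites$ref, sites$alt, sites$five,
                                          sites$three))
  sites$five <- NULL
  sites$three <- NULL

  # assign genes and coding consequences
  sites$gene_id <- NA_character_
  sites$cons <- NA_character_
  g <- genome$genes
  for (i in seq_len(nrow(g))) {
    in_gene <- sites$chrom == g$chrom[i] & sites$pos >= g$start[i] &
      sites$pos <= g$end[i]
    if (!any(in_gene)) next
    sites$gene_id[in_gene] <- g$gene_id[i]
    cds <- g$cds[i]
    cpos <- if (g$strand[i] == "+") {
      sites$pos[in_gene] - g$start[i] + 1L
    } else {
      g$end[i] - sites$pos[in_gene] + 1L
    }
    ref_c <- if (g$strand[i] == "+") sites$ref[in_gene] else
      complement_bases(sites$ref[in_gene])
    alt_c <- if (g$strand[i] == "+") sites$alt[in_gene] else
      complement_bases(sites$alt[in_gene])
    sites$cons[in_gene] <- classify_codon_change(cds, cpos, ref_c, alt_c)
  }

  out <- if (coding_only) sites[!is.na(sites$gene_id), , drop = FALSE] else sites
  rownames(out) <- NULL
  genome$cache[[key]] <- out
  out
}

# Classify substitutions at CDS positions `cpos` (1-based, CDS frame) with
# CDS-strand ref/alt bases.  Returns "syn"/"mis"/"non"; stop-loss is binned
# as missense.
classify_codon_change <- function(cds, cpos, ref_c, alt_c) {
  chars <- seq_chars(cds)
  stopifnot(all(chars[cpos] == ref_c))
  codon_i <- (cpos - 1L) %/% 3L
  within <- (cpos - 1L) %% 3L + 1L
  starts <- codon_i * 3L + 1L
  ref_codon <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_c
  ref_aa <- translate_codons(ref_codon)
  alt_aa <- translate_codons(alt_codon)
  ifelse(ref_aa == alt_aa, "syn",
         ifelse(alt_aa == "*" & ref_aa != "*", "non", "mis"))
}

# Start positions and base of homopolymer runs of length >= min_len.
homopolymer_runs <- function(genome, min_len = 4L) {
  out <- lapply(names(genome$chromosomes), function(ch) {
    s <- seq_chars(genome$chromosomes[[ch]])
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$lengths >= min_len & starts > 1L
    data.frame(chrom = ch, pos = starts[keep], base = r$values[keep],
               length = r$lengths[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a toy genome to disk
#'
#' Chromosomes are written as FASTA and the gene table as a BED-like TSV
#' (`gene_id`, `chrom`, `start`, `end`, `strand`, `cds`; 1-based inclusive
#' coordinates).
#'
#' @param genome a `toy_genome`.
#' @param dir output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
write_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "toy_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  tsv <- file.path(dir, "genes.tsv")
  seqinr::write.fasta(as.list(unname(genome$chromosomes)),
                      names = names(genome$chromosomes), file.out = fa,
                      nbchar = 80)
  utils::write.table(genome$genes, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, genes = tsv))
}

#' Read a toy genome written by [write_genome()]
#'
#' @param dir directory containing `genome.fa` and `genes.tsv`.
#' @return a `toy_genome`.
#' @export
read_genome <- function(dir) {
  fa <- seqinr::read.fasta(file.path(dir, "genome.fa"), as.string = TRUE,
                           forceDNAtolower = FALSE)
  chroms <- toupper(vapply(fa, function(x) as.character(x)[1], character(1)))
  names(chroms) <- names(fa)
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  genome <- list(genes = genes, chromosomes = chroms,
                 cache = new.env(parent = emptyenv()))
  class(genome) <- "toy_genome"
  genome
}
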