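# Consequence annotation against the toy gene models.
#
# The toy exome has no introns or UTRs, so the element vocabulary is
# exonic/intergenic and the coding effect of an exonic SNV is synonymous,
# missense or nonsense under the standard genetic code (table 1);
# stop-loss changes are binned as missense.

#' Annotate SNVs with gene element and coding consequence
#'
#' Classifies each SNV as exonic or intergenic and, for exonic variants,
#' derives the codon change strand-aware (minus-strand genes translate the
#' reverse complement) and labels it synonymous, missense or nonsense.
#'
#' @param variants data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (SNVs only).
#' @param genome a `toy_genome`.
#' @return the input with columns `gene_id` (`NA` when intergenic),
#'   `element` (`"exonic"`/`"intergenic"`), `coding_effect`
#'   (`"synonymous"`, `"missense"`, `"nonsense"`, `"not_applicable"`),
#'   `ref_codon`, `alt_codon` (`NA` when intergenic) appended.
#' @examples
#' g <- build_toy_exome(5, 90, seed = 1)
#' v <- site_index(g)[1:3, c("chrom", "pos", "ref", "alt")]
#' annotate_variants(v, g)[, c("pos", "element", "coding_effect")]
#' @export
annotate_variants <- function(variants, genome) {
  stopifnot(inherits(genome, "toy_genome"))
  v <- as.data.frame(variants)
  if (any(nchar(v$ref) != 1L | nchar(v$alt) != 1L)) {
    stop("annotate_variants accepts SNVs only")
  }
  lens <- nchar(genome$chromosomes)[v$chrom]
  if (anyNA(lens) || any(v$pos < 1L | v$pos > lens)) {
    bad <- which(is.na(lens) | v$pos < 1L | v$pos > lens)[1]
    stop(sprintf("variant %s:%s lies outside the genome",
                 v$chrom[bad], v$pos[bad]))
  }
  ref_g <- substr(genome$chromosomes[v$chrom], v$pos, v$pos)
  if (any(ref_g != v$ref)) {
    bad <- which(ref_g != v$ref)[1]
    stop(sprintf("ref allele mismatch at %s:%d (genome has %s, call says %s)",
                 v$chrom[bad], v$pos[bad], ref_g[bad], v$ref[bad]))
  }

  v$gene_id <- NA_character_
  v$element <- "intergenic"
  v$coding_effect <- "not_applicable"
  v$ref_codon <- NA_character_
  v$alt_codon <- NA_character_

  g <- genome$genes
  for (i in seq_len(nrow(g))) {
    hit <- v$chrom == g$chrom[i] & v$pos >= g$start[i] & v$pos <= g$end[i]
    if (!any(hit)) next
    v$gene_id[hit] <- g$gene_id[i]
    v$element[hit] <- "exonic"
    cpos <- if (g$strand[i] == "+") v$pos[hit] - g$start[i] + 1L else
      g$end[i] - v$pos[hit] + 1L
    ref_c <- if (g$strand[i] == "+") v$ref[hit] else
      complement_bases(v$ref[hit])
    alt_c <- if (g$strand[i] == "+") v$alt[hit] else
      complement_bases(v$alt[hit])
    chars <- seq_chars(g$cds[i])
    codon_i <- (cpos - 1L) %/% 3L
    within <- (cpos - 1L) %% 3L + 1L
    starts <- codon_i * 3L + 1L
    ref_codon <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    alt_codon <- ref_codon
    substr(alt_codon, within, within) <- alt_c
    ref_aa <- translate_codons(ref_codon)
    alt_aa <- translate_codons(alt_codon)
    v$ref_codon[hit] <- ref_codon
    v$alt_codon[hit] <- alt_codon
    v$coding_effect[hit] <- ifelse(
      ref_aa == alt_aa, "synonymous",
      ifelse(alt_aa == "*" & ref_aa != "*", "nonsense", "missense"))
  }
  v
}

#' Element / coding-effect proportion table for labelled variant sets
#'
#' Summarises one or more annotated variant collections (e.g. somatic vs. a
#' germline reference) into per-label proportions of gene elements and
#' coding consequences, the standard somatic-vs-reference comparison.
#'
#' @param ... named, annotated variant data frames (output of
#'   [annotate_variants()]), or a single named list of them.
#' @return data frame with one row per (label, category) and columns
#'   `label`, `dimension` (`"element"` or `"coding_effect"`), `category`,
#'   `count`, `proportion`.  Within each (label, dimension) the proportions
#'   sum to 1; `coding_effect` proportions are over exonic variants.
#' @export
consequence_summary <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !is.data.frame(sets[[1]])) {
    sets <- sets[[1]]
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("every variant collection must be named")
  }
  rows <- lapply(names(sets), function(nm) {
    v <- sets[[nm]]
    if (nrow(v) == 0L) stop("collection '", nm, "' is empty")
    if (!"element" %in% names(v)) stop("collection '", nm, "' not annotated")
    el <- table(factor(v$element, levels = c("exonic", "intergenic")))
    ex <- v[v$element == "exonic", , drop = FALSE]
    ce <- table(factor(ex$coding_effect,
                       levels = c("synonymous", "missense", "nonsense")))
    rbind(
      data.frame(label = nm, dimension = "element", category = names(el),
                 count = as.integer(el),
                 proportion = as.integer(el) / sum(el),
                 stringsAsFactors = FALSE),
      if (sum(ce) > 0) {
        data.frame(label = nm, dimension = "coding_effect",
                   category = names(ce), count = as.integer(ce),
                   proportion = as.integer(ce) / sum(ce),
                   stringsAsFactors = FALSE)
      })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
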