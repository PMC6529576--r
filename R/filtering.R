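# Multi-stage somatic refinement.
#
# The funnel, in fixed order: per-sample quality-flag filter -> merge /
# joint-genotype / re-filter -> panel-of-normals germline subtraction ->
# read-support threshold -> SNV restriction.  Each stage's output is a
# subset of its input and the per-stage removal counts are retained so the
# whole funnel can be reported.

call_keys <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

as_call_cohort <- function(calls) {
  samples <- unique(calls[, c("patient", "tissue")])
  rownames(samples) <- NULL
  structure(list(calls = calls, samples = samples), class = "call_cohort")
}

#' Discard quality-flagged calls
#'
#' Removes every call whose caller quality-flag set is non-empty (any of
#' `badReads`, `MQ`, `strandBias`, `SC`, `QD`); input order is preserved and
#' per-flag removal counts are attached.
#'
#' @param cohort a `call_cohort` (or a plain call data frame).
#' @return the filtered object, with attribute `flag_removals` (named counts
#'   of removed calls per flag; a call with several flags counts once per
#'   flag) and `n_removed`.
#' @export
filter_flagged <- function(cohort) {
  calls <- if (inherits(cohort, "call_cohort")) cohort$calls else cohort
  flagged <- calls$flags != ""
  per_flag <- vapply(FLAG_VOCABULARY, function(f) {
    sum(grepl(f, calls$flags, fixed = TRUE))
  }, integer(1))
  out <- calls[!flagged, , drop = FALSE]
  rownames(out) <- NULL
  res <- if (inherits(cohort, "call_cohort")) as_call_cohort(out) else out
  attr(res, "flag_removals") <- per_flag
  attr(res, "n_removed") <- sum(flagged)
  res
}

#' Merge calls across samples, joint-genotype, and re-filter
#'
#' The union of surviving variant keys is genotyped in every sample: a
#' sample without a call at a key is imputed hom-ref with 0 supporting
#' reads.  Variants that re-acquire a quality flag during the joint pass
#' (INFO/JF in the simulator's emission) are discarded from all samples.
#' The result is rectangular: a variant-by-sample genotype matrix is
#' attached.
#'
#' @param cohort a `call_cohort` whose calls already passed
#'   [filter_flagged()].
#' @return a `call_cohort` with carrier calls only in `$calls`, plus
#'   attributes `genotypes` (variant-by-sample character matrix over
#'   `het`/`hom`/`hom_ref`/`missing`) and `n_removed_joint`.
#' @export
merge_genotype_refilter <- function(cohort) {
  stopifnot(inherits(cohort, "call_cohort"))
  calls <- cohort$calls
  key <- call_keys(calls)
  joint_flagged_keys <- unique(key[!is.na(calls$joint_flag)])
  keep <- !key %in% joint_flagged_keys
  n_removed <- length(unique(key[!keep]))
  calls <- calls[keep, , drop = FALSE]
  key <- key[keep]

  sample_id <- paste(cohort$samples$patient, cohort$samples$tissue, sep = "_")
  ukeys <- sort(unique(key))
  gmat <- matrix("hom_ref", nrow = length(ukeys), ncol = length(sample_id),
                 dimnames = list(ukeys, sample_id))
  if (nrow(calls)) {
    sid <- paste(calls$patient, calls$tissue, sep = "_")
    gmat[cbind(match(key, ukeys), match(sid, sample_id))] <- calls$genotype
  }
  rownames(calls) <- NULL
  out <- as_call_cohort(calls)
  out$samples <- cohort$samples
  attr(out, "genotypes") <- gmat
  attr(out, "n_removed_joint") <- n_removed
  out
}

#' Classify somatic variants against the panel of normals
#'
#' A tumor call is somatic iff its (chromosome, position, ref, alt) key is
#' absent from every normal sample of every patient, it is supported by at
#' least `min_reads` reads, and it is an SNV.  Indels surviving the earlier
#' stages are excluded here and reported separately.
#'
#' @param cohort a `call_cohort` (after [merge_genotype_refilter()]).
#' @param min_reads minimum supporting reads (default 3).
#' @return an object of class `somatic_set`: a data frame of somatic SNVs
#'   (`chrom`, `pos`, `ref`, `alt`, `patient`, `read_support`, plus any
#'   carried columns), with attribute `funnel` giving per-stage removal
#'   counts.
#' @export
classify_somatic <- function(cohort, min_reads = 3L) {
  stopifnot(inherits(cohort, "call_cohort"))
  calls <- cohort$calls
  if (!any(cohort$samples$tissue == "normal")) {
    stop("cohort contains no normal samples; the panel of normals is undefined")
  }
  tumor <- calls[calls$tissue == "tumor", , drop = FALSE]
  normal_keys <- unique(call_keys(calls[calls$tissue == "normal", ,
                                        drop = FALSE]))
  n0 <- nrow(tumor)
  in_normal <- call_keys(tumor) %in% normal_keys
  tumor <- tumor[!in_normal, , drop = FALSE]
  low_support <- tumor$read_support < min_reads
  tumor <- tumor[!low_support, , drop = FALSE]
  is_snv <- nchar(tumor$ref) == 1L & nchar(tumor$alt) == 1L &
    tumor$ref %in% BASES & tumor$alt %in% BASES
  out <- tumor[is_snv, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("somatic_set", "data.frame"),
            funnel = c(tumor_calls = n0,
                       removed_in_normal = sum(in_normal),
                       removed_low_support = sum(low_support),
                       removed_indel = sum(!is_snv),
                       somatic_snvs = nrow(out)))
}

#' @export
print.somatic_set <- function(x, ...) {
  f <- attr(x, "funnel")
  cat("Somatic SNV set:", nrow(x), "variants in",
      length(unique(x$patient)), "patient(s)\n")
  if (!is.null(f)) {
    cat("  funnel:", paste(names(f), f, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Exclude recurrent somatic variants
#'
#' Removes somatic variants whose allele key occurs in more than
#' `max_tumors` patients' somatic sets — a guard against germline leakage
#' that would spuriously inflate dN/dS estimates.
#'
#' @param somatic a `somatic_set` (or data frame with a `patient` column).
#' @param max_tumors maximum number of tumors a retained variant may occur
#'   in (default 1).
#' @return the filtered `somatic_set`; attribute `n_recurrent_removed` gives
#'   the number of removed calls.
#' @export
exclude_recurrent <- function(somatic, max_tumors = 1L) {
  if (max_tumors < 1L) stop("'max_tumors' must be >= 1")
  key <- call_keys(somatic)
  n_tumors <- tapply(somatic$patient, key, function(p) length(unique(p)))
  recurrent <- names(n_tumors)[n_tumors > max_tumors]
  keep <- !key %in% recurrent
  out <- somatic[keep, , drop = FALSE]
  rownames(out) <- NULL
  attrs <- attributes(somatic)
  class(out) <- attrs$class
  attr(out, "funnel") <- attrs$funnel
  attr(out, "n_recurrent_removed") <- sum(!keep)
  out
}

#' Run the full refinement funnel
#'
#' Convenience composition of the fixed filter order: per-sample flag
#' filter, merge/joint-genotype/re-filter, panel-of-normals subtraction +
#' read-support threshold + SNV restriction.
#'
#' @param cohort a `call_cohort` of raw parsed calls.
#' @param min_reads minimum supporting reads for a somatic call.
#' @return a `somatic_set` whose `funnel` attribute covers all stages.
#' @export
refine_somatic <- function(cohort, min_reads = 3L) {
  n_raw <- nrow(cohort$calls)
  f1 <- filter_flagged(cohort)
  f2 <- merge_genotype_refilter(f1)
  som <- classify_somatic(f2, min_reads = min_reads)
  funnel <- c(raw_calls = n_raw,
              removed_flagged = attr(f1, "n_removed"),
              removed_joint_flagged = attr(f2, "n_removed_joint"),
              attr(som, "funnel"))
  attr(som, "funnel") <- funnel
  attr(som, "flag_removals") <- attr(f1, "flag_removals")
  som
}

#' Write the filter-funnel report
#'
#' @param somatic a `somatic_set` from [refine_somatic()].
#' @param path JSON output path.
#' @export
write_funnel_report <- function(somatic, path) {
  rep <- list(funnel = as.list(attr(somatic, "funnel")),
              flag_removals = as.list(attr(somatic, "flag_removals")))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a per-patient somatic variant table
#'
#' @param somatic a `somatic_set`.
#' @param path TSV output path.
#' @export
write_somatic_tsv <- function(somatic, path) {
  cols <- intersect(c("patient", "chrom", "pos", "ref", "alt",
                      "read_support"), names(somatic))
  utils::write.table(as.data.frame(somatic)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
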