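# Per-gene somatic mutation burden vs. patient mortality.
#
# Each gene's burden is compared between deceased and alive patients with a
# two-sided Fisher exact test on a 2x2 of variant counts (gene vs. rest of
# exome, by vital status), the genes are ranked by nominal p (deliberately
# with no multiple-testing adjustment), and calibration is assessed by the
# genomic inflation factor and QQ data.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, at
#' fixed margins, of every table whose point probability does not exceed
#' the observed table's (the minimum-likelihood convention of standard
#' statistical software).
#'
#' @param table 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filled by row.
#' @return the two-sided p-value in (0, 1].
#' @examples
#' fisher_two_sided(matrix(c(1, 5, 4, 0), 2, byrow = TRUE)) # 0.0476
#' @export
fisher_two_sided <- function(table) {
  if (is.vector(table) && length(table) == 4L) {
    table <- matrix(table, nrow = 2L, byrow = TRUE)
  }
  if (!all(dim(table) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(table < 0)) stop("cell counts must be non-negative")
  if (any(table != round(table))) stop("cell counts must be integers")
  if (sum(table) == 0) stop("at least one margin must be positive")
  # guard against floating-point overshoot of the summed tail probability
  min(max(stats::fisher.test(table)$p.value, .Machine$double.xmin), 1)
}

#' Per-gene burden contingency tables
#'
#' For each gene with at least one somatic variant cohort-wide, builds the
#' 2x2 of summed variant counts: (in gene, deceased), (in gene, alive),
#' (elsewhere, deceased), (elsewhere, alive).  A presence/absence mode
#' (patients with/without a variant in the gene, by vital status) is
#' available for sensitivity analysis.
#'
#' @param somatic annotated somatic variants (data frame with `patient` and
#'   `gene_id`; intergenic rows are ignored).
#' @param labels data frame with columns `patient`, `vital_status`
#'   (`"deceased"`/`"alive"`).
#' @param mode `"count"` (default; the operational definition of burden:
#'   total somatic mutations per gene per patient) or `"presence"`.
#' @return named list of 2x2 matrices, one per gene.
#' @export
gene_burden_tables <- function(somatic, labels, mode = c("count", "presence")) {
  mode <- match.arg(mode)
  v <- as.data.frame(somatic)
  v <- v[!is.na(v$gene_id), , drop = FALSE]
  status <- stats::setNames(labels$vital_status, labels$patient)
  if (!all(v$patient %in% names(status))) {
    stop("unlabelled patient(s): ",
         paste(setdiff(unique(v$patient), names(status)), collapse = ", "))
  }
  if (!all(status %in% c("deceased", "alive"))) {
    stop("vital_status must be 'deceased' or 'alive'")
  }
  v$dead <- status[v$patient] == "deceased"
  genes <- sort(unique(v$gene_id))
  if (mode == "count") {
    in_dead <- tapply(v$dead, v$gene_id, sum)[genes]
    in_alive <- (tapply(rep(1L, nrow(v)), v$gene_id, sum)[genes]) - in_dead
    tot_dead <- sum(v$dead)
    tot_alive <- nrow(v) - tot_dead
    lapply(stats::setNames(genes, genes), function(g) {
      a <- in_dead[[g]]; b <- in_alive[[g]]
      matrix(c(a, b, tot_dead - a, tot_alive - b), nrow = 2L, byrow = TRUE,
             dimnames = list(c("in_gene", "elsewhere"),
                             c("deceased", "alive")))
    })
  } else {
    n_dead <- sum(status == "deceased")
    n_alive <- sum(status == "alive")
    lapply(stats::setNames(genes, genes), function(g) {
      carriers <- unique(v$patient[v$gene_id == g])
      a <- sum(status[carriers] == "deceased")
      b <- length(carriers) - a
      matrix(c(a, b, n_dead - a, n_alive - b), nrow = 2L, byrow = TRUE,
             dimnames = list(c("with_variant", "without"),
                             c("deceased", "alive")))
    })
  }
}

#' Genomic inflation factor and QQ data
#'
#' Transforms p-values to upper-tail 1-df chi-square quantiles and reports
#' the median-based inflation factor: lambda = median(q) / 0.4549364 (the
#' 1-df chi-square median).  QQ pairs are (-log10 expected uniform order
#' statistic i/(n+1), -log10 observed sorted p).
#'
#' @param p_values numeric vector with all values in (0, 1].
#' @return an `inflation_report`: list with `lambda`, `observed`, `expected`
#'   (both on the -log10 scale, sorted ascending in p).
#' @export
inflation_lambda <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p) | p <= 0 | p > 1)) {
    stop("all p-values must lie in (0, 1]")
  }
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chi) / stats::qchisq(0.5, df = 1)
  n <- length(p)
  ord <- order(p)
  structure(list(lambda = lambda,
                 observed = -log10(p[ord]),
                 expected = -log10(seq_len(n) / (n + 1)),
                 n = n),
            class = "inflation_report")
}

#' @export
print.inflation_report <- function(x, digits = 3, ...) {
  cat("Genomic inflation: lambda =", round(x$lambda, digits), "over", x$n,
      "tests\n")
  invisible(x)
}

#' Rank genes by burden-test p-value
#'
#' Genes are sorted ascending by p, ties broken by descending in-gene
#' variant total, then lexicographic gene id.  The prioritized list is the
#' genes with p < `alpha`; no multiple-testing adjustment is applied (the
#' ranking is intentionally nominal).
#'
#' @param results data frame with columns `gene_id`, `p_value` and the
#'   in-gene counts `n_deceased`, `n_alive` (as produced by
#'   [burden_test()]).
#' @param alpha nominal significance level (default 0.05).
#' @return the results re-ordered, with `rank` and logical `prioritized`
#'   columns.
#' @export
rank_genes <- function(results, alpha = 0.05) {
  if (nrow(results) == 0L) stop("no burden results to rank")
  in_gene <- results$n_deceased + results$n_alive
  ord <- order(results$p_value, -in_gene, results$gene_id)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$prioritized <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Gene-level mutation burden association test
#'
#' Runs the per-gene two-sided Fisher exact burden test between deceased
#' and alive patients, ranks the genes, and computes the genomic inflation
#' diagnostics.
#'
#' @inheritParams gene_burden_tables
#' @param alpha nominal prioritization threshold.
#' @return an object of class `burden_fit`: list with `results` (ranked
#'   per-gene data frame: `gene_id`, `n_deceased`, `n_alive`,
#'   `elsewhere_deceased`, `elsewhere_alive`, `p_value`, `rank`,
#'   `prioritized`), `inflation` (an `inflation_report`), `alpha`, `mode`,
#'   `n_patients`.
#' @examples
#' \dontrun{
#' fit <- burden_test(annotated_somatic, labels)
#' summary(fit)
#' plot(fit)  # QQ plot
#' }
#' @export
burden_test <- function(somatic, labels, mode = c("count", "presence"),
                        alpha = 0.05) {
  mode <- match.arg(mode)
  tables <- gene_burden_tables(somatic, labels, mode = mode)
  if (length(tables) == 0L) stop("no genes with somatic variants")
  res <- data.frame(
    gene_id = names(tables),
    n_deceased = vapply(tables, function(t) t[1, 1], numeric(1)),
    n_alive = vapply(tables, function(t) t[1, 2], numeric(1)),
    elsewhere_deceased = vapply(tables, function(t) t[2, 1], numeric(1)),
    elsewhere_alive = vapply(tables, function(t) t[2, 2], numeric(1)),
    p_value = vapply(tables, fisher_two_sided, numeric(1)),
    stringsAsFactors = FALSE)
  res <- rank_genes(res, alpha = alpha)
  structure(list(results = res,
                 inflation = inflation_lambda(res$p_value),
                 alpha = alpha, mode = mode,
                 n_patients = nrow(labels)),
            class = "burden_fit")
}

#' @export
print.burden_fit <- function(x, n = 5, ...) {
  cat("Gene burden test (", x$mode, " mode): ", nrow(x$results),
      " genes, ", sum(x$results$prioritized), " prioritized at p < ",
      x$alpha, "\n", sep = "")
  cat("lambda =", round(x$inflation$lambda, 3), "\n")
  print(utils::head(x$results[, c("gene_id", "n_deceased", "n_alive",
                                  "p_value", "rank")], n))
  invisible(x)
}

#' @export
summary.burden_fit <- function(object, ...) {
  res <- object$results
  out <- list(n_genes = nrow(res), n_prioritized = sum(res$prioritized),
              lambda = object$inflation$lambda,
              min_p = min(res$p_value), top = utils::head(res, 10))
  class(out) <- "summary.burden_fit"
  out
}

#' @export
print.summary.burden_fit <- function(x, ...) {
  cat("Genes tested:      ", x$n_genes, "\n")
  cat("Prioritized genes: ", x$n_prioritized, "\n")
  cat("Lowest nominal p:  ", format(x$min_p, digits = 3), "\n")
  cat("Inflation lambda:  ", round(x$lambda, 3), "\n\nTop genes:\n")
  print(x$top[, c("gene_id", "n_deceased", "n_alive", "p_value", "rank")])
  invisible(x)
}

#' QQ plot of burden-test p-values
#'
#' @param x a `burden_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.burden_fit <- function(x, ...) {
  inf <- x$inflation
  graphics::plot(inf$expected, inf$observed,
                 xlab = expression(-log[10] ~ "expected p"),
                 ylab = expression(-log[10] ~ "observed p"),
                 main = sprintf("Burden test QQ (lambda = %.3f)",
                                inf$lambda), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Burden test on an external per-gene count table
#'
#' Validation mode: applies the same 2x2 construction and two-sided exact
#' test to externally supplied per-gene somatic variant counts stratified by
#' vital status (e.g. counts extracted from a public cohort).
#'
#' @param counts data frame with columns `gene_id`, `deceased_count`,
#'   `alive_count`.
#' @param totals named vector or list with `deceased` and `alive`: the
#'   cohort-wide variant totals per group; must be at least the column sums.
#' @param alpha nominal significance level.
#' @return a `burden_fit` (external mode) whose results flag nominally
#'   significant genes.
#' @export
external_burden_test <- function(counts, totals, alpha = 0.05) {
  need <- c("gene_id", "deceased_count", "alive_count")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns: ", paste(need, collapse = ", "))
  }
  tot_d <- as.numeric(totals[["deceased"]])
  tot_a <- as.numeric(totals[["alive"]])
  if (sum(counts$deceased_count) > tot_d || sum(counts$alive_count) > tot_a) {
    stop("per-gene counts exceed the supplied group totals")
  }
  res <- data.frame(
    gene_id = counts$gene_id,
    n_deceased = counts$deceased_count,
    n_alive = counts$alive_count,
    elsewhere_deceased = tot_d - counts$deceased_count,
    elsewhere_alive = tot_a - counts$alive_count,
    stringsAsFactors = FALSE)
  res$p_value <- apply(res[, 2:5], 1L, function(r) {
    fisher_two_sided(matrix(c(r[1], r[2], r[3], r[4]), 2L, byrow = TRUE))
  })
  res <- rank_genes(res, alpha = alpha)
  structure(list(results = res, inflation = inflation_lambda(res$p_value),
                 alpha = alpha, mode = "external",
                 n_patients = NA_integer_),
            class = "burden_fit")
}

#' Read the external validation inputs
#'
#' Expects a TSV with columns `gene_id`, `deceased_count`, `alive_count`
#' and a YAML sidecar (same path with extension `.yaml`, or given
#' explicitly) holding `totals: {deceased: ..., alive: ...}`.
#'
#' @param path TSV path.
#' @param yaml_path optional sidecar path.
#' @return list with `counts` and `totals` ready for
#'   [external_burden_test()].
#' @export
read_external_counts <- function(path, yaml_path = NULL) {
  counts <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  if (is.null(yaml_path)) {
    yaml_path <- paste0(tools::file_path_sans_ext(path), ".yaml")
  }
  if (!file.exists(yaml_path)) {
    stop("totals sidecar not found: ", yaml_path)
  }
  side <- yaml::read_yaml(yaml_path)
  if (is.null(side$totals$deceased) || is.null(side$totals$alive)) {
    stop("sidecar must define totals: {deceased, alive}")
  }
  list(counts = counts, totals = side$totals)
}
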