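# Mutational spectra and signature fitting.
#
# A tumor's somatic SNVs are classified into the 96 pyrimidine-normalised
# trinucleotide classes; a fixed catalog of signature profiles is then fit
# by constrained maximum likelihood (EM for a multinomial mixture with fixed
# components), with bootstrap uncertainty and a two-stage select-and-refit
# procedure that mirrors common practice: fit the full catalog, keep the
# signatures with credible activity, refit the reduced catalog.

#' Generate a synthetic signature catalog
#'
#' Produces a catalog of Dirichlet-random 96-context probability profiles in
#' the COSMIC v2 layout (rows = contexts, columns = signatures).  The values
#' are synthetic — this is a stand-in for tests and simulations, not a copy
#' of any published catalog.
#'
#' @param n_signatures number of columns (default 30, the size of the
#'   catalog generation the two-stage fit was designed around).
#' @param seed integer seed.
#' @param concentration Dirichlet concentration per context; smaller values
#'   give spikier, more mutually distinguishable profiles.
#' @return a `signature_catalog`: numeric 96 x S matrix, rows named by
#'   context label, columns `S1..Sn`, each column summing to 1.
#' @export
synthetic_signature_catalog <- function(n_signatures = 30L, seed = 42L,
                                        concentration = 0.5) {
  with_seed(seed, {
    m <- matrix(stats::rgamma(96L * n_signatures, shape = concentration),
                nrow = 96L)
    m <- sweep(m, 2L, colSums(m), "/")
    dimnames(m) <- list(CONTEXT96_LABELS, paste0("S", seq_len(n_signatures)))
    structure(m, class = c("signature_catalog", "matrix", "array"))
  })
}

#' Read / write a signature catalog TSV
#'
#' The file layout is the COSMIC v2 one: a `context` column of labels like
#' `A[C>A]A` followed by one numeric column per signature; 96 rows.  Rows may
#' appear in any order in the file and are re-ordered to the package's fixed
#' lexicographic (substitution, 5' base, 3' base) ordering.
#'
#' @param path file path.
#' @return a `signature_catalog` matrix.
#' @export
read_signature_catalog <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"context" %in% names(df)) stop("catalog file lacks a 'context' column")
  idx <- match(CONTEXT96_LABELS, df$context)
  if (anyNA(idx)) stop("catalog file does not contain all 96 context rows")
  m <- as.matrix(df[idx, setdiff(names(df), "context"), drop = FALSE])
  rownames(m) <- CONTEXT96_LABELS
  validate_catalog(m)
  structure(m, class = c("signature_catalog", "matrix", "array"))
}

#' @rdname read_signature_catalog
#' @param catalog a `signature_catalog`.
#' @export
write_signature_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  df <- data.frame(context = rownames(catalog), catalog, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_catalog <- function(catalog) {
  if (nrow(catalog) != 96L) stop("signature catalog must have 96 rows")
  if (any(catalog < 0)) stop("signature catalog entries must be >= 0")
  if (any(abs(colSums(catalog) - 1) > 1e-6)) {
    stop("every catalog column must sum to 1 (tolerance 1e-6)")
  }
  invisible(catalog)
}

#' 96-context mutation spectrum of a somatic SNV set
#'
#' Classifies each SNV by substitution type and flanking reference bases,
#' interpreting the pyrimidine of the Watson-Crick pair as the reference base
#' (purine-reference SNVs are reverse-complemented together with their
#' flanks).
#'
#' @param variants data frame of SNVs with columns `chrom`, `pos`, `ref`,
#'   `alt` (and optionally `patient`).
#' @param genome the `toy_genome` supplying flanking bases.
#' @param by_patient if `TRUE` and a `patient` column is present, return a
#'   96 x n_patients count matrix; otherwise a single spectrum.
#' @return a `mutation_spectrum`: named integer vector of length 96 (or a
#'   matrix with 96 rows).
#' @export
spectrum_96 <- function(variants, genome, by_patient = FALSE) {
  stopifnot(inherits(genome, "toy_genome"))
  v <- as.data.frame(variants)
  if (nrow(v) == 0L) stop("no variants supplied")
  if (any(nchar(v$ref) != 1L | nchar(v$alt) != 1L)) {
    stop("spectrum_96 accepts SNVs only")
  }
  lens <- nchar(genome$chromosomes)[v$chrom]
  if (anyNA(lens)) stop("variant chromosome not found in genome")
  at_edge <- v$pos <= 1L | v$pos >= lens
  if (any(at_edge)) {
    i <- which(at_edge)[1]
    stop(sprintf("variant %s:%d has no defined flanking base", v$chrom[i],
                 v$pos[i]))
  }
  five <- substr(genome$chromosomes[v$chrom], v$pos - 1L, v$pos - 1L)
  ref_g <- substr(genome$chromosomes[v$chrom], v$pos, v$pos)
  three <- substr(genome$chromosomes[v$chrom], v$pos + 1L, v$pos + 1L)
  if (any(ref_g != v$ref)) {
    stop("ref allele disagrees with the genome sequence at some positions")
  }
  cls <- context96_index(v$ref, v$alt, five, three)
  if (by_patient && "patient" %in% names(v)) {
    tab <- table(factor(CONTEXT96_LABELS[cls], levels = CONTEXT96_LABELS),
                 v$patient)
    m <- matrix(as.integer(tab), nrow = 96L,
                dimnames = list(CONTEXT96_LABELS, colnames(tab)))
    structure(m, class = c("mutation_spectrum", "matrix", "array"))
  } else {
    counts <- tabulate(cls, nbins = 96L)
    names(counts) <- CONTEXT96_LABELS
    structure(counts, class = "mutation_spectrum")
  }
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  tot <- if (is.matrix(x)) colSums(x) else sum(x)
  cat("96-context mutation spectrum;", if (is.matrix(x)) ncol(x) else 1,
      "tumor(s), SNV totals:", paste(tot, collapse = ", "), "\n")
  invisible(x)
}

# EM for a multinomial mixture with fixed component profiles.  Returns the
# weight vector, per-iteration log-likelihoods and iteration count.
em_exposures <- function(counts, P, tol = 1e-8, max_iter = 1e4L,
                         w0 = NULL) {
  S <- ncol(P)
  w <- if (is.null(w0)) rep(1 / S, S) else w0
  n <- sum(counts)
  ll <- numeric(0)
  for (it in seq_len(max_iter)) {
    mix <- as.vector(P %*% w)
    mix[mix == 0] <- .Machine$double.xmin
    ll <- c(ll, sum(counts * log(mix)))
    # E-step responsibilities folded into the weight update
    w_new <- w * as.vector(crossprod(P, counts / mix)) / n
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < tol) {
      w <- w_new
      break
    }
    w <- w_new
  }
  mix <- as.vector(P %*% w)
  mix[mix == 0] <- .Machine$double.xmin
  ll <- c(ll, sum(counts * log(mix)))
  list(weights = stats::setNames(w, colnames(P)), loglik = ll, iterations = it)
}

#' Fit signature exposures by constrained maximum likelihood
#'
#' Maximises the multinomial likelihood of a 96-context spectrum under a
#' convex mixture of fixed catalog signatures, by EM (monotone likelihood
#' ascent, converged when the largest weight update falls below `tol`).
#' Uncertainty comes from a nonparametric bootstrap of the SNV set: the
#' spectrum is resampled as a multinomial of its own size and refit.
#'
#' @param spectrum a length-96 count vector (class `mutation_spectrum` or
#'   plain numeric) with total >= 1.
#' @param catalog a `signature_catalog`.
#' @param n_boot bootstrap resamples for the percentile intervals
#'   (default 1000).
#' @param seed seed for the bootstrap.
#' @param tol convergence tolerance on the weight update.
#' @param max_iter iteration cap.
#' @param conf confidence level of the percentile interval.
#' @return an `exposure_fit`: list with `weights` (non-negative, sum 1),
#'   `lower`/`upper` percentile bounds, `loglik` trace, `iterations`,
#'   `n_snv`.
#' @export
fit_exposures <- function(spectrum, catalog, n_boot = 1000L, seed = 1L,
                          tol = 1e-8, max_iter = 1e4L, conf = 0.95) {
  counts <- as.numeric(spectrum)
  if (length(counts) != nrow(catalog)) {
    stop("spectrum length does not match catalog rows")
  }
  if (any(counts < 0) || sum(counts) < 1) {
    stop("spectrum must be non-negative with total >= 1")
  }
  validate_catalog(catalog)
  P <- unclass(catalog)
  fit <- em_exposures(counts, P, tol = tol, max_iter = max_iter)
  n <- sum(counts)
  boot <- with_seed(seed, {
    matrix(vapply(seq_len(n_boot), function(b) {
      x <- as.vector(stats::rmultinom(1L, size = n, prob = counts / n))
      em_exposures(x, P, tol = tol, max_iter = max_iter)$weights
    }, numeric(ncol(P))), nrow = ncol(P))
  })
  alpha <- (1 - conf) / 2
  lower <- apply(boot, 1L, stats::quantile, probs = alpha, names = FALSE)
  upper <- apply(boot, 1L, stats::quantile, probs = 1 - alpha, names = FALSE)
  structure(list(weights = fit$weights,
                 lower = stats::setNames(lower, colnames(P)),
                 upper = stats::setNames(upper, colnames(P)),
                 loglik = fit$loglik, iterations = fit$iterations,
                 n_snv = n, n_boot = n_boot, conf = conf),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, digits = 3, ...) {
  cat("Signature exposure fit:", x$n_snv, "SNVs,", length(x$weights),
      "signatures,", x$iterations, "EM iterations\n")
  w <- sort(x$weights, decreasing = TRUE)
  show <- w[w >= 0.01]
  if (length(show) == 0) show <- w[1]
  print(round(show, digits))
  invisible(x)
}

#' @export
coef.exposure_fit <- function(object, ...) object$weights

#' @export
plot.exposure_fit <- function(x, ...) {
  graphics::barplot(x$weights, las = 2, ylab = "exposure",
                    main = "Fitted signature exposures", ...)
  invisible(x)
}

#' Two-stage signature fitting: select, then refit
#'
#' Stage 1 fits the full catalog.  Signatures are selected when their
#' bootstrap lower bound is strictly positive and their point exposure is at
#' least `threshold`; stage 2 refits the selected subset only, so the final
#' exposures are renormalised over the active signatures.  If nothing is
#' selected the single best-weight signature is kept, with a warning.
#'
#' @inheritParams fit_exposures
#' @param threshold minimum stage-1 point exposure for selection
#'   (default 0.05).
#' @return an `exposure_fit` for the selected subset, with extra fields
#'   `selected` (logical over the full catalog) and `stage1` (the full-catalog
#'   fit).
#' @export
select_and_refit <- function(spectrum, catalog, threshold = 0.05,
                             n_boot = 1000L, seed = 1L, ...) {
  stage1 <- fit_exposures(spectrum, catalog, n_boot = n_boot, seed = seed, ...)
  selected <- stage1$lower > 0 & stage1$weights >= threshold
  if (!any(selected)) {
    warning("no signature passed selection; keeping the best-weight signature")
    selected[which.max(stage1$weights)] <- TRUE
  }
  sub <- catalog[, selected, drop = FALSE]
  class(sub) <- class(catalog)
  stage2 <- fit_exposures(spectrum, sub, n_boot = n_boot,
                          seed = child_seed(seed, 1L), ...)
  stage2$selected <- stats::setNames(selected, colnames(catalog))
  stage2$stage1 <- stage1
  stage2
}

#' Spearman correlation between a signature exposure and a covariate
#'
#' Computes the Spearman rank correlation between per-tumor exposures and a
#' per-tumor covariate (e.g. age at diagnosis).  For n <= 10 untied samples
#' the p-value is the exact permutation-null tail; otherwise the large-sample
#' approximation is used.
#'
#' @param exposure numeric vector of per-tumor exposures.
#' @param covariate numeric vector of the same length.
#' @return list with `rho`, `p_value`, `n`, `exact` (whether the exact null
#'   was used).
#' @export
exposure_covariate_correlation <- function(exposure, covariate) {
  if (length(exposure) != length(covariate)) stop("length mismatch")
  ok <- stats::complete.cases(exposure, covariate)
  x <- exposure[ok]; y <- covariate[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (length(unique(y)) == 1L || length(unique(x)) == 1L) {
    stop("Spearman correlation undefined for a constant vector")
  }
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  exact <- n <= 10L && !ties
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = exact))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n, exact = exact)
}
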