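# Trinucleotide-context-corrected dN/dS estimation.
#
# Context-specific mutation rates are estimated from synonymous counts
# divided by synonymous opportunities; the expected nonsynonymous count is
# the rate-weighted sum of nonsynonymous opportunities, and dN/dS is the
# ratio of observed to expected.  Departures from neutrality (ratio = 1)
# are tested with a Poisson likelihood-ratio test and profile-likelihood
# confidence intervals.  This is deliberately a simplified estimator: no
# negative-binomial gene-level dispersion and no covariates — it supports
# exactly the exome-wide-neutrality and per-gene-selection questions.

#' Count mutational opportunities of a toy exome
#'
#' Enumerates, for every coding position and each of its three possible
#' substitutions, the coding consequence (standard genetic code) and the
#' pyrimidine-normalised 96-context class of the change, then tallies
#' synonymous, missense and nonsense opportunities per gene and context
#' class.
#'
#' @param genome a `toy_genome`.
#' @return an `opportunity_table`: list with `by_gene` (data frame
#'   `gene_id`, `class96`, `n_syn`, `n_mis`, `n_non`) and `exome` (96 x 3
#'   matrix of class-level totals).  Opportunities sum to 3 per coding base.
#' @export
count_opportunities <- function(genome) {
  stopifnot(inherits(genome, "toy_genome"))
  if (any(nchar(genome$genes$cds) %% 3 != 0)) {
    stop("coding sequence length not divisible by 3")
  }
  sites <- site_index(genome, coding_only = TRUE)
  f_gene <- factor(sites$gene_id)
  f_class <- factor(sites$class96, levels = 1:96)
  counts <- lapply(c(syn = "syn", mis = "mis", non = "non"), function(cc) {
    table(f_gene[sites$cons == cc], f_class[sites$cons == cc])
  })
  genes <- levels(f_gene)
  by_gene <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g, class96 = 1:96,
               n_syn = as.integer(counts$syn[g, ]),
               n_mis = as.integer(counts$mis[g, ]),
               n_non = as.integer(counts$non[g, ]),
               stringsAsFactors = FALSE)
  }))
  exome <- cbind(
    syn = as.integer(colSums(counts$syn)),
    mis = as.integer(colSums(counts$mis)),
    non = as.integer(colSums(counts$non)))
  rownames(exome) <- CONTEXT96_LABELS
  structure(list(by_gene = by_gene, exome = exome,
                 coding_bases = sum(nchar(genome$genes$cds))),
            class = "opportunity_table")
}

#' @export
print.opportunity_table <- function(x, ...) {
  cat("Mutational opportunities:", x$coding_bases, "coding bases,",
      sum(x$exome), "possible substitutions (",
      paste(colnames(x$exome), colSums(x$exome), sep = "=", collapse = ", "),
      ")\n")
  invisible(x)
}

# Profile-likelihood inference for an exome-wide dN/dS ratio.  Synonymous
# and nonsynonymous counts are modelled jointly as Poisson per rate class
# (S_c ~ Pois(r_c Ls_c), N_c ~ Pois(w r_c Ln_c)) and the class rates r_c
# are profiled out, so the sampling noise of the estimated rates propagates
# into the neutrality test and the interval; a test that treats E[N] as
# known would be badly anticonservative.
profile_ratio_inference <- function(S, Ls, N, Ln, ratio, conf = 0.95) {
  keep <- (Ls + Ln) > 0 & (S + N) > 0
  S <- S[keep]; Ls <- Ls[keep]; N <- N[keep]; Ln <- Ln[keep]
  if (length(S) == 0L || is.na(ratio)) {
    return(list(ratio = ratio, lo = NA_real_, hi = NA_real_, p = NA_real_))
  }
  ll <- function(w) {
    r <- (S + N) / (Ls + w * Ln)
    mu_s <- r * Ls
    mu_n <- w * r * Ln
    sum(S[S > 0] * log(mu_s[S > 0])) + sum(N[N > 0] * log(mu_n[N > 0])) -
      sum(mu_s) - sum(mu_n)
  }
  upper <- max(ratio * 10 + 10, 10)
  if (sum(N) == 0) {
    w_hat <- 0
    ll_hat <- ll(0)
  } else {
    opt <- stats::optimize(function(w) -ll(w), c(1e-9, upper))
    w_hat <- opt$minimum
    ll_hat <- -opt$objective
  }
  p <- stats::pchisq(2 * (ll_hat - ll(1)), df = 1, lower.tail = FALSE)
  crit <- stats::qchisq(conf, df = 1) / 2
  g <- function(w) ll(w) - (ll_hat - crit)
  lo <- if (sum(N) == 0 || g(w_hat * 1e-6) > 0) 0 else
    stats::uniroot(g, c(w_hat * 1e-6, w_hat))$root
  hi_up <- upper
  while (g(hi_up) > 0) hi_up <- hi_up * 10
  hi <- stats::uniroot(g, c(max(w_hat, 1e-12), hi_up))$root
  list(ratio = ratio, lo = lo, hi = hi, p = p)
}

# Poisson LRT of obs vs. expected (expected treated as fixed): used per
# gene, where the exome-wide rates are estimated from vastly more data
# than any single gene contributes.
poisson_ratio_inference <- function(obs, expected, conf = 0.95) {
  if (expected <= 0) {
    return(list(ratio = NA_real_, lo = NA_real_, hi = NA_real_,
                p = NA_real_))
  }
  ratio <- obs / expected
  dev_at <- function(w) {
    term <- if (obs > 0) obs * log(obs / (w * expected)) else 0
    2 * (term - obs + w * expected)
  }
  p <- stats::pchisq(dev_at(1), df = 1, lower.tail = FALSE)
  crit <- stats::qchisq(conf, df = 1)
  f <- function(w) dev_at(w) - crit
  lo <- if (obs == 0) 0 else {
    stats::uniroot(f, c(ratio * 1e-8, ratio))$root
  }
  hi_upper <- max(ratio * 10 + 10, 10)
  while (f(hi_upper) < 0) hi_upper <- hi_upper * 10
  hi <- stats::uniroot(f, c(max(ratio, 1e-12), hi_upper))$root
  list(ratio = ratio, lo = lo, hi = hi, p = p)
}

#' Estimate exome-wide and per-gene dN/dS
#'
#' Fits per-context mutation rates from synonymous observations and
#' opportunities, computes expected missense and nonsense (truncating)
#' counts, and reports the observed/expected ratios with Poisson LRT
#' p-values against neutrality and profile-likelihood confidence
#' intervals.  The 96 context classes are collapsed to the 6 pyrimidine
#' substitution types when any class (with opportunities) carries fewer
#' than `min_syn_per_class` observed synonymous mutations; the collapse is
#' deterministic and recorded in the fit.  Per-gene ratios use gene-local
#' opportunities with exome-wide rates and are reported as `NA` when the
#' gene has no observed substitution.
#'
#' Recurrent variants (seen in more than one tumor) should be excluded
#' beforehand via [exclude_recurrent()].
#'
#' @param somatic somatic SNVs (data frame with `chrom`, `pos`, `ref`,
#'   `alt`); only variants inside genes contribute.
#' @param genome a `toy_genome`.
#' @param opportunities optional precomputed [count_opportunities()] result.
#' @param min_syn_per_class sparsity threshold triggering the 96 -> 6
#'   collapse (default 5).
#' @param conf confidence level.
#' @return an object of class `dnds_fit`: list with `exome` (data frame
#'   with rows `missense`, `truncating`, `all`: observed, expected, ratio,
#'   CI, p), `genes` (per-gene data frame), `rates`, `collapsed`
#'   (logical), `n_classes`.
#' @export
estimate_dnds <- function(somatic, genome, opportunities = NULL,
                          min_syn_per_class = 5L, conf = 0.95) {
  stopifnot(inherits(genome, "toy_genome"))
  if (is.null(opportunities)) opportunities <- count_opportunities(genome)
  v <- as.data.frame(somatic)

  # classify observed substitutions by consequence and context class
  sites <- site_index(genome, coding_only = TRUE)
  skey <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  vkey <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  hit <- match(vkey, skey)
  coding <- !is.na(hit)
  obs <- data.frame(gene_id = sites$gene_id[hit[coding]],
                    class96 = sites$class96[hit[coding]],
                    cons = sites$cons[hit[coding]],
                    stringsAsFactors = FALSE)
  n_syn_total <- sum(obs$cons == "syn")
  if (n_syn_total == 0L) {
    stop("no synonymous substitutions observed; context rates inestimable")
  }

  exo <- opportunities$exome
  syn_obs_96 <- tabulate(obs$class96[obs$cons == "syn"], nbins = 96L)
  informative <- exo[, "syn"] > 0
  collapsed <- any(syn_obs_96[informative] < min_syn_per_class)

  if (collapsed) {
    type_of <- rep(1:6, each = 16L)
    group <- type_of
    n_classes <- 6L
  } else {
    group <- 1:96
    n_classes <- 96L
  }
  gf <- factor(group, levels = sort(unique(group)))
  g_syn_obs <- tapply(syn_obs_96, gf, sum)
  g_syn_opp <- tapply(exo[, "syn"], gf, sum)
  rates <- ifelse(g_syn_opp > 0, g_syn_obs / g_syn_opp, 0)
  rate_of_class <- rates[as.character(group)]

  e_mis <- sum(rate_of_class * exo[, "mis"])
  e_non <- sum(rate_of_class * exo[, "non"])
  n_mis <- sum(obs$cons == "mis")
  n_non <- sum(obs$cons == "non")

  # per-(collapsed-)class observed counts for the joint-likelihood test
  mis_obs_96 <- tabulate(obs$class96[obs$cons == "mis"], nbins = 96L)
  non_obs_96 <- tabulate(obs$class96[obs$cons == "non"], nbins = 96L)
  g_mis_obs <- tapply(mis_obs_96, gf, sum)
  g_non_obs <- tapply(non_obs_96, gf, sum)
  g_mis_opp <- tapply(exo[, "mis"], gf, sum)
  g_non_opp <- tapply(exo[, "non"], gf, sum)

  scopes <- list(
    missense = list(obs = n_mis, exp = e_mis,
                    N = g_mis_obs, Ln = g_mis_opp),
    truncating = list(obs = n_non, exp = e_non,
                      N = g_non_obs, Ln = g_non_opp),
    all = list(obs = n_mis + n_non, exp = e_mis + e_non,
               N = g_mis_obs + g_non_obs, Ln = g_mis_opp + g_non_opp))
  exome_rows <- lapply(names(scopes), function(nm) {
    sc <- scopes[[nm]]
    ratio <- if (sc$exp > 0) sc$obs / sc$exp else NA_real_
    inf <- profile_ratio_inference(as.numeric(g_syn_obs),
                                   as.numeric(g_syn_opp),
                                   as.numeric(sc$N), as.numeric(sc$Ln),
                                   ratio, conf = conf)
    data.frame(scope = nm, observed = sc$obs, expected = sc$exp,
               ratio = inf$ratio, ci_lo = inf$lo, ci_hi = inf$hi,
               p_value = inf$p, stringsAsFactors = FALSE)
  })
  exome_df <- do.call(rbind, exome_rows)

  # per-gene: gene-local opportunities, exome-wide rates
  bg <- opportunities$by_gene
  bg$rate <- rate_of_class[bg$class96]
  e_gene <- rowsum(cbind(e_mis = bg$rate * bg$n_mis,
                         e_non = bg$rate * bg$n_non), bg$gene_id)
  genes <- rownames(e_gene)
  obs_mis <- table(factor(obs$gene_id[obs$cons == "mis"], levels = genes))
  obs_non <- table(factor(obs$gene_id[obs$cons == "non"], levels = genes))
  obs_syn <- table(factor(obs$gene_id[obs$cons == "syn"], levels = genes))
  gene_df <- data.frame(
    gene_id = genes,
    n_syn = as.integer(obs_syn), n_mis = as.integer(obs_mis),
    n_non = as.integer(obs_non),
    e_mis = e_gene[, "e_mis"], e_non = e_gene[, "e_non"],
    stringsAsFactors = FALSE)
  gene_inf <- mapply(function(o, e, any_obs) {
    if (!any_obs) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    inf <- poisson_ratio_inference(o, e, conf = conf)
    c(inf$ratio, inf$lo, inf$hi, inf$p)
  }, gene_df$n_mis + gene_df$n_non, gene_df$e_mis + gene_df$e_non,
     gene_df$n_syn + gene_df$n_mis + gene_df$n_non > 0L)
  gene_df$ratio <- gene_inf[1, ]
  gene_df$ci_lo <- gene_inf[2, ]
  gene_df$ci_hi <- gene_inf[3, ]
  gene_df$p_value <- gene_inf[4, ]
  rownames(gene_df) <- NULL

  structure(list(exome = exome_df, genes = gene_df,
                 rates = stats::setNames(as.numeric(rates),
                                         as.character(sort(unique(group)))),
                 collapsed = collapsed, n_classes = n_classes,
                 n_coding_variants = nrow(obs),
                 n_noncoding_dropped = sum(!coding), conf = conf),
            class = "dnds_fit")
}

#' @export
print.dnds_fit <- function(x, digits = 3, ...) {
  cat("dN/dS selection fit (", x$n_classes, " rate classes",
      if (x$collapsed) ", collapsed for sparsity" else "", "; ",
      x$n_coding_variants, " coding SNVs)\n", sep = "")
  df <- x$exome
  df$ratio <- round(df$ratio, digits)
  df$ci_lo <- round(df$ci_lo, digits)
  df$ci_hi <- round(df$ci_hi, digits)
  df$p_value <- signif(df$p_value, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.dnds_fit <- function(object, alpha = 0.05, ...) {
  sig <- object$genes[!is.na(object$genes$p_value) &
                        object$genes$p_value < alpha, , drop = FALSE]
  out <- list(exome = object$exome, n_genes = nrow(object$genes),
              significant_genes = sig, alpha = alpha,
              collapsed = object$collapsed)
  class(out) <- "summary.dnds_fit"
  out
}

#' @export
print.summary.dnds_fit <- function(x, ...) {
  cat("Exome-wide dN/dS:\n")
  print(x$exome, row.names = FALSE)
  cat("\nGenes with detectable selection at alpha =", x$alpha, ":",
      nrow(x$significant_genes), "of", x$n_genes, "\n")
  if (nrow(x$significant_genes)) {
    print(x$significant_genes[, c("gene_id", "ratio", "p_value")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a dN/dS fit as TSV
#'
#' @param fit a `dnds_fit`.
#' @param path output path; the exome-wide block is written with
#'   `scope = "exome"` rows followed by per-gene rows.
#' @export
write_dnds_tsv <- function(fit, path) {
  ex <- data.frame(scope = "exome", unit = fit$exome$scope,
                   fit$exome[, -1], stringsAsFactors = FALSE)
  gn <- data.frame(scope = "gene", unit = fit$genes$gene_id,
                   observed = fit$genes$n_mis + fit$genes$n_non,
                   expected = fit$genes$e_mis + fit$genes$e_non,
                   ratio = fit$genes$ratio, ci_lo = fit$genes$ci_lo,
                   ci_hi = fit$genes$ci_hi, p_value = fit$genes$p_value,
                   stringsAsFactors = FALSE)
  utils::write.table(rbind(ex, gn), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
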