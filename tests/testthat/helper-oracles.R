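# Independent oracles, deliberately simple and separate from the package's
# implementation paths.

# Two-sided Fisher p by full enumeration of all 2x2 tables with the observed
# margins, summing hypergeometric point probabilities <= the observed one
# (with a small relative tolerance against floating-point ties).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }, numeric(1))
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric enrichment p by exhaustive summation over
# overlap counts.
oracle_hyper_p <- function(overlap, set_size, query_size, universe) {
  js <- overlap:min(set_size, query_size)
  sum(vapply(js, function(j) {
    choose(set_size, j) * choose(universe - set_size, query_size - j) /
      choose(universe, query_size)
  }, numeric(1)))
}

# Benjamini-Hochberg by the textbook step-up formula.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Consequence of a coding SNV straight from a codon table lookup, using
# Biostrings' genetic code as the independent source when available.
oracle_consequence <- function(cds, cds_pos, alt_base) {
  code <- if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::GENETIC_CODE
  } else {
    exomeburden:::CODON_TABLE
  }
  chars <- strsplit(cds, "")[[1]]
  ci <- (cds_pos - 1) %/% 3
  codon <- paste(chars[ci * 3 + 1:3], collapse = "")
  alt_codon <- codon
  substr(alt_codon, (cds_pos - 1) %% 3 + 1, (cds_pos - 1) %% 3 + 1) <- alt_base
  aa1 <- unname(code[codon]); aa2 <- unname(code[alt_codon])
  if (aa1 == aa2) "synonymous"
  else if (aa2 == "*" && aa1 != "*") "nonsense"
  else "missense"
}

# Exact permutation p for Spearman rho (two-sided) by full enumeration of
# the n! rank permutations; feasible up to n ~ 7.
oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- perm_all(length(y))
  rhos <- apply(perms, 1, function(ix) cor(rx, ry[ix]))
  mean(abs(rhos) >= obs - 1e-12)
}

perm_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_all(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep(k, rows), sub + (sub >= k))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

# Grid-search maximum-likelihood mixture weight for a 2-signature catalog.
oracle_two_sig_weight <- function(counts, P, grid = seq(0, 1, by = 1e-3)) {
  ll <- vapply(grid, function(w) {
    mix <- w * P[, 1] + (1 - w) * P[, 2]
    sum(counts * log(pmax(mix, 1e-300)))
  }, numeric(1))
  grid[which.max(ll)]
}
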