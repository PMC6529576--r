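test_that("96-context binning follows the pyrimidine convention", {
  # chromosome TAGAT: G>T at position 3 has plus-strand context 5'-AGA-3';
  # the purine reference is flipped, giving T[C>A]T
  g <- list(genes = data.frame(gene_id = character(0), chrom = character(0),
                               start = integer(0), end = integer(0),
                               strand = character(0), cds = character(0)),
            chromosomes = c(chr1 = "TAGATACGTT"),
            cache = new.env(parent = emptyenv()))
  class(g) <- "toy_genome"
  sp <- spectrum_96(data.frame(chrom = "chr1", pos = 3, ref = "G",
                               alt = "T"), g)
  expect_equal(sum(sp), 1)
  expect_equal(names(which(sp == 1)), "T[C>A]T")
  # C>T inside 5'-ACG-3' stays unflipped: A[C>T]G
  sp2 <- spectrum_96(data.frame(chrom = "chr1", pos = 7, ref = "C",
                                alt = "T"), g)
  expect_equal(names(which(sp2 == 1)), "A[C>T]G")
  # edge positions carry no flank
  expect_error(spectrum_96(data.frame(chrom = "chr1", pos = 1, ref = "T",
                                      alt = "A"), g), "flank")
})

test_that("spectra are invariant under reverse-complementing the genome", {
  g <- build_toy_exome(10, 300, seed = 5)
  si <- site_index(g)
  set.seed(8)
  v <- si[sample(nrow(si), 500), c("chrom", "pos", "ref", "alt")]
  sp <- spectrum_96(v, g)
  # mirror genome: every chromosome reverse-complemented
  g2 <- g
  g2$chromosomes <- vapply(g$chromosomes, exomeburden:::revcomp,
                           character(1))
  g2$cache <- new.env(parent = emptyenv())
  L <- nchar(g$chromosomes)[v$chrom]
  v2 <- data.frame(chrom = v$chrom, pos = L - v$pos + 1L,
                   ref = exomeburden:::complement_bases(v$ref),
                   alt = exomeburden:::complement_bases(v$alt))
  sp2 <- spectrum_96(v2, g2)
  expect_equal(as.integer(sp2), as.integer(sp))
})

test_that("catalog constructor, validation and TSV round-trip work", {
  cat_ <- synthetic_signature_catalog(12, seed = 2)
  expect_equal(dim(cat_), c(96L, 12L))
  expect_equal(unname(colSums(cat_)), rep(1, 12), tolerance = 1e-12)
  d <- withr::local_tempdir()
  p <- file.path(d, "catalog.tsv")
  write_signature_catalog(cat_, p)
  back <- read_signature_catalog(p)
  expect_equal(unclass(back), unclass(cat_), tolerance = 1e-12)
  bad <- cat_; bad[1, 1] <- bad[1, 1] + 0.5
  expect_error(exomeburden:::validate_catalog(bad), "sum to 1")
})

test_that("EM exposures maximize the likelihood and stay on the simplex", {
  cat_ <- synthetic_signature_catalog(8, seed = 3)
  set.seed(4)
  for (i in 1:5) {
    w_true <- as.vector(rmultinom(1, 20, rep(1, 8))) / 20
    x <- as.vector(rmultinom(1, 3000, as.vector(cat_ %*% w_true)))
    f <- fit_exposures(x, cat_, n_boot = 50, seed = i)
    expect_true(all(f$weights >= 0))
    expect_equal(sum(f$weights), 1, tolerance = 1e-6)
    expect_true(all(diff(f$loglik) >= -1e-8))  # monotone ascent
  }
})

test_that("EM agrees with a grid-search oracle on two signatures", {
  cat2 <- synthetic_signature_catalog(2, seed = 9)
  set.seed(10)
  for (w in c(0.15, 0.5, 0.85)) {
    x <- as.vector(rmultinom(1, 5000, w * cat2[, 1] + (1 - w) * cat2[, 2]))
    f <- fit_exposures(x, cat2, n_boot = 20, seed = 1)
    expect_lt(abs(unname(f$weights[1]) -
                    oracle_two_sig_weight(x, unclass(cat2))), 2e-3)
  }
})

test_that("exposure recovery hits the documented accuracy marks", {
  cat_ <- synthetic_signature_catalog(30)
  # single signature: weight >= 0.95
  set.seed(7)
  x1 <- as.vector(rmultinom(1, 1000, cat_[, 3]))
  f1 <- fit_exposures(x1, cat_, n_boot = 100, seed = 1)
  expect_gte(unname(f1$weights[3]), 0.95)
  # two-signature truth (0.6, 0.4) at n = 10000: both within 0.05
  x2 <- as.vector(rmultinom(1, 10000, 0.6 * cat_[, 2] + 0.4 * cat_[, 9]))
  f2 <- fit_exposures(x2, cat_, n_boot = 100, seed = 1)
  expect_lt(abs(f2$weights[2] - 0.6), 0.05)
  expect_lt(abs(f2$weights[9] - 0.4), 0.05)
  # degenerate catalog of one signature: weight exactly 1
  cat1 <- cat_[, 1, drop = FALSE]
  class(cat1) <- class(cat_)
  f3 <- fit_exposures(x1, cat1, n_boot = 20, seed = 1)
  expect_equal(unname(f3$weights), 1)
  # dimension mismatch rejected
  expect_error(fit_exposures(x1[1:50], cat_), "match")
})

test_that("recovery error shrinks with the SNV count", {
  cat_ <- synthetic_signature_catalog(30)
  truth <- replace(numeric(30), c(2, 9), c(0.6, 0.4))
  err_at <- function(n, seed) {
    set.seed(seed)
    x <- as.vector(rmultinom(1, n, as.vector(cat_ %*% truth)))
    f <- fit_exposures(x, cat_, n_boot = 20, seed = 1)
    sum(abs(f$weights - truth))
  }
  expect_gt(err_at(100, 5), err_at(10000, 5))
})

test_that("select-and-refit keeps active signatures and renormalises", {
  cat_ <- synthetic_signature_catalog(30)
  # single active signature -> stage 2 weight exactly 1
  set.seed(15)
  x <- as.vector(rmultinom(1, 2000, cat_[, 6]))
  f <- select_and_refit(x, cat_, n_boot = 200, seed = 2)
  expect_true(f$selected[6])
  expect_equal(unname(f$weights["S6"]), 1, tolerance = 1e-6)
  # threshold 0 with every bound positive keeps the whole (2-col) catalog
  cat2 <- synthetic_signature_catalog(2, seed = 9)
  x2 <- as.vector(rmultinom(1, 5000, 0.5 * cat2[, 1] + 0.5 * cat2[, 2]))
  f2 <- select_and_refit(x2, cat2, threshold = 0, n_boot = 200, seed = 2)
  if (all(f2$stage1$lower > 0)) {
    expect_true(all(f2$selected))
    expect_length(f2$weights, 2L)
  }
})

test_that("Spearman exposure-covariate association matches a permutation oracle", {
  # perfectly monotone and reversed pairs
  expect_equal(exposure_covariate_correlation(1:6, c(2, 4, 5, 7, 9, 11))$rho, 1)
  expect_equal(exposure_covariate_correlation(1:6, 6:1)$rho, -1)
  expect_error(exposure_covariate_correlation(1:5, rep(3, 5)), "constant")
  expect_error(exposure_covariate_correlation(1:2, 2:1), "3")
  # exact p at n = 6 against full 720-permutation enumeration
  set.seed(19)
  for (i in 1:5) {
    x <- runif(6); y <- runif(6)
    got <- exposure_covariate_correlation(x, y)
    expect_true(got$exact)
    expect_equal(got$p_value, oracle_spearman_p(x, y), tolerance = 1e-10)
  }
})
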