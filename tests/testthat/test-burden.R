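test_that("two-sided exact test matches known cohort-table values", {
  # group comparisons from a 6-control / 4-case design
  expect_equal(round(fisher_two_sided(c(1, 5, 4, 0)), 2), 0.05)
  expect_equal(round(fisher_two_sided(c(4, 2, 3, 1)), 2), 1.00)
  expect_equal(round(fisher_two_sided(c(2, 4, 1, 3)), 2), 1.00)
  expect_equal(round(fisher_two_sided(c(2, 4, 2, 2)), 2), 1.00)
  expect_equal(fisher_two_sided(c(3, 0, 0, 3)), 0.1)
  expect_equal(fisher_two_sided(c(0, 5, 0, 5)), 1.0)
  expect_error(fisher_two_sided(c(-1, 1, 1, 1)), "non-negative")
  expect_error(fisher_two_sided(c(0, 0, 0, 0)), "margin")
})

test_that("exact test equals margin-fixed enumeration on random tables", {
  set.seed(1)
  for (i in 1:200) {
    tb <- sample(0:12, 4, replace = TRUE)
    if (sum(tb) == 0) next
    expect_equal(fisher_two_sided(tb),
                 oracle_fisher_p(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-10)
  }
})

test_that("two-sided p is invariant under swapping group labels", {
  set.seed(2)
  for (i in 1:50) {
    tb <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (sum(tb) == 0) next
    expect_equal(fisher_two_sided(tb), fisher_two_sided(tb[, 2:1]))
    expect_equal(fisher_two_sided(tb), fisher_two_sided(tb[2:1, ]))
  }
})

make_somatic <- function(genes, patients) {
  data.frame(chrom = "chr1", pos = seq_along(genes), ref = "A", alt = "C",
             gene_id = genes, patient = patients, stringsAsFactors = FALSE)
}

test_that("per-gene tables count in-gene vs elsewhere by vital status", {
  # 100 variants total: gene gX holds 10 in deceased, 0 in alive; the
  # remaining 90 split 40 deceased / 50 alive
  som <- make_somatic(
    c(rep("gX", 10), rep("gY", 90)),
    c(rep("P01", 10), rep("P01", 40), rep("P02", 50)))
  labels <- data.frame(patient = c("P01", "P02"),
                       vital_status = c("deceased", "alive"))
  tabs <- gene_burden_tables(som, labels)
  expect_equal(unname(tabs$gX), matrix(c(10, 0, 40, 50), 2, byrow = TRUE))
  # genes with no variants are absent
  expect_named(tabs, c("gX", "gY"))
  # unlabelled patient errors
  expect_error(gene_burden_tables(som, labels[1, , drop = FALSE]),
               "unlabelled")
})

test_that("presence mode counts patients rather than variants", {
  som <- make_somatic(rep("gX", 5), c("P01", "P01", "P01", "P02", "P02"))
  labels <- data.frame(patient = c("P01", "P02", "P03"),
                       vital_status = c("deceased", "alive", "alive"))
  tabs <- gene_burden_tables(som, labels, mode = "presence")
  expect_equal(unname(tabs$gX), matrix(c(1, 1, 0, 1), 2, byrow = TRUE))
})

test_that("gene ranking applies the p / count / id tie-break and alpha cut", {
  res <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    n_deceased = c(1, 8, 2, 3), n_alive = c(0, 4, 1, 0),
    elsewhere_deceased = 10, elsewhere_alive = 10,
    p_value = c(0.001, 0.04, 0.04, 0.2), stringsAsFactors = FALSE)
  out <- rank_genes(res, alpha = 0.05)
  expect_equal(out$gene_id, c("gA", "gB", "gC", "gD"))  # 12 variants beat 3
  expect_equal(out$rank, 1:4)
  expect_equal(sum(out$prioritized), 3L)
  # all p above alpha -> empty prioritized list
  res2 <- transform(res, p_value = p_value + 0.5)
  expect_equal(sum(rank_genes(res2)$prioritized), 0L)
})

test_that("inflation factor matches its closed forms and null simulation", {
  expect_equal(inflation_lambda(rep(0.5, 11))$lambda, 1)
  lam <- inflation_lambda(rep(0.05, 11))$lambda
  expect_equal(lam, qchisq(0.95, 1) / qchisq(0.5, 1), tolerance = 1e-10)
  expect_equal(round(lam, 2), 8.44)
  set.seed(3)
  lam_u <- inflation_lambda(runif(10000))$lambda
  expect_gt(lam_u, 0.95)
  expect_lt(lam_u, 1.05)
  expect_error(inflation_lambda(c(0.5, 0)), "0, 1")
  expect_error(inflation_lambda(c(0.5, 1.2)), "0, 1")
  # QQ vectors: equal length, expected sorted
  rep_ <- inflation_lambda(runif(50))
  expect_length(rep_$observed, 50)
  expect_length(rep_$expected, 50)
  expect_true(all(diff(rep_$observed) <= 0) || all(diff(rep_$observed) >= 0))
})

test_that("external count-table mode reproduces the shared test machinery", {
  counts <- data.frame(gene_id = c("gA", "gB", "gC"),
                       deceased_count = c(10, 0, 3),
                       alive_count = c(0, 0, 4))
  fit <- external_burden_test(counts, c(deceased = 50, alive = 50))
  res <- fit$results
  expect_equal(res$p_value[res$gene_id == "gA"],
               fisher_two_sided(c(10, 0, 40, 50)))
  expect_equal(res$p_value[res$gene_id == "gB"], 1)
  # significance flags equal the enumerated p < 0.05 set
  for (i in seq_len(nrow(res))) {
    want <- oracle_fisher_p(res$n_deceased[i], res$n_alive[i],
                            res$elsewhere_deceased[i],
                            res$elsewhere_alive[i]) < 0.05
    expect_equal(res$prioritized[i], want)
  }
  expect_error(external_burden_test(counts, c(deceased = 5, alive = 50)),
               "exceed")
})

test_that("external counts load with their YAML totals sidecar", {
  d <- withr::local_tempdir()
  tsv <- file.path(d, "ext.tsv")
  write.table(data.frame(gene_id = c("gA", "gB"), deceased_count = c(2, 0),
                         alive_count = c(1, 3)),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("totals:\n  deceased: 40\n  alive: 60",
             file.path(d, "ext.yaml"))
  ext <- read_external_counts(tsv)
  expect_equal(ext$totals$deceased, 40)
  fit <- external_burden_test(ext$counts, ext$totals)
  expect_equal(nrow(fit$results), 2L)
})

test_that("a planted high-burden gene attains the minimum p end-to-end", {
  g <- shared_genome()
  cfg <- cohort_config(burden_effects = c(g042 = 20), seed = 77)
  sim <- simulate_cohort(g, cfg)
  som <- refine_somatic(as_cohort(sim))
  fit <- burden_test(annotate_variants(som, g), sim$patients)
  expect_equal(fit$results$gene_id[1], "g042")
  expect_equal(which.min(fit$results$p_value), 1L)
})
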