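test_that("cohort configuration rejects invalid parameters", {
  expect_error(cohort_config(somatic_rate = -1), "somatic_rate")
  expect_error(cohort_config(mortality_fraction = 1.5), "mortality_fraction")
  expect_error(cohort_config(signature_exposures = rep(0.5, 30)),
               "sum to 1")
  expect_error(cohort_config(signature_exposures = c(1, 0.5)),
               "per catalog signature")
  expect_error(cohort_config(burden_effects = c(3)), "named")
})

test_that("simulate_cohort rejects burden genes absent from the genome", {
  g <- build_toy_exome(5, 90, seed = 1)
  cfg <- quick_config(burden_effects = c(gZZZ = 10))
  expect_error(simulate_cohort(g, cfg), "gZZZ")
})

test_that("with somatic and artifact rates zero, tumor equals matched normal", {
  g <- build_toy_exome(20, 300, seed = 3)
  cfg <- quick_config(somatic_rate = 0, artifact_snv_rate = 0,
                      homopolymer_indel_rate = 0)
  sim <- simulate_cohort(g, cfg)
  for (p in sim$patients$patient) {
    tum <- sim$calls[sim$calls$patient == p & sim$calls$tissue == "tumor", ]
    nor <- sim$calls[sim$calls$patient == p & sim$calls$tissue == "normal", ]
    k <- function(x) sort(paste(x$chrom, x$pos, x$ref, x$alt))
    expect_identical(k(tum), k(nor))
  }
})

test_that("truth labels partition the call set and germline is consistent", {
  g <- build_toy_exome(20, 300, seed = 3)
  sim <- simulate_cohort(g, quick_config(seed = 8))
  expect_true(all(sim$calls$truth %in% c("somatic", "germline", "artifact")))
  expect_equal(sum(sim$truth$label_counts), nrow(sim$calls))
  # germline consistency: every truth-germline variant of patient i is in
  # patient i's normal call set
  germ <- sim$calls[sim$calls$truth == "germline", ]
  for (p in unique(germ$patient)) {
    gp <- germ[germ$patient == p, ]
    norm_keys <- paste(gp$chrom, gp$pos, gp$ref, gp$alt)[gp$tissue == "normal"]
    tum_keys <- paste(gp$chrom, gp$pos, gp$ref, gp$alt)[gp$tissue == "tumor"]
    expect_true(all(tum_keys %in% norm_keys))
  }
  # somatic variants appear only in tumors
  expect_true(all(sim$calls$tissue[sim$calls$truth == "somatic"] == "tumor"))
})

test_that("simulation is reproducible and patient streams are independent", {
  g <- build_toy_exome(20, 300, seed = 3)
  s1 <- simulate_cohort(g, quick_config(seed = 4))
  s2 <- simulate_cohort(g, quick_config(seed = 4))
  expect_identical(s1$calls, s2$calls)
  # adding a patient leaves earlier patients' calls untouched
  s3 <- simulate_cohort(g, quick_config(n_patients = 5L, seed = 4,
                                        mortality_fraction = 0))
  s4 <- simulate_cohort(g, quick_config(n_patients = 4L, seed = 4,
                                        mortality_fraction = 0))
  keep <- s3$calls$patient %in% s4$calls$patient
  a <- s3$calls[keep, setdiff(names(s3$calls), "joint_flag")]
  b <- s4$calls[, setdiff(names(s4$calls), "joint_flag")]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("pooled somatic spectrum matches a single-signature profile", {
  g <- shared_genome()
  catalog <- synthetic_signature_catalog(30)
  expo <- replace(numeric(30), 4, 1)
  cfg <- cohort_config(n_patients = 1, somatic_rate = 5000,
                       germline_rate = 0, signature_exposures = expo,
                       catalog = catalog, artifact_snv_rate = 0,
                       homopolymer_indel_rate = 0, artifact_flag_rate = 0,
                       joint_flag_rate = 0, mortality_fraction = 0,
                       exonic_fraction = 1, seed = 2)
  sim <- simulate_cohort(g, cfg)
  som <- sim$calls[sim$calls$truth == "somatic", ]
  sp <- spectrum_96(som, g)
  tv <- 0.5 * sum(abs(sp / sum(sp) - catalog[, 4]))
  expect_lt(tv, 0.05)
})

test_that("spectrum fidelity improves as the somatic load grows", {
  g <- shared_genome()
  catalog <- synthetic_signature_catalog(30)
  tv_at <- function(n) {
    cfg <- cohort_config(n_patients = 1, somatic_rate = n, germline_rate = 0,
                         signature_exposures = replace(numeric(30), 4, 1),
                         catalog = catalog, artifact_snv_rate = 0,
                         homopolymer_indel_rate = 0, artifact_flag_rate = 0,
                         joint_flag_rate = 0, mortality_fraction = 0,
                         exonic_fraction = 1, seed = 9)
    sim <- simulate_cohort(g, cfg)
    som <- sim$calls[sim$calls$truth == "somatic", ]
    sp <- spectrum_96(som, g)
    0.5 * sum(abs(sp / sum(sp) - catalog[, 4]))
  }
  expect_lt(tv_at(10000), tv_at(1000))
})

test_that("homopolymer indel artifacts sit inside >=4-base runs", {
  g <- build_toy_exome(20, 300, seed = 3)
  sim <- simulate_cohort(g, quick_config(homopolymer_indel_rate = 30,
                                         seed = 6))
  ind <- sim$calls[nchar(sim$calls$ref) != nchar(sim$calls$alt), ]
  expect_gt(nrow(ind), 0)
  expect_true(all(ind$truth == "artifact"))
  runs <- exomeburden:::homopolymer_runs(g)
  run_keys <- paste(runs$chrom, runs$pos)
  expect_true(all(paste(ind$chrom, ind$pos) %in% run_keys))
})

test_that("written cohort VCFs parse back to the simulated calls", {
  g <- build_toy_exome(20, 300, seed = 3)
  sim <- simulate_cohort(g, quick_config(seed = 5))
  d <- withr::local_tempdir()
  paths <- write_cohort(sim, d)
  expect_length(paths, 2L * nrow(sim$patients))
  coh <- parse_calls(d)
  cols <- c("chrom", "pos", "ref", "alt", "patient", "tissue",
            "read_support", "flags", "joint_flag", "genotype")
  a <- sim$calls[, cols]
  a <- a[order(a$patient, a$tissue, a$chrom, a$pos, a$alt), ]
  b <- coh$calls[order(coh$calls$patient, coh$calls$tissue, coh$calls$chrom,
                       coh$calls$pos, coh$calls$alt), ]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
  expect_true(file.exists(file.path(d, "truth_labels.tsv")))
  expect_true(file.exists(file.path(d, "truth.json")))
})
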