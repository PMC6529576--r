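# A hand-written 5-record VCF exercising the parsing contract.
write_toy_vcf <- function(path, sample = "P01_tumor") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=NV,Number=1,Type=Integer,Description=\"Supporting reads\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample),
    "chr1\t11\t.\tA\tC\t.\tPASS\t.\tGT:NV\t0/1:12",
    "chr1\t15\t.\tG\tT\t.\tPASS\t.\tGT:NV\t1/1:30",
    "chr1\t19\t.\tC\tG\t.\tPASS\t.\tGT:NV\t0/1:8",
    "chr1\t25\t.\tT\tA\t.\tstrandBias;MQ\t.\tGT:NV\t0/1:4",
    "chr1\t30\t.\tA\tC,T\t.\tPASS\t.\tGT:NV\t1/2:9"
  ), path)
  path
}

test_that("VCF parsing honours flags, genotypes and multi-allelic splitting", {
  d <- withr::local_tempdir()
  f <- write_toy_vcf(file.path(d, "P01_tumor.vcf"))
  coh <- parse_calls(f)
  calls <- coh$calls
  expect_equal(nrow(calls), 6L)  # 5 records, one split in two
  expect_equal(calls$patient[1], "P01")
  expect_equal(calls$tissue[1], "tumor")
  # three PASS SNVs with empty flag sets
  expect_equal(sum(calls$flags == ""), 5L)
  expect_equal(calls$flags[calls$pos == 25], "strandBias;MQ")
  # the multi-allelic record becomes A>C and A>T at the same locus
  split <- calls[calls$pos == 30, ]
  expect_equal(sort(split$alt), c("C", "T"))
  expect_equal(unique(split$ref), "A")
  expect_equal(split$genotype, c("het", "het"))
  expect_equal(calls$genotype[calls$pos == 15], "hom")
  expect_equal(calls$read_support[calls$pos == 11], 12L)
})

test_that("unknown FILTER values and bad sample names are rejected", {
  d <- withr::local_tempdir()
  f <- file.path(d, "P01_tumor.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP01_tumor",
    "chr1\t11\t.\tA\tC\t.\tlowQual\t.\tGT\t0/1"), f)
  expect_error(parse_calls(f), "badReads")
  f2 <- file.path(d, "odd.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampleX",
    "chr1\t11\t.\tA\tC\t.\tPASS\t.\tGT\t0/1"), f2)
  expect_error(parse_calls(f2), "tissue")
})

test_that("flag filtering keeps exactly the unflagged calls, in order", {
  set.seed(42)
  flags <- c(rep("", 12), "badReads", "MQ", "strandBias;QD", "SC", "QD",
             "badReads;MQ", "", "")
  calls <- do.call(rbind, lapply(seq_along(flags), function(i) {
    call_row(pos = 10L + i, flags = flags[i])
  }))
  out <- filter_flagged(calls)
  expect_equal(nrow(out), sum(flags == ""))
  expect_equal(out$pos, calls$pos[flags == ""])  # order preserved
  expect_equal(attr(out, "n_removed"), sum(flags != ""))
  rem <- attr(out, "flag_removals")
  expect_equal(unname(rem["badReads"]), 2L)
  expect_equal(unname(rem["QD"]), 2L)
  # degenerate cases
  all_flagged <- calls[flags != "", ]
  expect_equal(nrow(filter_flagged(all_flagged)), 0L)
})

test_that("joint genotyping imputes hom-ref across samples and re-filters", {
  calls <- rbind(
    call_row(pos = 11, patient = "P01", tissue = "tumor"),
    call_row(pos = 11, patient = "P01", tissue = "normal"),
    call_row(pos = 20, patient = "P02", tissue = "tumor"),
    call_row(pos = 30, patient = "P02", tissue = "tumor",
             joint_flag = "MQ"),
    call_row(pos = 99, patient = "P02", tissue = "normal"))
  coh <- as_cohort(calls)
  out <- merge_genotype_refilter(coh)
  gmat <- attr(out, "genotypes")
  # the variant seen only in P02's tumor is genotyped hom-ref elsewhere
  expect_equal(gmat["chr1:20:A:C", "P01_tumor"], "hom_ref")
  expect_equal(gmat["chr1:20:A:C", "P02_tumor"], "het")
  # the joint-flagged variant is gone from all samples
  expect_false("chr1:30:A:C" %in% rownames(gmat))
  expect_false(any(out$calls$pos == 30))
  expect_equal(attr(out, "n_removed_joint"), 1L)
  # rectangular over all samples
  expect_equal(ncol(gmat), 4L)
})

test_that("single-sample cohort: merge stage adds nothing beyond flag filter", {
  calls <- rbind(call_row(pos = 11), call_row(pos = 12, flags = "MQ"),
                 call_row(pos = 13))
  f1 <- filter_flagged(as_cohort(calls))
  out <- merge_genotype_refilter(f1)
  expect_identical(out$calls, f1$calls)
})

test_that("somatic classification applies panel-of-normals, support and SNV rules", {
  calls <- rbind(
    # tumor-only SNV, well supported -> somatic
    call_row(pos = 11, patient = "P01", read_support = 10L),
    # present in ANOTHER patient's normal -> germline, removed
    call_row(pos = 20, patient = "P01", read_support = 10L),
    call_row(pos = 20, patient = "P02", tissue = "normal"),
    # tumor-only but 2 supporting reads -> removed
    call_row(pos = 30, patient = "P01", read_support = 2L),
    # tumor-only indel -> excluded from the SNV set
    call_row(pos = 40, patient = "P01", ref = "A", alt = "AT"),
    # P02 needs a tumor sample for a rectangular cohort
    call_row(pos = 50, patient = "P02", read_support = 7L))
  som <- classify_somatic(as_cohort(calls))
  expect_s3_class(som, "somatic_set")
  expect_setequal(som$pos, c(11, 50))
  f <- attr(som, "funnel")
  expect_equal(unname(f["removed_in_normal"]), 1L)
  expect_equal(unname(f["removed_low_support"]), 1L)
  expect_equal(unname(f["removed_indel"]), 1L)
  # no normals -> the panel is undefined
  tum_only <- calls[calls$tissue == "tumor", ]
  expect_error(classify_somatic(as_cohort(tum_only)), "panel of normals")
})

test_that("somatic classification is idempotent", {
  calls <- rbind(
    call_row(pos = 11, patient = "P01", read_support = 10L),
    call_row(pos = 13, patient = "P01", read_support = 5L),
    call_row(pos = 99, patient = "P01", tissue = "normal"))
  som <- classify_somatic(as_cohort(calls))
  again <- classify_somatic(as_cohort(rbind(
    as.data.frame(som), calls[calls$tissue == "normal", ])))
  expect_identical(sort(paste(again$chrom, again$pos, again$alt)),
                   sort(paste(som$chrom, som$pos, som$alt)))
})

test_that("recurrent variants are removed from every patient", {
  som <- rbind(
    call_row(pos = 11, patient = "P01"),
    call_row(pos = 11, patient = "P02"),   # shared by 2 tumors
    call_row(pos = 30, patient = "P01"))
  out <- exclude_recurrent(som, max_tumors = 1)
  expect_equal(out$pos, 30)
  expect_equal(attr(out, "n_recurrent_removed"), 2L)
  # max_tumors = 2 keeps the doubly-seen variant
  out2 <- exclude_recurrent(som, max_tumors = 2)
  expect_equal(nrow(out2), 3L)
  # all variants shared by all tumors -> empty
  shared <- rbind(call_row(pos = 11, patient = "P01"),
                  call_row(pos = 11, patient = "P02"))
  expect_equal(nrow(exclude_recurrent(shared)), 0L)
  expect_error(exclude_recurrent(som, max_tumors = 0), "max_tumors")
})

test_that("funnel stages are monotone and counters sum on simulated data", {
  g <- build_toy_exome(20, 300, seed = 3)
  sim <- simulate_cohort(g, quick_config(seed = 7))
  coh <- as_cohort(sim)
  f1 <- filter_flagged(coh)
  expect_lte(nrow(f1$calls), nrow(coh$calls))
  f2 <- merge_genotype_refilter(f1)
  expect_lte(nrow(f2$calls), nrow(f1$calls))
  som <- classify_somatic(f2)
  fu <- attr(som, "funnel")
  expect_equal(unname(fu["tumor_calls"]),
               unname(fu["removed_in_normal"] + fu["removed_low_support"] +
                        fu["removed_indel"] + fu["somatic_snvs"]))
})

test_that("on synthetic truth the refined set is germline-free and fully sensitive", {
  g <- build_toy_exome(30, 300, seed = 3)
  sim <- simulate_cohort(g, quick_config(n_patients = 5L, seed = 10))
  som <- refine_somatic(as_cohort(sim))
  expect_true(all(som$truth == "somatic"))
  # all clean truth-somatic calls survive
  clean <- sim$calls[sim$calls$truth == "somatic" & sim$calls$flags == "" &
                       is.na(sim$calls$joint_flag) &
                       sim$calls$read_support >= 3, ]
  k <- function(x) paste(x$chrom, x$pos, x$alt, x$patient)
  expect_true(all(k(clean) %in% k(som)))
})
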