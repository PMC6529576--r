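# Fixtures built in code: hand-constructed toy genomes, call tables and
# in-memory cohorts.

# A toy_genome with fully controlled content: one gene per element of `cds`,
# each on its own chromosome, flanked by fixed-width spacers.
make_genome <- function(cds, strand = rep("+", length(cds)),
                        spacer = "ACGTACGTAC") {
  genes <- vector("list", length(cds))
  chroms <- character(length(cds))
  for (i in seq_along(cds)) {
    gseq <- if (strand[i] == "+") cds[i] else exomeburden:::revcomp(cds[i])
    chroms[i] <- paste0(spacer, gseq, spacer)
    genes[[i]] <- data.frame(
      gene_id = sprintf("g%03d", i), chrom = paste0("chr", i),
      start = nchar(spacer) + 1L, end = nchar(spacer) + nchar(gseq),
      strand = strand[i], cds = cds[i], stringsAsFactors = FALSE)
  }
  names(chroms) <- paste0("chr", seq_along(cds))
  g <- list(genes = do.call(rbind, genes), chromosomes = chroms,
            cache = new.env(parent = emptyenv()))
  class(g) <- "toy_genome"
  g
}

# Wrap a calls data frame (or a cohort_sim) as a call_cohort without going
# through VCF files.
as_cohort <- function(x) {
  calls <- if (inherits(x, "cohort_sim")) x$calls else x
  exomeburden:::as_call_cohort(calls)
}

# Minimal call-table row constructor.
call_row <- function(chrom = "chr1", pos = 11L, ref = "A", alt = "C",
                     patient = "P01", tissue = "tumor", read_support = 10L,
                     flags = "", joint_flag = NA_character_,
                     genotype = "het") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             patient = patient, tissue = tissue,
             read_support = read_support, flags = flags,
             joint_flag = joint_flag, genotype = genotype,
             stringsAsFactors = FALSE)
}

# Shared mid-size genome for expensive tests (built once per test run).
shared_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- build_toy_exome(100, 900, seed = 1)
    g
  }
})

# Quiet default-ish config for small simulations.
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(n_patients = 4L, somatic_rate = 200, germline_rate = 300,
                   artifact_snv_rate = 10, homopolymer_indel_rate = 10,
                   seed = 1L)
  do.call(cohort_config, utils::modifyList(defaults, args))
}
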