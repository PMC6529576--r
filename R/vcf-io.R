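# VCF v4.2 emission and parsing.
#
# One single-sample VCF per (patient, tissue); caller quality flags are
# carried in FILTER (values from the five-flag vocabulary, PASS when clean),
# joint-genotyping flags in INFO/JF, and per-sample genotype / supporting
# read count in FORMAT GT:NV.  Parsing goes through vcfR.

write_calls_vcf <- function(calls, path, sample_name, genome = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=exomeburden-simulator",
    sprintf("##FILTER=<ID=%s,Description=\"Caller quality flag %s\">",
            FLAG_VOCABULARY, FLAG_VOCABULARY),
    "##INFO=<ID=JF,Number=1,Type=String,Description=\"Flag acquired at joint genotyping\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=NV,Number=1,Type=Integer,Description=\"Number of reads supporting the variant\">")
  if (!is.null(genome)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(genome$chromosomes),
                          nchar(genome$chromosomes)))
  }
  hdr <- c(hdr, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                       sample_name))
  gt <- c(het = "0/1", hom = "1/1", hom_ref = "0/0", missing = "./.")
  if (nrow(calls)) {
    filt <- ifelse(calls$flags == "", "PASS", calls$flags)
    info <- ifelse(is.na(calls$joint_flag), ".",
                   paste0("JF=", calls$joint_flag))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s\tGT:NV\t%s:%d",
                    calls$chrom, calls$pos, calls$ref, calls$alt, filt, info,
                    gt[calls$genotype], calls$read_support)
  } else {
    body <- character(0)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Parse per-sample VCF call files into a cohort
#'
#' Reads VCF v4.2 files (one sample per file, file or sample name encoding
#' `{patient}_{tumor|normal}`) into the package's flat call table.
#' Multi-allelic records are split into one call per alternate allele;
#' FILTER values are validated against the five-flag vocabulary
#' (`badReads`, `MQ`, `strandBias`, `SC`, `QD`).
#'
#' @param paths character vector of VCF paths, or a single directory, in
#'   which case all `*.vcf` files in it are read.
#' @return an object of class `call_cohort`: list with `calls` (data frame
#'   with columns `chrom`, `pos`, `ref`, `alt`, `patient`, `tissue`,
#'   `read_support`, `flags`, `joint_flag`, `genotype`) and `samples`.
#' @export
parse_calls <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.vcf$", full.names = TRUE)
  }
  if (length(paths) == 0L) stop("no VCF files to parse")
  per_file <- lapply(paths, parse_one_vcf)
  calls <- do.call(rbind, per_file)
  rownames(calls) <- NULL
  samples <- unique(calls[, c("patient", "tissue")])
  rownames(samples) <- NULL
  structure(list(calls = calls, samples = samples), class = "call_cohort")
}

parse_one_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  sample_name <- colnames(v@gt)[2]
  if (is.null(sample_name)) {
    stop("file ", path, " has no sample column")
  }
  parts <- strsplit(sample_name, "_", fixed = TRUE)[[1]]
  tissue <- parts[length(parts)]
  patient <- paste(parts[-length(parts)], collapse = "_")
  if (!tissue %in% c("tumor", "normal")) {
    stop("sample name '", sample_name, "' in ", path,
         " does not encode tissue (expected {patient}_{tumor|normal})")
  }
  if (n == 0L) {
    out <- empty_calls()
    out$truth <- NULL
    return(out)
  }

  filt <- fix[, "FILTER"]
  flags <- character(n)
  for (i in seq_len(n)) {
    f <- filt[i]
    if (is.na(f) || f == "PASS" || f == ".") {
      flags[i] <- ""
    } else {
      parts_f <- strsplit(f, ";", fixed = TRUE)[[1]]
      bad <- setdiff(parts_f, FLAG_VOCABULARY)
      if (length(bad)) {
        stop(sprintf(
          "%s line %d: unknown FILTER value '%s' (allowed: PASS, %s)",
          path, i, bad[1], paste(FLAG_VOCABULARY, collapse = ", ")))
      }
      flags[i] <- paste(parts_f, collapse = ";")
    }
  }

  info <- fix[, "INFO"]
  jf <- rep(NA_character_, n)
  has_jf <- grepl("(^|;)JF=", info)
  jf[has_jf] <- sub("^.*JF=([^;]+).*$", "\\1", info[has_jf])

  gt_raw <- v@gt[, 2]
  fmt <- v@gt[, 1]
  gt_field <- function(key) {
    vapply(seq_len(n), function(i) {
      keys <- strsplit(fmt[i], ":", fixed = TRUE)[[1]]
      vals <- strsplit(gt_raw[i], ":", fixed = TRUE)[[1]]
      j <- match(key, keys)
      if (is.na(j) || j > length(vals)) NA_character_ else vals[j]
    }, character(1))
  }
  gt <- gt_field("GT")
  nv <- suppressWarnings(as.integer(gt_field("NV")))
  nv[is.na(nv)] <- 0L

  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  if (anyNA(pos) || anyNA(ref) || anyNA(alt)) {
    i <- which(is.na(pos) | is.na(ref) | is.na(alt))[1]
    stop(sprintf("%s line %d: malformed record", path, i))
  }

  # split multi-allelic records: one call per alternate allele
  alt_list <- strsplit(alt, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  idx <- rep(seq_len(n), n_alt)
  alt_flat <- unlist(alt_list, use.names = FALSE)
  which_alt <- sequence(n_alt)

  genotype <- genotype_class(gt[idx], which_alt)
  data.frame(chrom = fix[idx, "CHROM"], pos = pos[idx], ref = ref[idx],
             alt = alt_flat, patient = patient, tissue = tissue,
             read_support = nv[idx], flags = flags[idx],
             joint_flag = jf[idx], genotype = genotype,
             stringsAsFactors = FALSE)
}

# Map a VCF GT string to {het, hom, hom_ref, missing} relative to a given
# alternate-allele index.
genotype_class <- function(gt, alt_index) {
  out <- character(length(gt))
  for (i in seq_along(gt)) {
    if (is.na(gt[i]) || grepl("\\.", gt[i])) {
      out[i] <- "missing"
      next
    }
    alleles <- as.integer(strsplit(gt[i], "[/|]")[[1]])
    k <- sum(alleles == alt_index[i])
    out[i] <- if (k == 0L) "hom_ref" else if (k == length(alleles)) "hom"
      else "het"
  }
  out
}

#' @export
print.call_cohort <- function(x, ...) {
  cat("Call cohort:", nrow(x$calls), "calls across", nrow(x$samples),
      "samples (", sum(x$samples$tissue == "tumor"), "tumor /",
      sum(x$samples$tissue == "normal"), "normal )\n")
  invisible(x)
}
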