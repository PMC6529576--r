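# Synthetic tumor-normal cohort generation.
#
# The simulator emits, per patient, a tumor and a normal call set with the
# statistical structure the downstream analyses assume: shared and private
# germline variants present in both tissues, somatic SNVs private to the
# tumor with trinucleotide spectra drawn from a signature mixture, planted
# per-gene burden effects in deceased patients, caller quality flags,
# homopolymer indel artifacts, and a per-call truth label.

FLAG_VOCABULARY <- c("badReads", "MQ", "strandBias", "SC", "QD")

#' Cohort simulation configuration
#'
#' Constructs and validates the configuration of [simulate_cohort()].  The
#' defaults describe the study design the package targets: ten tumor-normal
#' pairs, on the order of 10^3 somatic SNVs per cohort, a three-signature
#' mutational process, and a 40% mortality fraction.
#'
#' @param n_patients number of tumor-normal pairs.
#' @param somatic_rate expected somatic SNVs per tumor.
#' @param germline_rate expected germline variants per patient.
#' @param shared_germline_fraction probability a germline variant is drawn
#'   from a cohort-wide common pool (and hence recurs across patients).
#' @param signature_exposures numeric vector (or n_patients-row matrix) of
#'   mixture weights over the catalog columns; non-negative, summing to 1.
#'   Default: weights 0.5/0.3/0.2 on catalog columns 1, 5 and 12, the
#'   three-active-signatures structure the analysis is designed to recover.
#' @param catalog a `signature_catalog`; default
#'   [synthetic_signature_catalog()] with 30 columns.
#' @param artifact_flag_rate probability that a true call carries each caller
#'   quality flag (independently per flag).
#' @param joint_flag_rate probability that a variant site is flagged only at
#'   the joint-genotyping stage (emitted as INFO/JF).
#' @param artifact_snv_rate expected spurious SNV calls per sample; these are
#'   truth-labelled `artifact` and always carry at least one quality flag.
#' @param homopolymer_indel_rate expected artifactual indels per sample,
#'   placed only inside homopolymer runs of length >= 4.
#' @param burden_effects named numeric vector: per-gene multiplier of the
#'   somatic rate in deceased patients' tumors (e.g. `c(g007 = 20)`).
#' @param mortality_fraction fraction of patients labelled deceased.
#' @param read_support list with `mean` (shifted-Poisson mean of supporting
#'   reads) and `low_fraction` (fraction of calls contaminated with 1-2
#'   supporting reads).
#' @param exonic_fraction fraction of somatic SNVs placed inside genes.
#' @param seed master seed; each patient derives an independent stream from
#'   it, so adding a patient does not perturb earlier patients' data.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 10L,
                          somatic_rate = 900,
                          germline_rate = 2000,
                          shared_germline_fraction = 0.5,
                          signature_exposures = NULL,
                          catalog = synthetic_signature_catalog(),
                          artifact_flag_rate = 0.05,
                          joint_flag_rate = 0.01,
                          artifact_snv_rate = 30,
                          homopolymer_indel_rate = 50,
                          burden_effects = NULL,
                          mortality_fraction = 0.4,
                          read_support = list(mean = 30, low_fraction = 0.05),
                          exonic_fraction = 0.54,
                          seed = 1L) {
  validate_catalog(catalog)
  if (is.null(signature_exposures)) {
    signature_exposures <- numeric(ncol(catalog))
    active <- c(1L, 5L, 12L)
    active <- active[active <= ncol(catalog)]
    signature_exposures[active] <- c(0.5, 0.3, 0.2)[seq_along(active)]
    signature_exposures <- signature_exposures / sum(signature_exposures)
  }
  if (is.matrix(signature_exposures)) {
    if (nrow(signature_exposures) != n_patients ||
        ncol(signature_exposures) != ncol(catalog)) {
      stop("'signature_exposures' matrix must be n_patients x n_signatures")
    }
  } else {
    if (length(signature_exposures) != ncol(catalog)) {
      stop("'signature_exposures' must have one weight per catalog signature")
    }
    signature_exposures <- matrix(signature_exposures, nrow = n_patients,
                                  ncol = ncol(catalog), byrow = TRUE)
  }
  colnames(signature_exposures) <- colnames(catalog)
  if (any(signature_exposures < 0)) {
    stop("'signature_exposures' must be non-negative")
  }
  if (any(abs(rowSums(signature_exposures) - 1) > 1e-6)) {
    stop("'signature_exposures' rows must sum to 1")
  }
  rates <- c(somatic_rate = somatic_rate, germline_rate = germline_rate,
             artifact_flag_rate = artifact_flag_rate,
             joint_flag_rate = joint_flag_rate,
             artifact_snv_rate = artifact_snv_rate,
             homopolymer_indel_rate = homopolymer_indel_rate)
  for (nm in names(rates)) {
    if (!is.numeric(rates[[nm]]) || rates[[nm]] < 0) {
      stop(sprintf("'%s' must be >= 0", nm))
    }
  }
  if (mortality_fraction < 0 || mortality_fraction > 1) {
    stop("'mortality_fraction' must lie in [0, 1]")
  }
  if (shared_germline_fraction < 0 || shared_germline_fraction > 1) {
    stop("'shared_germline_fraction' must lie in [0, 1]")
  }
  if (exonic_fraction < 0 || exonic_fraction > 1) {
    stop("'exonic_fraction' must lie in [0, 1]")
  }
  if (n_patients < 1) stop("'n_patients' must be >= 1")
  if (!is.null(burden_effects)) {
    burden_effects <- unlist(burden_effects)  # YAML configs deliver a list
    if (is.null(names(burden_effects)) || !is.numeric(burden_effects) ||
        any(burden_effects < 0)) {
      stop("'burden_effects' must be a named non-negative numeric vector")
    }
  }
  structure(list(
    n_patients = as.integer(n_patients), somatic_rate = somatic_rate,
    germline_rate = germline_rate,
    shared_germline_fraction = shared_germline_fraction,
    signature_exposures = signature_exposures, catalog = catalog,
    artifact_flag_rate = artifact_flag_rate,
    joint_flag_rate = joint_flag_rate,
    artifact_snv_rate = artifact_snv_rate,
    homopolymer_indel_rate = homopolymer_indel_rate,
    burden_effects = burden_effects,
    mortality_fraction = mortality_fraction,
    read_support = read_support, exonic_fraction = exonic_fraction,
    seed = as.integer(seed)), class = "cohort_config")
}

# empty call-table skeleton
empty_calls <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), patient = character(0), tissue = character(0),
             read_support = integer(0), flags = character(0),
             joint_flag = character(0), genotype = character(0),
             truth = character(0), stringsAsFactors = FALSE)
}

draw_read_support <- function(n, rs) {
  base <- 3L + stats::rpois(n, max(rs$mean - 3, 0))
  low <- stats::runif(n) < rs$low_fraction
  base[low] <- sample(1:2, sum(low), replace = TRUE)
  base
}

draw_flags <- function(n, rate) {
  vapply(seq_len(n), function(i) {
    f <- FLAG_VOCABULARY[stats::runif(5) < rate]
    paste(f, collapse = ";")
  }, character(1))
}

#' Simulate a synthetic tumor-normal cohort
#'
#' Generates one tumor and one normal call set per patient over a toy
#' genome, together with a complete truth record.  Germline variants appear
#' in both tissues of their patient (and, when drawn from the shared pool,
#' in several patients); somatic SNVs appear only in their patient's tumor,
#' with trinucleotide contexts drawn from the patient's exposure-weighted
#' signature mixture; artifact calls carry quality flags, low read support
#' or homopolymer-indel alleles.  Deceased patients' tumors receive the
#' configured per-gene burden multipliers.  The result is a deterministic
#' function of (genome, config).
#'
#' @param genome a `toy_genome`.
#' @param config a `cohort_config`.
#' @return an object of class `cohort_sim`: list with `calls` (one row per
#'   emitted call, including a `truth` label in `somatic`/`germline`/
#'   `artifact`), `patients` (data frame of `patient`, `vital_status`),
#'   `truth` (list with `exposures`, `burden_effects`, `label_counts`),
#'   `genome`, `config`.
#' @export
simulate_cohort <- function(genome, config) {
  stopifnot(inherits(genome, "toy_genome"), inherits(config, "cohort_config"))
  if (!is.null(config$burden_effects)) {
    missing <- setdiff(names(config$burden_effects), genome$genes$gene_id)
    if (length(missing)) {
      stop("burden_effects gene(s) not in genome: ",
           paste(missing, collapse = ", "))
    }
  }
  sites <- site_index(genome)
  coding <- which(!is.na(sites$gene_id))
  intergenic <- which(is.na(sites$gene_id))
  runs <- homopolymer_runs(genome)
  patients <- sprintf("P%02d", seq_len(config$n_patients))

  # Cohort-level draws under the master seed.  The mutable site space is
  # partitioned into disjoint germline- / somatic- / artifact-eligible
  # subsets so truth categories can never collide on a variant key: in a
  # full-size genome such collisions are vanishingly rare, but in a toy
  # exome they would otherwise corrupt the panel-of-normals truth structure.
  master <- with_seed(config$seed, {
    part <- sample.int(3L, nrow(sites), replace = TRUE,
                       prob = c(0.25, 0.65, 0.10))
    germ_universe <- which(part == 1L)
    pool_n <- max(100L, ceiling(config$germline_rate))
    pool <- germ_universe[sample.int(length(germ_universe),
                                     min(pool_n, length(germ_universe)))]
    n_dec <- round(config$mortality_fraction * config$n_patients)
    vital <- rep("alive", config$n_patients)
    vital[sample(config$n_patients, n_dec)] <- "deceased"
    list(vital = vital, pool = pool, part = part,
         germ_universe = germ_universe)
  })
  vital <- stats::setNames(master$vital, patients)

  gene_len <- stats::setNames(nchar(genome$genes$cds), genome$genes$gene_id)
  gene_ids <- genome$genes$gene_id
  som_coding <- coding[master$part[coding] == 2L]
  som_intergenic <- intergenic[master$part[intergenic] == 2L]
  art_universe <- which(master$part == 3L)
  coding_by_gene <- split(som_coding, sites$gene_id[som_coding])
  p96_by_patient <- config$catalog %*% t(config$signature_exposures)

  per_patient <- lapply(seq_along(patients), function(i) {
    pid <- patients[i]
    with_seed(child_seed(config$seed, i), {
      ## --- germline (both tissues) ---
      n_g <- stats::rpois(1L, config$germline_rate)
      from_pool <- stats::runif(n_g) < config$shared_germline_fraction
      g_rows <- integer(n_g)
      g_rows[from_pool] <- resample(master$pool, sum(from_pool))
      g_rows[!from_pool] <- master$germ_universe[
        sample.int(length(master$germ_universe), sum(!from_pool))]
      g_rows <- unique(g_rows)
      g_geno <- sample(c("het", "hom"), length(g_rows), replace = TRUE,
                       prob = c(0.7, 0.3))

      ## --- somatic (tumor only), signature-mixture contexts ---
      mult <- rep(1, length(gene_ids))
      names(mult) <- gene_ids
      if (!is.null(config$burden_effects) && vital[pid] == "deceased") {
        mult[names(config$burden_effects)] <- config$burden_effects
      }
      w_gene <- gene_len * mult
      lam_gene <- config$somatic_rate * config$exonic_fraction *
        w_gene / sum(gene_len)
      n_per_gene <- stats::rpois(length(lam_gene), lam_gene)
      n_int <- stats::rpois(1L, config$somatic_rate *
                              (1 - config$exonic_fraction))
      n_som <- sum(n_per_gene) + n_int
      cls <- sample.int(96L, n_som, replace = TRUE,
                        prob = p96_by_patient[, i])
      # sites are drawn without replacement within each (region, class)
      # stratum so the pooled spectrum tracks the signature mixture; a
      # stratum short of sites falls back to unused sites of the region
      draw_sites <- function(cand, classes) {
        taken <- integer(0)
        for (c96 in unique(classes)) {
          need <- sum(classes == c96)
          hit <- setdiff(cand[sites$class96[cand] == c96], taken)
          taken <- c(taken, hit[sample.int(length(hit),
                                           min(need, length(hit)))])
        }
        short <- length(classes) - length(taken)
        if (short > 0L) {
          rest <- setdiff(cand, taken)
          taken <- c(taken, rest[sample.int(length(rest),
                                            min(short, length(rest)))])
        }
        taken
      }
      k <- 0L
      som_rows <- integer(0)
      for (gi in seq_along(gene_ids)) {
        ng <- n_per_gene[gi]
        if (ng == 0L) next
        som_rows <- c(som_rows,
                      draw_sites(coding_by_gene[[gene_ids[gi]]],
                                 cls[(k + 1L):(k + ng)]))
        k <- k + ng
      }
      if (n_int > 0L) {
        som_rows <- c(som_rows,
                      draw_sites(som_intergenic, cls[(k + 1L):(k + n_int)]))
      }

      ## --- artifact SNV calls (per tissue) ---
      art_t <- art_universe[sample.int(
        length(art_universe), stats::rpois(1L, config$artifact_snv_rate))]
      art_n <- art_universe[sample.int(
        length(art_universe), stats::rpois(1L, config$artifact_snv_rate))]

      ## --- homopolymer indels (per tissue) ---
      mk_indels <- function(n) {
        if (n == 0L || nrow(runs) == 0L) return(NULL)
        ri <- sample(nrow(runs), min(n, nrow(runs)))
        ins <- stats::runif(length(ri)) < 0.5
        data.frame(
          chrom = runs$chrom[ri], pos = runs$pos[ri],
          ref = ifelse(ins, runs$base[ri],
                       paste0(runs$base[ri], runs$base[ri])),
          alt = ifelse(ins, paste0(runs$base[ri], runs$base[ri]),
                       runs$base[ri]),
          stringsAsFactors = FALSE)
      }
      ind_t <- mk_indels(stats::rpois(1L, config$homopolymer_indel_rate))
      ind_n <- mk_indels(stats::rpois(1L, config$homopolymer_indel_rate))

      mk <- function(rows, tissue, truth, genotype) {
        if (length(rows) == 0L) return(empty_calls())
        data.frame(chrom = sites$chrom[rows], pos = sites$pos[rows],
                   ref = sites$ref[rows], alt = sites$alt[rows],
                   patient = pid, tissue = tissue, read_support = 0L,
                   flags = "", joint_flag = NA_character_,
                   genotype = genotype, truth = truth,
                   stringsAsFactors = FALSE)
      }
      calls <- rbind(
        mk(g_rows, "tumor", "germline", g_geno),
        mk(g_rows, "normal", "germline", g_geno),
        mk(som_rows, "tumor", "somatic", "het"),
        mk(art_t, "tumor", "artifact", "het"),
        mk(art_n, "normal", "artifact", "het"))
      mk_ind <- function(df, tissue) {
        if (is.null(df)) return(empty_calls())
        data.frame(df, patient = pid, tissue = tissue, read_support = 0L,
                   flags = "", joint_flag = NA_character_, genotype = "het",
                   truth = "artifact", stringsAsFactors = FALSE)
      }
      calls <- rbind(calls, mk_ind(ind_t, "tumor"), mk_ind(ind_n, "normal"))

      ## read support per call; quality flags per variant site (flags are
      ## locus properties, so tumor and normal of a patient agree)
      calls$read_support <- draw_read_support(nrow(calls),
                                              config$read_support)
      ckey <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)
      uk <- unique(ckey)
      site_flags <- draw_flags(length(uk), config$artifact_flag_rate)
      names(site_flags) <- uk
      art_keys <- unique(ckey[calls$truth == "artifact" &
                                nchar(calls$ref) == 1L &
                                nchar(calls$alt) == 1L])
      # spurious SNV calls must be distinguishable: force at least one flag
      force_flag <- art_keys[site_flags[art_keys] == ""]
      site_flags[force_flag] <- sample(FLAG_VOCABULARY, length(force_flag),
                                       replace = TRUE)
      # homopolymer indels predominantly read-quality flagged
      ind_keys <- unique(ckey[nchar(calls$ref) != nchar(calls$alt)])
      flag_ind <- ind_keys[stats::runif(length(ind_keys)) < 0.8]
      site_flags[flag_ind] <- ifelse(site_flags[flag_ind] == "", "badReads",
                                     paste0(site_flags[flag_ind],
                                            ";badReads"))
      calls$flags <- unname(site_flags[ckey])
      calls
    })
  })
  calls <- do.call(rbind, per_patient)

  ## deduplicate per sample (the same site can be drawn twice, e.g. via the
  ## shared germline pool); truth categories live on disjoint site subsets,
  ## so labels partition the calls by construction
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)
  calls <- calls[!duplicated(paste(calls$patient, calls$tissue, key)), ,
                 drop = FALSE]
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)

  ## joint-genotyping flags are a property of the variant site
  ukeys <- unique(key)
  jf <- with_seed(child_seed(config$seed, 999983L), {
    hit <- stats::runif(length(ukeys)) < config$joint_flag_rate
    stats::setNames(ifelse(hit, sample(FLAG_VOCABULARY, length(ukeys),
                                       replace = TRUE), NA_character_),
                    ukeys)
  })
  calls$joint_flag <- unname(jf[key])

  ord <- order(calls$patient, calls$tissue, calls$chrom, calls$pos, calls$alt)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL

  structure(list(
    calls = calls,
    patients = data.frame(patient = patients, vital_status = unname(vital),
                          stringsAsFactors = FALSE),
    truth = list(exposures = config$signature_exposures,
                 burden_effects = config$burden_effects,
                 label_counts = table(calls$truth)),
    genome = genome, config = config), class = "cohort_sim")
}

# sample() protection against the length-1 scalar expansion
resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

#' @export
print.cohort_sim <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$patients), "tumor-normal pairs,",
      nrow(x$calls), "emitted calls\n")
  print(x$truth$label_counts)
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits one VCF v4.2 per sample (named `{patient}_{tumor|normal}.vcf`),
#' the truth record as TSV + JSON, and the patient vital-status table.
#'
#' @param cohort a `cohort_sim`.
#' @param dir output directory.
#' @return invisibly, the vector of written VCF paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (pid in cohort$patients$patient) {
    for (tis in c("tumor", "normal")) {
      sub <- cohort$calls[cohort$calls$patient == pid &
                            cohort$calls$tissue == tis, , drop = FALSE]
      path <- file.path(dir, paste0(pid, "_", tis, ".vcf"))
      write_calls_vcf(sub, path, sample_name = paste0(pid, "_", tis),
                      genome = cohort$genome)
      paths <- c(paths, path)
    }
  }
  truth <- cohort$calls[, c("patient", "tissue", "chrom", "pos", "ref",
                            "alt", "truth")]
  utils::write.table(truth, file.path(dir, "truth_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$patients, file.path(dir, "patients.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_json <- list(
    label_counts = as.list(cohort$truth$label_counts),
    burden_effects = as.list(cohort$truth$burden_effects),
    exposures = apply(cohort$truth$exposures, 1L, function(r)
      as.list(r[r > 0]), simplify = FALSE))
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
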