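# End-to-end orchestration: simulate -> filter -> annotate -> burden ->
# dN/dS -> signatures -> enrichment -> external validation, under one
# validated configuration, with a machine-readable run report.

#' Build a pipeline run configuration
#'
#' @param out_dir output directory for all artifacts.
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "filter", "annotate", "burden", "dnds", "signatures",
#'   "enrich", "validate_external")`.
#' @param genome_dir directory with `genome.fa` + `genes.tsv` (required
#'   when `vcf_dir` is given; otherwise a toy genome is generated).
#' @param vcf_dir directory of per-sample call files; when `NULL` the
#'   `simulate` stage must be enabled and generates them.
#' @param labels_path TSV of `patient`, `vital_status`; defaults to the
#'   simulator's truth labels when simulating.
#' @param catalog_path signature catalog TSV; defaults to the built-in
#'   synthetic catalog.
#' @param gmt_path GMT library (required when `enrich` is enabled).
#' @param universe_path optional universe file for enrichment.
#' @param external_counts_path external per-gene count TSV (+ `.yaml`
#'   sidecar) for the validation stage.
#' @param simulate_params list passed to [cohort_config()].
#' @param genome_params list with `n_genes`, `mean_cds_length`, `seed`.
#' @param alpha burden prioritization level.
#' @param signature_threshold select-and-refit minimum exposure.
#' @param n_boot bootstrap resamples for signature fitting.
#' @param n_subsamples,size_range subsampling sensitivity settings.
#' @param seed master seed for all stage streams.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(out_dir,
                            stages = c("simulate", "filter", "annotate",
                                       "burden", "dnds", "signatures"),
                            genome_dir = NULL, vcf_dir = NULL,
                            labels_path = NULL, catalog_path = NULL,
                            gmt_path = NULL, universe_path = NULL,
                            external_counts_path = NULL,
                            simulate_params = list(),
                            genome_params = list(n_genes = 100L,
                                                 mean_cds_length = 900L,
                                                 seed = 1L),
                            alpha = 0.05, signature_threshold = 0.05,
                            n_boot = 1000L, n_subsamples = 71000L,
                            size_range = c(30L, 100L), seed = 1L) {
  structure(list(out_dir = out_dir, stages = stages,
                 genome_dir = genome_dir, vcf_dir = vcf_dir,
                 labels_path = labels_path, catalog_path = catalog_path,
                 gmt_path = gmt_path, universe_path = universe_path,
                 external_counts_path = external_counts_path,
                 simulate_params = simulate_params,
                 genome_params = genome_params, alpha = alpha,
                 signature_threshold = signature_threshold,
                 n_boot = n_boot, n_subsamples = n_subsamples,
                 size_range = size_range, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the [pipeline_config()] arguments.
#'   Relative paths are resolved against the YAML file's directory.
#' @return a `run_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix_path <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  }
  for (key in c("genome_dir", "vcf_dir", "labels_path", "catalog_path",
                "gmt_path", "universe_path", "external_counts_path")) {
    y[[key]] <- fix_path(y[[key]])
  }
  if (is.null(y$out_dir)) stop("config must set out_dir")
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

KNOWN_STAGES <- c("simulate", "filter", "annotate", "burden", "dnds",
                  "signatures", "enrich", "validate_external")

#' Validate a pipeline configuration
#'
#' Checks stage names, stage dependencies and referenced paths without
#' mutating any state.  An empty return value means [run_pipeline()]'s
#' preconditions hold.
#'
#' @param config a `run_config`.
#' @return character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(p) problems <<- c(problems, p)
  st <- config$stages
  unknown <- setdiff(st, KNOWN_STAGES)
  if (length(unknown)) {
    add(paste0("unknown stage(s): ", paste(unknown, collapse = ", ")))
  }
  if ("filter" %in% st && !("simulate" %in% st) && is.null(config$vcf_dir)) {
    add("stage 'filter' enabled but neither 'simulate' nor vcf_dir provides calls")
  }
  for (s in c("annotate", "signatures")) {
    if (s %in% st && !("filter" %in% st)) {
      add(sprintf("stage '%s' requires stage 'filter'", s))
    }
  }
  for (s in c("burden", "dnds")) {
    if (s %in% st && !("annotate" %in% st)) {
      add(sprintf("stage '%s' requires stage 'annotate'", s))
    }
  }
  if ("enrich" %in% st) {
    if (!("burden" %in% st)) add("stage 'enrich' requires stage 'burden'")
    if (is.null(config$gmt_path)) {
      add("stage 'enrich' enabled but 'gmt_path' is not set")
    } else if (!file.exists(config$gmt_path)) {
      add(paste0("gmt_path does not exist: ", config$gmt_path))
    }
  }
  if ("validate_external" %in% st) {
    if (is.null(config$external_counts_path)) {
      add("stage 'validate_external' enabled but 'external_counts_path' is not set")
    } else if (!file.exists(config$external_counts_path)) {
      add(paste0("external_counts_path does not exist: ",
                 config$external_counts_path))
    }
  }
  if (!is.null(config$vcf_dir) && !dir.exists(config$vcf_dir)) {
    add(paste0("vcf_dir does not exist: ", config$vcf_dir))
  }
  for (key in c("labels_path", "catalog_path", "universe_path")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p)) {
      add(paste0(key, " does not exist: ", p))
    }
  }
  if (!is.null(config$genome_dir) &&
      !file.exists(file.path(config$genome_dir, "genome.fa"))) {
    add(paste0("genome_dir lacks genome.fa: ", config$genome_dir))
  }
  problems
}

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in dependency order, writes every artifact
#' atomically under `config$out_dir`, and returns (and serialises) a run
#' report with the filter funnel, inflation factor, prioritized gene count,
#' dN/dS summary, selected signatures and top enrichment terms.  Rerunning
#' with an identical configuration reproduces all artifacts.
#'
#' @param config a `run_config` (see [pipeline_config()] /
#'   [read_pipeline_config()]).
#' @return the run report, invisibly (also written to
#'   `out_dir/run_report.json`).
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  report <- list(package_version =
                   as.character(utils::packageVersion("exomeburden")),
                 stages = st, seed = config$seed,
                 config_hash = config_hash(config))
  if (length(st) == 0L) {
    write_atomic(function(p) jsonlite::write_json(report, p,
                                                  auto_unbox = TRUE,
                                                  digits = NA, pretty = TRUE),
                 file.path(out, "run_report.json"))
    return(invisible(report))
  }

  ## genome
  genome <- if (!is.null(config$genome_dir)) {
    read_genome(config$genome_dir)
  } else {
    gp <- config$genome_params
    build_toy_exome(gp$n_genes, gp$mean_cds_length,
                    seed = if (is.null(gp$seed)) config$seed else gp$seed)
  }
  if (is.null(config$genome_dir)) write_genome(genome, file.path(out, "genome"))

  catalog <- if (!is.null(config$catalog_path)) {
    read_signature_catalog(config$catalog_path)
  } else {
    synthetic_signature_catalog()
  }

  ## calls + labels
  labels <- NULL
  cohort <- NULL
  if ("simulate" %in% st) {
    sp <- config$simulate_params
    sp$catalog <- catalog
    if (is.null(sp$seed)) sp$seed <- config$seed
    cfg <- do.call(cohort_config, sp)
    sim <- simulate_cohort(genome, cfg)
    write_cohort(sim, file.path(out, "calls"))
    cohort <- as_call_cohort(sim$calls[, setdiff(names(sim$calls), "truth")])
    labels <- sim$patients
    report$simulate <- list(n_patients = nrow(sim$patients),
                            emitted_calls = nrow(sim$calls),
                            truth_labels = as.list(sim$truth$label_counts))
  } else if (!is.null(config$vcf_dir)) {
    cohort <- parse_calls(config$vcf_dir)
  }
  if (!is.null(config$labels_path)) {
    labels <- utils::read.table(config$labels_path, sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  }

  somatic <- NULL
  if ("filter" %in% st) {
    somatic <- refine_somatic(cohort)
    write_atomic(function(p) write_somatic_tsv(somatic, p),
                 file.path(out, "somatic_snvs.tsv"))
    write_atomic(function(p) write_funnel_report(somatic, p),
                 file.path(out, "filter_funnel.json"))
    report$filter_funnel <- as.list(attr(somatic, "funnel"))
  }

  annotated <- NULL
  if ("annotate" %in% st) {
    annotated <- annotate_variants(somatic, genome)
    write_atomic(function(p) utils::write.table(
      annotated[, c("patient", "chrom", "pos", "ref", "alt", "gene_id",
                    "element", "coding_effect")],
      p, sep = "\t", quote = FALSE, row.names = FALSE),
      file.path(out, "somatic_annotated.tsv"))
    report$annotate <- list(
      n_variants = nrow(annotated),
      exonic_fraction = mean(annotated$element == "exonic"))
  }

  if ("burden" %in% st) {
    if (is.null(labels)) stop("burden stage requires patient labels")
    fit <- burden_test(annotated, labels, alpha = config$alpha)
    write_atomic(function(p) utils::write.table(fit$results, p, sep = "\t",
                                                quote = FALSE,
                                                row.names = FALSE),
                 file.path(out, "burden_ranked.tsv"))
    write_atomic(function(p) utils::write.table(
      data.frame(expected = fit$inflation$expected,
                 observed = fit$inflation$observed),
      p, sep = "\t", quote = FALSE, row.names = FALSE),
      file.path(out, "burden_qq.tsv"))
    report$burden <- list(n_genes = nrow(fit$results),
                          n_prioritized = sum(fit$results$prioritized),
                          lambda = fit$inflation$lambda,
                          min_p = min(fit$results$p_value),
                          top_gene = fit$results$gene_id[1])
    prioritized <- fit$results$gene_id[fit$results$prioritized]
  }

  if ("dnds" %in% st) {
    som1 <- exclude_recurrent(annotated)
    dnds <- estimate_dnds(som1, genome)
    write_atomic(function(p) write_dnds_tsv(dnds, p),
                 file.path(out, "dnds.tsv"))
    ex <- dnds$exome[dnds$exome$scope == "all", ]
    report$dnds <- list(ratio_all = ex$ratio, ci = c(ex$ci_lo, ex$ci_hi),
                        p_value = ex$p_value,
                        n_recurrent_removed =
                          attr(som1, "n_recurrent_removed"),
                        collapsed = dnds$collapsed)
  }

  if ("signatures" %in% st) {
    spectra <- spectrum_96(somatic, genome, by_patient = TRUE)
    write_atomic(function(p) utils::write.table(
      data.frame(context = rownames(spectra), spectra, check.names = FALSE),
      p, sep = "\t", quote = FALSE, row.names = FALSE),
      file.path(out, "spectra_96.tsv"))
    # cohort-pooled two-stage fit + per-tumor exposures over the selection
    pooled <- rowSums(spectra)
    fit2 <- select_and_refit(pooled, catalog,
                             threshold = config$signature_threshold,
                             n_boot = config$n_boot,
                             seed = child_seed(config$seed, 11L))
    sel <- names(fit2$selected)[fit2$selected]
    sub <- catalog[, sel, drop = FALSE]
    class(sub) <- class(catalog)
    per_tumor <- lapply(colnames(spectra), function(s) {
      f <- fit_exposures(spectra[, s], sub, n_boot = config$n_boot,
                         seed = child_seed(config$seed, 12L))
      data.frame(tumor = s, signature = names(f$weights),
                 weight = as.numeric(f$weights),
                 lo = as.numeric(f$lower), hi = as.numeric(f$upper),
                 selected = TRUE, stringsAsFactors = FALSE)
    })
    write_atomic(function(p) utils::write.table(
      do.call(rbind, per_tumor), p, sep = "\t", quote = FALSE,
      row.names = FALSE), file.path(out, "signature_exposures.tsv"))
    report$signatures <- list(selected = sel,
                              pooled_weights = as.list(round(fit2$weights, 4)))
  }

  if ("enrich" %in% st) {
    lib <- load_gmt(config$gmt_path, universe = config$universe_path)
    er <- enrich(prioritized, lib, alpha = config$alpha)
    write_atomic(function(p) write_enrichment_tsv(er, p),
                 file.path(out, "enrichment.tsv"))
    sens <- subsample_sensitivity(
      prioritized, lib, n_subsamples = config$n_subsamples,
      size_range = config$size_range, alpha = config$alpha,
      seed = child_seed(config$seed, 13L))
    write_atomic(function(p) write_enrichment_tsv(sens, p),
                 file.path(out, "enrichment_sensitivity.tsv"))
    report$enrich <- list(
      top_terms = utils::head(er$set, 3),
      top_adjusted_p = utils::head(er$adjusted_p, 3),
      stability = as.list(round(sens$proportions, 4)))
  }

  if ("validate_external" %in% st) {
    ext <- read_external_counts(config$external_counts_path)
    efit <- external_burden_test(ext$counts, ext$totals,
                                 alpha = config$alpha)
    write_atomic(function(p) utils::write.table(efit$results, p,
                                                sep = "\t", quote = FALSE,
                                                row.names = FALSE),
                 file.path(out, "external_validation.tsv"))
    report$validate_external <- list(
      n_genes = nrow(efit$results),
      n_significant = sum(efit$results$prioritized))
  }

  write_atomic(function(p) jsonlite::write_json(report, p,
                                                auto_unbox = TRUE,
                                                digits = NA, pretty = TRUE),
               file.path(out, "run_report.json"))
  invisible(report)
}

# md5 of the canonicalised configuration; path-valued fields are excluded
# so the hash identifies the analysis settings, not the filesystem layout
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  path_keys <- c("out_dir", "genome_dir", "vcf_dir", "labels_path",
                 "catalog_path", "gmt_path", "universe_path",
                 "external_counts_path")
  cfg <- config[setdiff(names(config), path_keys)]
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
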