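# Hypergeometric gene-set enrichment with subsampling sensitivity.
#
# Overlap-based enrichment of a prioritized gene list against a local GMT
# library: upper-tail hypergeometric p per set, Benjamini-Hochberg
# adjustment across the library, and a stability analysis that re-runs the
# enrichment on many random subsets of the query.

#' Load a GMT gene-set library
#'
#' GMT format: one set per line — set name, description, then tab-separated
#' member genes.  Identifiers are uppercased and duplicates within a set are
#' removed.  The background universe defaults to the union of all sets.
#'
#' @param path GMT file path.
#' @param universe optional explicit universe (character vector, or a file
#'   with one gene per line); the recommended setting is all genes carrying
#'   at least one somatic variant.
#' @return a `geneset_library`: list with `sets` (named list of character
#'   vectors) and `universe`.
#' @export
load_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(sprintf("%s line %d: expected at least 3 tab-separated fields",
                   path, i))
    }
    members <- unique(toupper(f[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop(sprintf("%s line %d: set '%s' has no members", path, i, f[1]))
    }
    sets[[f[1]]] <- members
  }
  geneset_library(sets, universe)
}

#' Construct a gene-set library from a named list
#'
#' @param sets named list of character vectors of gene ids.
#' @param universe optional universe; defaults to the union of the sets.
#'   Sets are harmonised (uppercased, deduplicated) and clipped to the
#'   universe.
#' @return a `geneset_library`.
#' @export
geneset_library <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("all gene sets must be named")
  }
  sets <- lapply(sets, function(s) unique(toupper(s)))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    if (length(universe) == 1L && file.exists(universe)) {
      universe <- readLines(universe)
    }
    universe <- sort(unique(toupper(trimws(universe))))
    universe <- universe[nzchar(universe)]
    sets <- lapply(sets, intersect, y = universe)
  }
  if (any(lengths(sets) == 0L)) {
    stop("set(s) empty after harmonisation: ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  }
  structure(list(sets = sets, universe = universe),
            class = "geneset_library")
}

#' @export
print.geneset_library <- function(x, ...) {
  cat("Gene-set library:", length(x$sets), "sets over a universe of",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Hypergeometric gene-set enrichment
#'
#' For each library set, the p-value is the probability of observing at
#' least the observed overlap when `|query|` genes are drawn from the
#' universe without replacement; adjusted p-values are Benjamini-Hochberg
#' across all sets in the library.
#'
#' @param query character vector of gene ids (uppercased internally).
#' @param library a `geneset_library`.
#' @param alpha significance level used for the `significant` flag on
#'   adjusted p-values.
#' @return an `enrich_result` data frame, sorted by adjusted then raw p:
#'   columns `set`, `overlap`, `set_size`, `query_size`, `universe_size`,
#'   `p_value`, `adjusted_p`, `significant`, `overlap_genes`.
#' @export
enrich <- function(query, library, alpha = 0.05) {
  stopifnot(inherits(library, "geneset_library"))
  q <- intersect(unique(toupper(query)), library$universe)
  if (length(q) == 0L) {
    stop("query has no genes in the library universe")
  }
  U <- length(library$universe)
  k <- length(q)
  rows <- lapply(names(library$sets), function(nm) {
    s <- library$sets[[nm]]
    ov <- intersect(q, s)
    m <- length(s)
    p <- stats::phyper(length(ov) - 1L, m, U - m, k, lower.tail = FALSE)
    data.frame(set = nm, overlap = length(ov), set_size = m,
               query_size = k, universe_size = U, p_value = p,
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$adjusted_p < alpha
  out <- out[order(out$adjusted_p, out$p_value, out$set), ,
             drop = FALSE]
  rownames(out) <- NULL
  out <- out[, c("set", "overlap", "set_size", "query_size",
                 "universe_size", "p_value", "adjusted_p", "significant",
                 "overlap_genes")]
  class(out) <- c("enrich_result", "data.frame")
  out
}

#' @export
print.enrich_result <- function(x, n = 10, ...) {
  cat("Gene-set enrichment:", nrow(x), "sets;",
      sum(x$significant), "significant after BH\n")
  df <- utils::head(as.data.frame(x)[, c("set", "overlap", "set_size",
                                         "p_value", "adjusted_p")], n)
  df$p_value <- signif(df$p_value, 3)
  df$adjusted_p <- signif(df$adjusted_p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Subsampling sensitivity of enrichment results
#'
#' Re-runs the enrichment on `n_subsamples` random subsets of the query
#' (sizes uniform over `size_range`, clamped to the query size; genes drawn
#' without replacement) and records, per set, the proportion of subsamples
#' in which the set is significant in the adjusted test — the paper-style
#' stability check on a prioritized gene list, with a per-size breakdown.
#'
#' @param query character vector of prioritized genes.
#' @param library a `geneset_library`.
#' @param n_subsamples number of random subsets (default 71000).
#' @param size_range integer two-vector `(lo, hi)` of subset sizes
#'   (default `c(30, 100)`).
#' @param alpha adjusted-significance level (default 0.05).
#' @param seed integer seed; the report is deterministic given it.
#' @return a `sensitivity_report`: list with `proportions` (named, per
#'   set), `by_size` (sets x sizes proportion matrix), `size_counts`,
#'   `n_subsamples`, `size_range`, `alpha`.
#' @export
subsample_sensitivity <- function(query, library, n_subsamples = 71000L,
                                  size_range = c(30L, 100L), alpha = 0.05,
                                  seed = 1L) {
  stopifnot(inherits(library, "geneset_library"))
  if (n_subsamples < 1L) stop("'n_subsamples' must be >= 1")
  lo <- as.integer(size_range[1]); hi <- as.integer(size_range[2])
  if (lo < 1L || hi < lo) stop("invalid 'size_range'")
  q <- intersect(unique(toupper(query)), library$universe)
  if (length(q) == 0L) stop("query has no genes in the library universe")
  if (lo > length(q)) stop("'size_range' lower bound exceeds the query size")
  hi <- min(hi, length(q))

  set_names <- names(library$sets)
  sizes_all <- lo:hi
  with_seed(seed, {
    sizes <- sizes_all[sample.int(length(sizes_all), n_subsamples,
                                  replace = TRUE)]
    sig <- matrix(FALSE, nrow = length(set_names), ncol = n_subsamples,
                  dimnames = list(set_names, NULL))
    # precompute set membership for speed
    U <- length(library$universe)
    m <- lengths(library$sets)
    memb <- lapply(library$sets, function(s) q %in% s)
    for (b in seq_len(n_subsamples)) {
      pick <- sample.int(length(q), sizes[b])
      ov <- vapply(memb, function(ms) sum(ms[pick]), integer(1))
      p <- stats::phyper(ov - 1L, m, U - m, sizes[b], lower.tail = FALSE)
      sig[, b] <- stats::p.adjust(p, method = "BH") < alpha
    }
    by_size <- vapply(sizes_all, function(s) {
      cols <- sizes == s
      if (!any(cols)) rep(NA_real_, length(set_names)) else
        rowMeans(sig[, cols, drop = FALSE])
    }, numeric(length(set_names)))
    by_size <- matrix(by_size, nrow = length(set_names),
                      dimnames = list(set_names, as.character(sizes_all)))
    structure(list(proportions = rowMeans(sig),
                   by_size = by_size,
                   size_counts = stats::setNames(
                     vapply(sizes_all, function(s) sum(sizes == s),
                            integer(1)), as.character(sizes_all)),
                   n_subsamples = as.integer(n_subsamples),
                   size_range = c(lo, hi), alpha = alpha),
              class = "sensitivity_report")
  })
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Subsampling sensitivity:", x$n_subsamples, "subsets of size",
      paste(x$size_range, collapse = "-"), "at alpha =", x$alpha, "\n")
  print(round(sort(x$proportions, decreasing = TRUE), 3))
  invisible(x)
}

#' Write enrichment / sensitivity results as TSV
#'
#' @param x an `enrich_result` or `sensitivity_report`.
#' @param path output path.
#' @export
write_enrichment_tsv <- function(x, path) {
  if (inherits(x, "sensitivity_report")) {
    df <- data.frame(set = names(x$proportions),
                     proportion_significant = as.numeric(x$proportions),
                     x$by_size, check.names = FALSE,
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(x)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
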