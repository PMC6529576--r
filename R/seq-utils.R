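# Low-level sequence machinery shared by the simulator, the consequence
# annotator, the dN/dS opportunity counter and the 96-context spectra.

BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")

# Standard nuclear genetic code (NCBI translation table 1), "*" = stop.
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

SENSE_CODONS <- names(CODON_TABLE)[CODON_TABLE != "*"]

#' Complement and reverse-complement of base strings
#'
#' Vectorised over character vectors; only bases A, C, G and T are handled.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @keywords internal
#' @noRd
complement_bases <- function(x) chartr("ACGT", "TGCA", x)

#' @noRd
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(complement_bases(s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# The 96 trinucleotide mutation classes, pyrimidine-normalised, ordered
# lexicographically by (substitution type, 5' base, 3' base).  This ordering
# is the row order of all spectrum and catalog files written by the package.
SUBSTITUTION_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

CONTEXT96_LABELS <- local({
  grid <- expand.grid(three = BASES, five = BASES, type = SUBSTITUTION_TYPES,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$type, SUBSTITUTION_TYPES), grid$five,
                     grid$three), ]
  paste0(grid$five, "[", grid$type, "]", grid$three)
})

#' Map SNVs to 96-context class indices
#'
#' Purine-reference substitutions are reverse-complemented (substitution and
#' both flanking bases) so that the reference base of the reported class is
#' always a pyrimidine, the convention used for COSMIC-style signature
#' catalogs.
#'
#' @param ref,alt single reference/alternate bases (vectorised).
#' @param five,three the bases immediately 5' and 3' of the variant on the
#'   reference (plus) strand.
#' @return integer vector of class indices in `1:96`, named by class label.
#' @keywords internal
#' @noRd
context96_index <- function(ref, alt, five, three) {
  stopifnot(length(ref) == length(alt), length(five) == length(ref),
            length(three) == length(ref))
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, complement_bases(ref), ref)
  a <- ifelse(flip, complement_bases(alt), alt)
  f <- ifelse(flip, complement_bases(three), five)
  t3 <- ifelse(flip, complement_bases(five), three)
  type <- paste0(r, ">", a)
  ti <- match(type, SUBSTITUTION_TYPES)
  fi <- match(f, BASES)
  gi <- match(t3, BASES)
  bad <- is.na(ti) | is.na(fi) | is.na(gi)
  if (any(bad)) {
    stop("cannot classify substitution(s): ",
         paste(unique(paste0(five, "[", ref, ">", alt, "]", three)[bad]),
               collapse = ", "))
  }
  idx <- (ti - 1L) * 16L + (fi - 1L) * 4L + gi
  names(idx) <- CONTEXT96_LABELS[idx]
  idx
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so callers' RNG streams are untouched.
#'
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stream child seed from a master seed; fixed multiplier keeps
# streams disjoint in practice and the result inside 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) + 7919 * as.double(index)) %% 2147483646 + 1)
}

#' @noRd
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Translate codons with the built-in standard code
#' @keywords internal
#' @noRd
translate_codons <- function(codons) {
  aa <- CODON_TABLE[codons]
  if (anyNA(aa)) stop("non-ACGT codon encountered")
  unname(aa)
}
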