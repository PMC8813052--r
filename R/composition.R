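#' Kyte-Doolittle hydropathy scale
#'
#' The original per-residue hydrophobicity constants, embedded verbatim so
#' tests and documentation can reference a single table. Range -4.5 (Arg)
#' to +4.5 (Ile); Phe = 2.8, Leu = 3.8.
#'
#' @format Named numeric vector over [AA_ALPHABET].
#' @export
KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

#' Amino-acid composition of a sequence
#'
#' Fractions are counts / length over the full 20-letter alphabet (zeros
#' included), in the fixed column order of [AA_ALPHABET].
#'
#' @param record A `protein_record` or string.
#' @return An object of class `composition_profile`: list with `fractions`
#'   (named 20-vector summing to 1) and `length`.
#' @examples
#' aa_composition("ACDE")$fractions[c("A", "C", "D", "E")]
#' @export
aa_composition <- function(record) {
  chars <- seq_chars(record)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  fractions <- as.numeric(counts) / length(chars)
  names(fractions) <- AA_ALPHABET
  structure(
    list(fractions = fractions, length = length(chars)),
    class = "composition_profile"
  )
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("<composition_profile> length", x$length, "\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Composition matrix for a set of sequences
#'
#' One row per record, columns in [AA_ALPHABET] order, plus heatmap-style
#' flag columns: `max_fraction` and `flagged` (any amino-acid fraction
#' above `flag_threshold`, the "highly enriched residue" category).
#'
#' @param records Non-empty list of `protein_record` (or strings).
#' @param flag_threshold Enrichment flag cutoff (default 0.15).
#' @return A data.frame: 20 fraction columns, `max_fraction`, `flagged`;
#'   row names are record ids.
#' @export
composition_matrix <- function(records, flag_threshold = 0.15) {
  if (inherits(records, "protein_record")) records <- list(records)
  if (length(records) == 0L) stop("composition_matrix needs >= 1 record")
  records <- lapply(records, as_protein_record)
  m <- t(vapply(
    records, function(r) aa_composition(r)$fractions, numeric(20L)
  ))
  rownames(m) <- vapply(records, `[[`, "", "id")
  df <- as.data.frame(m)
  df$max_fraction <- apply(m, 1L, max)
  df$flagged <- df$max_fraction > flag_threshold
  df
}

#' Write a composition matrix as TSV
#'
#' Header row of one-letter codes plus the flag columns; row names emitted
#' as a leading `id` column.
#'
#' @param mat Result of [composition_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(mat, path) {
  out <- cbind(id = rownames(mat), mat)
  utils::write.table(
    out, path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Shannon sequence complexity (informational entropy)
#'
#' Natural-log Shannon entropy of the amino-acid frequency distribution,
#' `-sum(p * ln p)` over residues with `p > 0`. Plug-in frequencies with
#' `0 * ln 0 = 0`; no pseudocounts or finite-sample correction. The
#' theoretical range is 0 to `ln(20)` (about 3.0), which fixes the
#' logarithm base as natural. Permutation-invariant by construction.
#'
#' @param record A `protein_record` or string.
#' @return Entropy in nats (single numeric).
#' @examples
#' shannon_complexity("AAAA") # 0
#' shannon_complexity(paste(AA_ALPHABET, collapse = "")) # ln(20)
#' @export
shannon_complexity <- function(record) {
  p <- aa_composition(record)$fractions
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mean Kyte-Doolittle hydropathy
#'
#' Arithmetic mean of [KD_HYDROPATHY] values over all residues.
#'
#' @param record A `protein_record` or string.
#' @return Mean hydropathy (single numeric in \[-4.5, 4.5\]).
#' @export
mean_hydropathy <- function(record) {
  mean(KD_HYDROPATHY[seq_chars(record)])
}

#' Fraction of residues belonging to a set
#'
#' E.g. `fraction_of_set(x, c("L", "I", "V"))` gives the
#' branched-hydrophobic content, `fraction_of_set(x, c("F", "W", "Y"))`
#' the aromatic content.
#'
#' @param record A `protein_record` or string.
#' @param residue_set Non-empty subset of [AA_ALPHABET].
#' @return Count of set residues divided by sequence length.
#' @export
fraction_of_set <- function(record, residue_set) {
  residue_set <- toupper(residue_set)
  stopifnot(length(residue_set) > 0L, all(residue_set %in% AA_ALPHABET))
  chars <- seq_chars(record)
  sum(chars %in% residue_set) / length(chars)
}

#' Per-amino-acid percent composition difference
#'
#' `100 * (query fraction - reference fraction)` for each amino acid; the
#' sign is positive where the query is enriched relative to the
#' reference (query minus reference).
#'
#' @param query,reference `composition_profile` objects (or records /
#'   strings, coerced via [aa_composition()]).
#' @return Named numeric 20-vector of signed percent differences.
#' @export
composition_percent_difference <- function(query, reference) {
  as_profile <- function(x) {
    if (inherits(x, "composition_profile")) x else aa_composition(x)
  }
  100 * (as_profile(query)$fractions - as_profile(reference)$fractions)
}
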