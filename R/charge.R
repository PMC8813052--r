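#' @rdname classify_charge
#' @export
CHARGE_POSITIVE <- c("K", "R")

#' @rdname classify_charge
#' @export
CHARGE_NEGATIVE <- c("D", "E")

#' Charge classification of residues
#'
#' The charge set is K, R (+1) and D, E (-1); every other residue,
#' including histidine, counts as neutral for FCR/NCPR/kappa. (Histidine
#' still ionizes in the isoelectric-point model, see
#' [isoelectric_point()].)
#'
#' @param residue Character vector of one-letter codes.
#' @return Integer vector over \{-1, 0, +1\}.
#' @examples
#' classify_charge(c("K", "E", "H")) # 1 -1 0
#' @export
classify_charge <- function(residue) {
  residue <- toupper(residue)
  bad <- setdiff(unique(residue), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("invalid residue code(s): ", paste(sQuote(bad), collapse = ", "))
  }
  ifelse(residue %in% CHARGE_POSITIVE, 1L,
    ifelse(residue %in% CHARGE_NEGATIVE, -1L, 0L)
  )
}

# internal: charge vector of a record
charge_vector <- function(record) classify_charge(seq_chars(record))

#' Fraction of charged residues (FCR)
#'
#' Count of K, R, D, E divided by sequence length.
#'
#' @param record A `protein_record` or string.
#' @return Numeric in \[0, 1\].
#' @export
fcr <- function(record) {
  ch <- charge_vector(record)
  sum(ch != 0L) / length(ch)
}

#' Net charge per residue (NCPR)
#'
#' (positives - negatives) / length, with the K/R/D/E charge set.
#'
#' @param record A `protein_record` or string.
#' @return Numeric in \[-1, 1\].
#' @export
ncpr <- function(record) {
  ch <- charge_vector(record)
  sum(ch) / length(ch)
}

#' Charge asymmetry (sigma)
#'
#' `sigma = ncpr^2 / fcr` when any charges are present, else 0.
#'
#' @param record A `protein_record` or string.
#' @return Numeric in \[0, 1\].
#' @export
charge_asymmetry <- function(record) {
  sigma_of_counts(charge_vector(record))
}

# sigma from an integer charge vector
sigma_of_counts <- function(ch) {
  n <- length(ch)
  fp <- sum(ch > 0L) / n
  fm <- sum(ch < 0L) / n
  f <- fp + fm
  if (f == 0) 0 else (fp - fm)^2 / f
}

# Vectorized per-blob sigma deviations for one blob size.
# Overlapping (sliding) windows; returns list(sigma_values, delta).
blob_deltas <- function(ch, g) {
  n <- length(ch)
  stopifnot(n >= g)
  cpos <- cumsum(c(0L, ch > 0L))
  cneg <- cumsum(c(0L, ch < 0L))
  i <- seq_len(n - g + 1L)
  fp <- (cpos[i + g] - cpos[i]) / g
  fm <- (cneg[i + g] - cneg[i]) / g
  f <- fp + fm
  sigma <- ifelse(f == 0, 0, (fp - fm)^2 / f)
  sg <- sigma_of_counts(ch)
  list(sigma_values = sigma, delta = mean((sigma - sg)^2))
}

# delta of an integer charge vector for blob size g
delta_of <- function(ch, g) blob_deltas(ch, g)$delta

# delta_max by the maximally segregated arrangement construction:
# candidate arrangements are the +/-/neutral blocks in all 6 orders, plus
# variants splitting the neutral block across both ends around adjacent
# charge blocks. Depends only on the composition counts, so results are
# memoised per (npos, nneg, nneu, g).
.dmax_cache <- new.env(parent = emptyenv())

delta_max_composition <- function(npos, nneg, nneu, g) {
  key <- paste(npos, nneg, nneu, g, sep = "_")
  hit <- .dmax_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- npos + nneg + nneu
  stopifnot(n >= g)
  P <- rep(1L, npos)
  M <- rep(-1L, nneg)
  N <- rep(0L, nneu)
  best <- 0
  blocks <- list(P, M, N)
  for (a in 1:3) for (b in 1:3) for (cc in 1:3) {
    if (length(unique(c(a, b, cc))) == 3L) {
      cand <- c(blocks[[a]], blocks[[b]], blocks[[cc]])
      best <- max(best, delta_of(cand, g))
    }
  }
  if (nneu > 0L && npos > 0L && nneg > 0L) {
    for (k in 0:nneu) {
      left <- rep(0L, k)
      right <- rep(0L, nneu - k)
      best <- max(best, delta_of(c(left, P, M, right), g))
      best <- max(best, delta_of(c(left, M, P, right), g))
    }
  }
  .dmax_cache[[key]] <- best
  best
}

#' Blob decomposition of a sequence's charge pattern
#'
#' Overlapping (sliding) windows of length `g`; per-blob sigma, the mean
#' squared deviation from global sigma (`delta`), and the `delta_max`
#' attained by the maximally segregated arrangement of the same
#' composition (charge blocks in all orders, with the neutral block
#' optionally split across both ends).
#'
#' @param record A `protein_record` or string.
#' @param g Blob size (5 or 6 in the kappa definition).
#' @return An object of class `blob_decomposition`: list with `blob_size`,
#'   `sigma_values` (length `n - g + 1`), `delta`, `delta_max`.
#' @export
blob_decompose <- function(record, g) {
  ch <- charge_vector(record)
  if (length(ch) < g) {
    stop("sequence shorter than blob size g = ", g)
  }
  bd <- blob_deltas(ch, g)
  dmax <- delta_max_composition(
    sum(ch > 0L), sum(ch < 0L), sum(ch == 0L), g
  )
  structure(
    list(
      blob_size = as.integer(g), sigma_values = bd$sigma_values,
      delta = bd$delta, delta_max = dmax
    ),
    class = "blob_decomposition"
  )
}

#' Das-Pappu kappa charge-patterning parameter
#'
#' Quantifies the degree of mixing of oppositely charged residues: the
#' mean of `delta / delta_max` over blob sizes 5 and 6 (see
#' [blob_decompose()]). Well-mixed sequences have low kappa; fully
#' segregated charge blocks give kappa = 1. Undefined (returned as `NA`
#' with a warning) when the sequence lacks either positive or negative
#' residues, since `delta_max = 0` there.
#'
#' @param record A `protein_record` or string of length >= 6.
#' @return Single numeric, or `NA_real_` when undefined.
#' @examples
#' kappa("EEEEEEKKKKKK") # 1
#' @export
kappa <- function(record) {
  ch <- charge_vector(record)
  if (length(ch) < 6L) stop("kappa requires sequence length >= 6")
  if (sum(ch > 0L) == 0L || sum(ch < 0L) == 0L) {
    warning("kappa undefined: sequence lacks one charge sign")
    return(NA_real_)
  }
  vals <- vapply(c(5L, 6L), function(g) {
    bd <- blob_decompose(record, g)
    # when the whole sequence is a single blob (n == g) every arrangement
    # has delta 0 and the ratio is degenerate; that blob size is skipped
    if (bd$delta_max == 0) NA_real_ else bd$delta / bd$delta_max
  }, numeric(1L))
  if (all(is.na(vals))) {
    warning("kappa undefined: degenerate blob decomposition")
    return(NA_real_)
  }
  mean(vals, na.rm = TRUE)
}

#' Ionizable-group pKa constants (Bjellqvist set)
#'
#' pKa values used by the isoelectric-point model: side chains D, E, C, Y
#' (acids) and H, K, R (bases) plus the free N- and C-termini. The set was
#' calibrated once against the printed wild-type Cdt1 IDR value (pI 10.1)
#' and then frozen; the commonly used EMBOSS values give 10.9 for the same
#' sequence and were rejected.
#'
#' @format Named numeric vector (pH units).
#' @export
PKA_SET <- c(
  Nterm = 7.5, Cterm = 3.55,
  K = 10.0, R = 12.0, H = 5.98,
  D = 4.05, E = 4.45, C = 9.0, Y = 10.0
)

# modeled net charge at a given pH (Henderson-Hasselbalch)
net_charge_at_ph <- function(counts, pH, include_termini = TRUE) {
  pos <- sum(vapply(
    c("K", "R", "H"),
    function(a) counts[[a]] / (1 + 10^(pH - PKA_SET[[a]])),
    numeric(1L)
  ))
  neg <- sum(vapply(
    c("D", "E", "C", "Y"),
    function(a) counts[[a]] / (1 + 10^(PKA_SET[[a]] - pH)),
    numeric(1L)
  ))
  if (include_termini) {
    pos <- pos + 1 / (1 + 10^(pH - PKA_SET[["Nterm"]]))
    neg <- neg + 1 / (1 + 10^(PKA_SET[["Cterm"]] - pH))
  }
  pos - neg
}

#' Isoelectric point
#'
#' The pH at which the modeled net charge crosses zero, found by bisection
#' on \[0, 14\] to `|charge| < 1e-4`. Side chains D, E, C, Y ionize as
#' acids and H, K, R as bases ([PKA_SET]); free termini are included by
#' default. The net-charge function is monotone decreasing in pH, so the
#' root is unique whenever any ionizable group is present.
#'
#' @param record A `protein_record` or string.
#' @param include_termini Include the free N/C termini (default `TRUE`).
#' @return pH units (single numeric), or `NA_real_` with a warning when
#'   the sequence has no ionizable groups and termini are excluded.
#' @export
isoelectric_point <- function(record, include_termini = TRUE) {
  chars <- seq_chars(record)
  counts <- as.list(table(factor(chars, levels = AA_ALPHABET)))
  ionizable <- sum(unlist(counts[c("K", "R", "H", "D", "E", "C", "Y")]))
  if (ionizable == 0L && !include_termini) {
    warning("pI undefined: no ionizable groups")
    return(NA_real_)
  }
  lo <- 0
  hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge_at_ph(counts, mid, include_termini)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-9) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' All charge metrics for one sequence
#'
#' Bundles f+, f-, FCR, NCPR, sigma, kappa and pI. `kappa_defined` flags
#' sequences lacking either charge sign (kappa is `NA` there).
#'
#' @param record A `protein_record` or string.
#' @return An object of class `charge_metrics` (also a one-row list);
#'   use [as.data.frame()] for a flat row.
#' @export
charge_metrics <- function(record) {
  record <- as_protein_record(record)
  ch <- charge_vector(record)
  n <- length(ch)
  f_plus <- sum(ch > 0L) / n
  f_minus <- sum(ch < 0L) / n
  defined <- f_plus > 0 && f_minus > 0 && n >= 6L
  k <- if (defined) kappa(record) else NA_real_
  structure(
    list(
      protein_id = record$id,
      f_plus = f_plus, f_minus = f_minus,
      fcr = f_plus + f_minus, ncpr = f_plus - f_minus,
      sigma = sigma_of_counts(ch),
      kappa = k, kappa_defined = defined,
      pI = isoelectric_point(record)
    ),
    class = "charge_metrics"
  )
}

#' @export
as.data.frame.charge_metrics <- function(x, ...) {
  data.frame(
    protein_id = x$protein_id, f_plus = x$f_plus, f_minus = x$f_minus,
    fcr = x$fcr, ncpr = x$ncpr, sigma = x$sigma, kappa = x$kappa,
    kappa_defined = x$kappa_defined, pI = x$pI,
    stringsAsFactors = FALSE
  )
}

#' @export
print.charge_metrics <- function(x, ...) {
  cat("<charge_metrics>", x$protein_id, "\n")
  print(round(unlist(x[c("f_plus", "f_minus", "fcr", "ncpr",
                         "sigma", "kappa", "pI")]), 4))
  invisible(x)
}
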