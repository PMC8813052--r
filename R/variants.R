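# Composition-preserving sequence variant designers and dotplot
# verification. All randomised designs are driven by an explicit seed
# through an isolated RNG state so package calls never perturb (or depend
# on) the caller's random stream.

#' BLOSUM62 substitution scores
#'
#' The standard 20x20 integer BLOSUM62 table (the default protein matrix
#' lineage of the classic dotplot tools), embedded as a documented
#' constant so dotplot scoring is self-contained. Rows and columns in
#' [AA_ALPHABET] order.
#'
#' @format Integer matrix, 20 x 20, dimnames = amino acids.
#' @export
BLOSUM62 <- local({
  m <- rbind(
    c(  4,   0,  -2,  -1,  -2,   0,  -2,  -1,  -1,  -1,  -1,  -2,  -1,  -1,  -1,   1,   0,   0,  -3,  -2),
    c(  0,   9,  -3,  -4,  -2,  -3,  -3,  -1,  -3,  -1,  -1,  -3,  -3,  -3,  -3,  -1,  -1,  -1,  -2,  -2),
    c( -2,  -3,   6,   2,  -3,  -1,  -1,  -3,  -1,  -4,  -3,   1,  -1,   0,  -2,   0,  -1,  -3,  -4,  -3),
    c( -1,  -4,   2,   5,  -3,  -2,   0,  -3,   1,  -3,  -2,   0,  -1,   2,   0,   0,  -1,  -2,  -3,  -2),
    c( -2,  -2,  -3,  -3,   6,  -3,  -1,   0,  -3,   0,   0,  -3,  -4,  -3,  -3,  -2,  -2,  -1,   1,   3),
    c(  0,  -3,  -1,  -2,  -3,   6,  -2,  -4,  -2,  -4,  -3,   0,  -2,  -2,  -2,   0,  -2,  -3,  -2,  -3),
    c( -2,  -3,  -1,   0,  -1,  -2,   8,  -3,  -1,  -3,  -2,   1,  -2,   0,   0,  -1,  -2,  -3,  -2,   2),
    c( -1,  -1,  -3,  -3,   0,  -4,  -3,   4,  -3,   2,   1,  -3,  -3,  -3,  -3,  -2,  -1,   3,  -3,  -1),
    c( -1,  -3,  -1,   1,  -3,  -2,  -1,  -3,   5,  -2,  -1,   0,  -1,   1,   2,   0,  -1,  -2,  -3,  -2),
    c( -1,  -1,  -4,  -3,   0,  -4,  -3,   2,  -2,   4,   2,  -3,  -3,  -2,  -2,  -2,  -1,   1,  -2,  -1),
    c( -1,  -1,  -3,  -2,   0,  -3,  -2,   1,  -1,   2,   5,  -2,  -2,   0,  -1,  -1,  -1,   1,  -1,  -1),
    c( -2,  -3,   1,   0,  -3,   0,   1,  -3,   0,  -3,  -2,   6,  -2,   0,   0,   1,   0,  -3,  -4,  -2),
    c( -1,  -3,  -1,  -1,  -4,  -2,  -2,  -3,  -1,  -3,  -2,  -2,   7,  -1,  -2,  -1,  -1,  -2,  -4,  -3),
    c( -1,  -3,   0,   2,  -3,  -2,   0,  -3,   1,  -2,   0,   0,  -1,   5,   1,   0,  -1,  -2,  -2,  -1),
    c( -1,  -3,  -2,   0,  -3,  -2,   0,  -3,   2,  -2,  -1,   0,  -2,   1,   5,  -1,  -1,  -3,  -3,  -2),
    c(  1,  -1,   0,   0,  -2,   0,  -1,  -2,   0,  -2,  -1,   1,  -1,   0,  -1,   4,   1,  -2,  -3,  -2),
    c(  0,  -1,  -1,  -1,  -2,  -2,  -2,  -1,  -1,  -1,  -1,   0,  -1,  -1,  -1,   1,   5,   0,  -2,  -2),
    c(  0,  -1,  -3,  -2,  -1,  -3,  -3,   3,  -2,   1,   1,  -3,  -2,  -2,  -3,  -2,   0,   4,  -3,  -1),
    c( -3,  -2,  -4,  -3,   1,  -2,  -2,  -3,  -3,  -2,  -1,  -4,  -4,  -2,  -3,  -3,  -2,  -3,  11,   2),
    c( -2,  -2,  -3,  -2,   3,  -3,   2,  -1,  -2,  -1,  -1,  -2,  -3,  -1,  -2,  -2,  -2,  -1,   2,   7)
  )
  dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
  storage.mode(m) <- "integer"
  m
})

# run expr with an isolated, seeded RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

design_result <- function(variant, parent, design_kind, seed, report) {
  structure(
    list(
      variant = variant, parent_id = as_protein_record(parent)$id,
      design_kind = design_kind, seed = seed, report = report
    ),
    class = "design_result"
  )
}

#' @export
print.design_result <- function(x, ...) {
  cat(
    "<design_result>", x$design_kind, "of", x$parent_id, "->",
    x$variant$id, "\n"
  )
  utils::str(x$report, give.attr = FALSE)
  invisible(x)
}

# multiset composition check
same_composition <- function(a, b) {
  identical(
    sort(seq_chars(a)), sort(seq_chars(b))
  )
}

#' Randomly scramble a sequence (composition-preserving null)
#'
#' Uniform random permutation of the residues (Fisher-Yates via
#' `sample.int`), seeded and reproducible. The report carries a
#' composition-identity check, kappa before/after and the dotplot match
#' count against the parent at the standard window/threshold, verifying
#' that no sequence motifs were inadvertently retained.
#'
#' @param record A `protein_record` or string.
#' @param seed Integer seed.
#' @param dotplot_window,dotplot_threshold Verification dotplot
#'   parameters (defaults 15 / 32).
#' @return A `design_result`; `$variant` is the scrambled record.
#' @export
scramble <- function(record, seed, dotplot_window = 15L,
                     dotplot_threshold = 32L) {
  record <- as_protein_record(record)
  chars <- seq_chars(record)
  perm <- with_seed(seed, sample.int(length(chars)))
  variant <- protein_record(
    paste0(record$id, "_scr", seed), paste(chars[perm], collapse = "")
  )
  kb <- suppressWarnings(if (nchar(record$sequence) >= 6L)
    kappa(record) else NA_real_)
  ka <- suppressWarnings(if (nchar(variant$sequence) >= 6L)
    kappa(variant) else NA_real_)
  nmatch <- if (nchar(record$sequence) >= dotplot_window) {
    nrow(dotplot(variant, record, dotplot_window, dotplot_threshold)$matches)
  } else NA_integer_
  design_result(
    variant, record, "scramble", seed,
    list(
      composition_identical = same_composition(variant, record),
      kappa_before = kb, kappa_after = ka,
      dotplot_match_count = nmatch
    )
  )
}

#' Ungapped dotplot of two sequences
#'
#' For every pair of window start positions the ungapped window score
#' under [BLOSUM62] (sum of per-position substitution scores, no gaps) is
#' computed; pairs scoring `>= threshold` are reported. The defaults
#' (window 15, threshold 32) are the classic repeat-finding settings.
#' Self-comparison of any natural sequence shows the full main diagonal;
#' off-diagonal matches indicate repetitive motifs.
#'
#' @param a,b `protein_record`s or strings, both at least `window` long.
#' @param window Window length.
#' @param threshold Integer score threshold.
#' @return An object of class `dotplot_result`: `window`, `threshold`,
#'   `matrix_name`, and `matches` (data.frame `pos_a`, `pos_b`, `score`
#'   of 1-based window starts).
#' @export
dotplot <- function(a, b, window = 15L, threshold = 32L) {
  a <- as_protein_record(a)
  b <- as_protein_record(b)
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  na <- length(ca)
  nb <- length(cb)
  if (na < window || nb < window) {
    stop("both sequences must be at least window = ", window, " long")
  }
  S <- BLOSUM62[ca, cb, drop = FALSE] # per-position score matrix
  hits <- vector("list", na + nb - 1L)
  h <- 0L
  # rolling window sums along every diagonal
  for (off in (-(na - window)):(nb - window)) {
    if (off >= 0L) {
      i0 <- 1L
      j0 <- 1L + off
    } else {
      i0 <- 1L - off
      j0 <- 1L
    }
    len <- min(na - i0 + 1L, nb - j0 + 1L)
    d <- S[cbind(i0 + 0:(len - 1L), j0 + 0:(len - 1L))]
    cs <- cumsum(c(0L, d))
    k <- seq_len(len - window + 1L)
    sc <- cs[k + window] - cs[k]
    ok <- sc >= threshold
    if (any(ok)) {
      h <- h + 1L
      hits[[h]] <- data.frame(
        pos_a = i0 + k[ok] - 1L, pos_b = j0 + k[ok] - 1L,
        score = as.integer(sc[ok])
      )
    }
  }
  matches <- if (h > 0L) do.call(rbind, hits[seq_len(h)]) else
    data.frame(pos_a = integer(), pos_b = integer(), score = integer())
  matches <- matches[order(matches$pos_a, matches$pos_b), , drop = FALSE]
  rownames(matches) <- NULL
  structure(
    list(
      window = as.integer(window), threshold = as.integer(threshold),
      matrix_name = "BLOSUM62", matches = matches,
      id_a = a$id, id_b = b$id
    ),
    class = "dotplot_result"
  )
}

#' @export
print.dotplot_result <- function(x, ...) {
  cat(
    "<dotplot_result>", x$id_a, "vs", x$id_b, "window", x$window,
    "threshold", x$threshold, ":", nrow(x$matches), "matches\n"
  )
  invisible(x)
}

#' Redistribute charged residues uniformly (kappa minimisation)
#'
#' Produces a permutation of the input in which only charged residues are
#' repositioned: neutral residues keep their relative order, charged
#' residues (K, R, D, E) are first placed at evenly spaced positions in
#' alternating sign order, then refined by seeded swap moves (charged
#' with charged, and charged with neutral positions) accepted only when
#' kappa decreases, until `kappa <= target_kappa` or `max_iter` moves
#' have been proposed. Composition, and hence FCR, entropy, hydropathy
#' and pI, are preserved exactly.
#'
#' @param record A `protein_record` or string containing both charge
#'   signs.
#' @param target_kappa Stop once kappa falls to this value (default 0.07).
#' @param seed Integer seed for the refinement moves.
#' @param max_iter Maximum number of proposed swaps (default 2000).
#' @return A `design_result`; `report$achieved` is `FALSE` when the
#'   target was unreachable within `max_iter` (best-found returned).
#' @export
design_uniform_charge <- function(record, target_kappa = 0.07, seed = 1L,
                                  max_iter = 2000L) {
  record <- as_protein_record(record)
  chars <- seq_chars(record)
  ch <- classify_charge(chars)
  n <- length(ch)
  if (sum(ch > 0L) == 0L || sum(ch < 0L) == 0L) {
    stop("uniform-charge design requires both charge signs")
  }
  kappa_before <- kappa(record)

  pos_res <- chars[ch > 0L]
  neg_res <- chars[ch < 0L]
  neu_res <- chars[ch == 0L]
  ncharged <- length(pos_res) + length(neg_res)
  # alternating sign order, longer sign padded at the end
  ord <- character(ncharged)
  pi_ <- 1L
  ni_ <- 1L
  take_pos <- length(pos_res) >= length(neg_res)
  for (t in seq_len(ncharged)) {
    if ((take_pos && pi_ <= length(pos_res)) || ni_ > length(neg_res)) {
      ord[t] <- pos_res[pi_]
      pi_ <- pi_ + 1L
    } else {
      ord[t] <- neg_res[ni_]
      ni_ <- ni_ + 1L
    }
    take_pos <- !take_pos
  }
  slots <- unique(round(seq(1L, n, length.out = ncharged)))
  # rounding collisions: fall back to the first ncharged distinct slots
  if (length(slots) < ncharged) {
    slots <- sort(union(slots, setdiff(seq_len(n), slots)))[seq_len(ncharged)]
  }
  out <- character(n)
  out[slots] <- ord
  out[setdiff(seq_len(n), slots)] <- neu_res

  # cached delta_max: composition is fixed under all moves
  np <- sum(ch > 0L)
  nm <- sum(ch < 0L)
  dm5 <- delta_max_composition(np, nm, n - np - nm, 5L)
  dm6 <- delta_max_composition(np, nm, n - np - nm, 6L)
  kap <- function(v) {
    cv <- classify_charge(v)
    (delta_of(cv, 5L) / dm5 + delta_of(cv, 6L) / dm6) / 2
  }

  k_init <- kap(out)
  k_cur <- k_init
  iters <- 0L
  with_seed(seed, {
    while (k_cur > target_kappa && iters < max_iter) {
      iters <- iters + 1L
      i <- sample.int(n, 1L)
      j <- sample.int(n, 1L)
      if (i == j || out[i] == out[j]) next
      # at least one endpoint must be charged (only charges move)
      if (classify_charge(out[i]) == 0L && classify_charge(out[j]) == 0L) next
      cand <- out
      cand[c(i, j)] <- out[c(j, i)]
      k_new <- kap(cand)
      if (k_new < k_cur) {
        out <- cand
        k_cur <- k_new
      }
    }
  })
  variant <- protein_record(
    paste0(record$id, "_uniform"), paste(out, collapse = "")
  )
  design_result(
    variant, record, "uniform_charge", seed,
    list(
      composition_identical = same_composition(variant, record),
      kappa_before = kappa_before, kappa_initial = k_init,
      kappa_after = k_cur, achieved = k_cur <= target_kappa,
      iterations = iters
    )
  )
}

#' Substitute residues of a set by a target residue
#'
#' Occurrences of `from_set` residues (optionally restricted to a
#' region), ordered left to right, are selected and replaced by
#' `to_residue`. `fraction = 1` replaces all occurrences; for a partial
#' fraction `f`, every `round(1/f)`-th occurrence starting from the
#' first is replaced (so `f = 0.5` mutates the 1st, 3rd, 5th, ...
#' occurrence).
#'
#' @param record A `protein_record` or string.
#' @param from_set Residues to replace.
#' @param to_residue Single replacement residue.
#' @param fraction Fraction of occurrences to replace, in (0, 1\].
#' @param reg Optional `region` restricting the substitution.
#' @return A `design_result`; an identity result with a warning when no
#'   occurrences exist.
#' @export
substitute_residues <- function(record, from_set, to_residue,
                                fraction = 1.0, reg = NULL) {
  record <- as_protein_record(record)
  from_set <- toupper(from_set)
  to_residue <- toupper(to_residue)
  stopifnot(
    all(from_set %in% AA_ALPHABET), to_residue %in% AA_ALPHABET,
    fraction > 0, fraction <= 1
  )
  chars <- seq_chars(record)
  in_region <- rep(TRUE, length(chars))
  if (!is.null(reg)) {
    stopifnot(inherits(reg, "region"))
    if (reg$end > length(chars)) stop("region out of range")
    in_region <- seq_along(chars) >= reg$start & seq_along(chars) <= reg$end
  }
  occ <- which(chars %in% from_set & in_region)
  if (length(occ) == 0L) {
    warning("no occurrences of the target set; returning identity")
    sel <- integer()
  } else if (fraction == 1) {
    sel <- occ
  } else {
    sel <- occ[seq(1L, length(occ), by = round(1 / fraction))]
  }
  chars[sel] <- to_residue
  variant <- protein_record(
    paste0(
      record$id, "_", paste(from_set, collapse = ""), "to", to_residue,
      if (fraction < 1) paste0("_", fraction) else ""
    ),
    paste(chars, collapse = "")
  )
  design_result(
    variant, record, "substitute", NA_integer_,
    list(
      n_replaced = length(sel), positions = sel,
      composition_identical = same_composition(variant, record)
    )
  )
}

#' Delete a region from a sequence
#'
#' Removes the inclusive 1-based region; deleting the whole sequence is
#' an error.
#'
#' @param record A `protein_record` or string.
#' @param reg A `region` within the record.
#' @return A `design_result`; `$variant` is the shortened record.
#' @export
delete_region <- function(record, reg) {
  record <- as_protein_record(record)
  stopifnot(inherits(reg, "region"))
  n <- nchar(record$sequence)
  if (reg$end > n) stop("region out of range for ", sQuote(record$id))
  if (reg$start == 1L && reg$end == n) {
    stop("deleting the whole sequence is not allowed")
  }
  chars <- seq_chars(record)
  kept <- chars[-(reg$start:reg$end)]
  variant <- protein_record(
    paste0(record$id, "_del", reg$start, "-", reg$end),
    paste(kept, collapse = "")
  )
  design_result(
    variant, record, "delete", NA_integer_,
    list(deleted_start = reg$start, deleted_end = reg$end,
         n_deleted = reg$end - reg$start + 1L)
  )
}

#' Write a design as FASTA plus a JSON report
#'
#' @param result A `design_result`.
#' @param fasta_path Output FASTA path for the variant sequence.
#' @param report_path Output JSON path for the design report (seed, kind,
#'   verification metrics).
#' @return Invisibly, a list of the two paths.
#' @export
write_design <- function(result, fasta_path, report_path) {
  stopifnot(inherits(result, "design_result"))
  write_fasta(result$variant, fasta_path)
  payload <- list(
    variant_id = result$variant$id, parent_id = result$parent_id,
    design_kind = result$design_kind, seed = result$seed,
    report = result$report
  )
  jsonlite::write_json(
    payload, report_path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(list(fasta = fasta_path, report = report_path))
}
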