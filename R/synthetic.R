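# Seeded generators for synthetic sequences and proteomes with the
# statistical structure the analyses assume: ordered and disordered
# segments with distinct composition profiles, noisy disorder-score
# tracks with known block boundaries, and charge-segregation ladders for
# the kappa metric. All generators are pure functions of (config, seed).

normalise_profile <- function(w) {
  stopifnot(identical(sort(names(w)), sort(AA_ALPHABET)), all(w >= 0))
  w <- w[AA_ALPHABET]
  w / sum(w)
}

#' Default composition profile of synthetic ordered segments
#'
#' Mild enrichment of branched hydrophobics and aromatics, mild depletion
#' of charged residues, relative to uniform; the resulting per-segment
#' Shannon complexity centers near 2.9 nats with a narrow spread. The
#' magnitudes are generator configuration, not biological claims.
#'
#' @return Named numeric 20-vector summing to 1.
#' @export
default_ordered_profile <- function() {
  w <- stats::setNames(rep(1, 20L), AA_ALPHABET)
  w[c("I", "L", "V", "A", "F")] <- 1.6
  w[c("K", "R", "D", "E")] <- 0.7
  w[c("W", "C", "H")] <- 0.5
  normalise_profile(w)
}

#' Default composition profile of synthetic disordered segments
#'
#' Strong enrichment of charged residues (K/E, then R/D) plus S, P, Q,
#' and depletion of hydrophobics and aromatics; per-segment complexity
#' centers near 2.7 nats with a broader spread than the ordered class.
#'
#' @return Named numeric 20-vector summing to 1.
#' @export
default_disordered_profile <- function() {
  w <- stats::setNames(rep(1, 20L), AA_ALPHABET)
  w[c("K", "E")] <- 2.6
  w[c("R", "D")] <- 1.8
  w[c("S", "P", "Q")] <- 1.9
  w[c("I", "L", "V")] <- 0.55
  w[c("F", "W", "Y", "C", "M", "H")] <- 0.25
  normalise_profile(w)
}

#' Sample an i.i.d. random sequence from a composition profile
#'
#' @param profile Named numeric 20-vector of non-negative weights (will
#'   be normalised); e.g. `aa_composition(x)$fractions` or one of the
#'   default class profiles.
#' @param length Sequence length (>= 1).
#' @param seed Integer seed.
#' @param id Identifier for the resulting record.
#' @return A `protein_record`.
#' @export
sample_sequence <- function(profile, length, seed, id = "synth") {
  stopifnot(length >= 1L)
  p <- normalise_profile(profile)
  chars <- with_seed(
    seed, sample(AA_ALPHABET, length, replace = TRUE, prob = p)
  )
  protein_record(id, paste(chars, collapse = ""))
}

#' Configuration for a synthetic proteome
#'
#' Proteins are assembled from alternating ordered/disordered blocks.
#' Each protein gets `n_blocks` blocks (sampled uniformly from the given
#' range) with lengths drawn uniformly from `block_length_range`; the
#' first block's class is random. Disorder scores are the block indicator
#' (1 for disordered residues) plus additive Gaussian noise clipped to
#' \[0, 1\]. The default noise sd of 0.05 reflects a confident predictor;
#' real predictor error is structured, not white, so recovery results on
#' this generator bound only the pipeline's bookkeeping, not predictor
#' quality.
#'
#' @param n_proteins Number of proteins (default 100).
#' @param n_blocks_range Range of blocks per protein (default 2-4).
#' @param block_length_range Block length range in residues (default
#'   150-400, comfortably above the segmentation cutoffs).
#' @param ordered_profile,disordered_profile Class composition profiles.
#' @param noise_sd Disorder-score noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return A list of class `synthetic_proteome_config`.
#' @export
synthetic_proteome_config <- function(
    n_proteins = 100L,
    n_blocks_range = c(2L, 4L),
    block_length_range = c(150L, 400L),
    ordered_profile = default_ordered_profile(),
    disordered_profile = default_disordered_profile(),
    noise_sd = 0.05,
    seed = 1L) {
  stopifnot(n_proteins >= 1L, noise_sd >= 0)
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      n_blocks_range = as.integer(n_blocks_range),
      block_length_range = as.integer(block_length_range),
      ordered_profile = normalise_profile(ordered_profile),
      disordered_profile = normalise_profile(disordered_profile),
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "synthetic_proteome_config"
  )
}

#' Generate a synthetic proteome with ground-truth labels
#'
#' @param config A [synthetic_proteome_config()].
#' @return A list with `records` (list of `protein_record`), `tracks`
#'   (list of noisy `disorder_track`), and `truth` (data.frame
#'   `protein_id`, `start`, `end`, `label` of the generating blocks).
#' @export
generate_proteome <- function(config = synthetic_proteome_config()) {
  stopifnot(inherits(config, "synthetic_proteome_config"))
  with_seed(config$seed, {
    records <- vector("list", config$n_proteins)
    tracks <- vector("list", config$n_proteins)
    truth <- vector("list", config$n_proteins)
    for (i in seq_len(config$n_proteins)) {
      id <- sprintf("synth%03d", i)
      nb <- sample(
        seq(config$n_blocks_range[1L], config$n_blocks_range[2L]), 1L
      )
      first_disordered <- sample(c(TRUE, FALSE), 1L)
      lab <- if (first_disordered) {
        rep(c("disordered", "ordered"), length.out = nb)
      } else {
        rep(c("ordered", "disordered"), length.out = nb)
      }
      lens <- sample(
        seq(config$block_length_range[1L], config$block_length_range[2L]),
        nb, replace = TRUE
      )
      chars <- unlist(lapply(seq_len(nb), function(j) {
        p <- if (lab[j] == "disordered") config$disordered_profile else
          config$ordered_profile
        sample(AA_ALPHABET, lens[j], replace = TRUE, prob = p)
      }))
      indicator <- rep(as.numeric(lab == "disordered"), times = lens)
      noisy <- pmin(pmax(
        indicator + stats::rnorm(length(indicator), 0, config$noise_sd),
        0
      ), 1)
      ends <- cumsum(lens)
      starts <- ends - lens + 1L
      records[[i]] <- protein_record(id, paste(chars, collapse = ""))
      tracks[[i]] <- disorder_track(id, noisy)
      truth[[i]] <- data.frame(
        protein_id = id, start = starts, end = ends, label = lab,
        stringsAsFactors = FALSE
      )
    }
    list(
      records = records, tracks = tracks, truth = do.call(rbind, truth)
    )
  })
}

#' Ladder of permutations with increasing charge segregation
#'
#' All ladder members are permutations of the same residue multiset. The
#' first member interleaves the two charge signs in alternating order
#' with neutral residues spread evenly (a well-mixed, low-kappa
#' arrangement); the last is the fully segregated block arrangement
#' (positives, then neutrals, then negatives). Intermediate states are
#' taken from an adjacent-transposition path between the two and filtered
#' so that kappa is non-decreasing along the ladder by construction.
#'
#' @param composition Character vector: the residue multiset (must
#'   contain both charge signs and at least 6 residues).
#' @param n_steps Number of ladder sequences to return (>= 2).
#' @param seed Integer seed (shuffles the neutral residue identities).
#' @return A list of `n_steps` `protein_record`s, ids `ladder01`, ...
#' @export
kappa_ladder <- function(composition, n_steps = 6L, seed = 1L) {
  composition <- toupper(composition)
  stopifnot(
    all(composition %in% AA_ALPHABET), n_steps >= 2L,
    length(composition) >= 6L
  )
  ch <- classify_charge(composition)
  if (sum(ch > 0L) == 0L || sum(ch < 0L) == 0L) {
    stop("composition must contain both charge signs")
  }
  pos <- composition[ch > 0L]
  neg <- composition[ch < 0L]
  neu <- with_seed(seed, sample(composition[ch == 0L]))
  n <- length(composition)

  # start state: alternate +/- charges at evenly spaced slots
  ncharged <- length(pos) + length(neg)
  ord <- character(ncharged)
  pi_ <- 1L
  ni_ <- 1L
  take_pos <- length(pos) >= length(neg)
  for (t in seq_len(ncharged)) {
    if ((take_pos && pi_ <= length(pos)) || ni_ > length(neg)) {
      ord[t] <- pos[pi_]
      pi_ <- pi_ + 1L
    } else {
      ord[t] <- neg[ni_]
      ni_ <- ni_ + 1L
    }
    take_pos <- !take_pos
  }
  slots <- unique(round(seq(1L, n, length.out = ncharged)))
  if (length(slots) < ncharged) {
    slots <- sort(union(slots, setdiff(seq_len(n), slots)))[seq_len(ncharged)]
  }
  start <- character(n)
  start[slots] <- ord
  start[setdiff(seq_len(n), slots)] <- neu

  end <- c(pos, neu, neg) # fully segregated blocks
  # adjacent-transposition path: selection-sort `start` into `end`
  path <- list(start)
  cur <- start
  for (t in seq_len(n)) {
    j <- t - 1L + which(cur[t:n] == end[t])[1L]
    if (j > t) {
      for (k in j:(t + 1L)) {
        cur[c(k - 1L, k)] <- cur[c(k, k - 1L)]
      }
      path[[length(path) + 1L]] <- cur
    }
  }
  path[[length(path) + 1L]] <- end

  kap <- function(v) suppressWarnings(
    kappa(paste(v, collapse = ""))
  )
  # pick n_steps states, enforcing monotone kappa along the ladder
  idx <- unique(round(seq(1L, length(path), length.out = n_steps * 3L)))
  kvals <- vapply(path[idx], kap, numeric(1L))
  keep <- logical(length(idx))
  best <- -Inf
  for (i in seq_along(idx)) {
    if (kvals[i] >= best) {
      keep[i] <- TRUE
      best <- kvals[i]
    }
  }
  cand <- idx[keep]
  pick <- unique(round(seq(1L, length(cand), length.out = n_steps)))
  chosen <- path[cand[pick]]
  lapply(seq_along(chosen), function(i) {
    protein_record(
      sprintf("ladder%02d", i), paste(chosen[[i]], collapse = "")
    )
  })
}
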