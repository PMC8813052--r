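# Independent brute-force oracles used by the charge-patterning tests.
# These re-derive sigma/delta from first principles (plain loops, no
# cumulative-sum tricks) so they share no code path with the package.

oracle_sigma <- function(ch) {
  n <- length(ch)
  fp <- sum(ch > 0) / n
  fm <- sum(ch < 0) / n
  if (fp + fm == 0) 0 else (fp - fm)^2 / (fp + fm)
}

oracle_delta <- function(ch, g) {
  sg <- oracle_sigma(ch)
  vals <- vapply(seq_len(length(ch) - g + 1L), function(i) {
    (oracle_sigma(ch[i:(i + g - 1L)]) - sg)^2
  }, numeric(1L))
  mean(vals)
}

# exact maximum of delta over every distinct arrangement of a charge
# composition (npos +1s, nneg -1s, nneu 0s); feasible for length <= 12
oracle_delta_max_exhaustive <- function(npos, nneg, nneu, g) {
  n <- npos + nneg + nneu
  best <- 0
  pos_sets <- utils::combn(n, npos)
  for (a in seq_len(ncol(pos_sets))) {
    pp <- pos_sets[, a]
    rest <- setdiff(seq_len(n), pp)
    neg_sets <- if (nneg > 0L) utils::combn(length(rest), nneg) else
      matrix(integer(), nrow = 0L, ncol = 1L)
    for (b in seq_len(ncol(neg_sets))) {
      ch <- integer(n)
      ch[pp] <- 1L
      ch[rest[neg_sets[, b]]] <- -1L
      d <- oracle_delta(ch, g)
      if (d > best) best <- d
    }
  }
  best
}

charge_vec_of <- function(s) {
  chars <- strsplit(s, "")[[1L]]
  ifelse(chars %in% c("K", "R"), 1L, ifelse(chars %in% c("D", "E"), -1L, 0L))
}

# kappa recomputed with an exhaustively maximised delta_max
oracle_kappa_exhaustive <- function(s) {
  ch <- charge_vec_of(s)
  npos <- sum(ch > 0)
  nneg <- sum(ch < 0)
  nneu <- sum(ch == 0)
  vals <- vapply(c(5L, 6L), function(g) {
    dm <- oracle_delta_max_exhaustive(npos, nneg, nneu, g)
    if (dm == 0) NA_real_ else oracle_delta(ch, g) / dm
  }, numeric(1L))
  mean(vals, na.rm = TRUE)
}

# random charged sequence with given counts (uses K/E/G as the three
# residue classes)
random_charged_seq <- function(n, npos, nneg) {
  chars <- c(rep("K", npos), rep("E", nneg), rep("G", n - npos - nneg))
  paste(sample(chars), collapse = "")
}
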