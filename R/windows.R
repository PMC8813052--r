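# Sliding-window tracks and local sequence statistics.
#
# Tracks have no edge padding: a window statistic over windows of size w
# on a sequence of length L yields L - w + 1 values, indexed by the
# 1-based start position of each window. Figure-style center coordinates
# are a plotting concern, not stored.

window_track <- function(protein_id, window_size, values, start_positions) {
  structure(
    list(
      protein_id = protein_id, window_size = as.integer(window_size),
      values = values, start_positions = as.integer(start_positions)
    ),
    class = "window_track"
  )
}

#' @export
print.window_track <- function(x, ...) {
  cat(
    "<window_track>", x$protein_id, "window", x$window_size,
    "n =", length(x$values), "\n"
  )
  invisible(x)
}

#' Sliding-window NCPR track
#'
#' Net charge per residue of each window of size `window` (default 5, the
#' convention used for charge-cluster plots).
#'
#' @param record A `protein_record` or string with length >= `window`.
#' @param window Window size.
#' @return A `window_track`; values in \[-1, 1\], one per window start.
#' @export
ncpr_track <- function(record, window = 5L) {
  record <- as_protein_record(record)
  ch <- charge_vector(record)
  n <- length(ch)
  if (n < window) stop("sequence shorter than window = ", window)
  cs <- cumsum(c(0L, ch))
  i <- seq_len(n - window + 1L)
  window_track(record$id, window, (cs[i + window] - cs[i]) / window, i)
}

#' Sliding-window fraction-of-set track
#'
#' Fraction of window residues belonging to `residue_set`; with the
#' default set L/I/V this is the branched-hydrophobic density track.
#'
#' @param record A `protein_record` or string with length >= `window`.
#' @param residue_set Non-empty subset of [AA_ALPHABET].
#' @param window Window size (default 5).
#' @return A `window_track`; values in \[0, 1\].
#' @export
fraction_track <- function(record, residue_set = c("L", "I", "V"),
                           window = 5L) {
  record <- as_protein_record(record)
  residue_set <- toupper(residue_set)
  stopifnot(length(residue_set) > 0L, all(residue_set %in% AA_ALPHABET))
  hit <- seq_chars(record) %in% residue_set
  n <- length(hit)
  if (n < window) stop("sequence shorter than window = ", window)
  cs <- cumsum(c(0L, hit))
  i <- seq_len(n - window + 1L)
  window_track(record$id, window, (cs[i + window] - cs[i]) / window, i)
}

# threshold comparison with a small tolerance so that fractions of small
# integers (3/5, 4/5) compare exactly at their nominal values
at_or_above <- function(values, threshold) values >= threshold - 1e-9

#' Count windows at or above a threshold
#'
#' @param track A `window_track`.
#' @param threshold Threshold value; comparison is `>=`.
#' @return Integer count of window positions.
#' @export
count_windows_at_or_above <- function(track, threshold) {
  stopifnot(inherits(track, "window_track"))
  sum(at_or_above(track$values, threshold))
}

#' Merged regions where a track reaches a threshold
#'
#' Overlapping qualifying windows are merged into maximal regions; each
#' row covers the union of the residues spanned by a run of qualifying
#' windows (1-based inclusive, BED-like). Both this merged-region view and
#' the raw window count ([count_windows_at_or_above()]) are informative:
#' a single hydrophobic patch yields several overlapping windows.
#'
#' @param track A `window_track`.
#' @param threshold Threshold value; comparison is `>=`.
#' @return data.frame with `protein_id`, `start`, `end`, `n_windows`.
#' @export
threshold_regions <- function(track, threshold) {
  stopifnot(inherits(track, "window_track"))
  ok <- at_or_above(track$values, threshold)
  if (!any(ok)) {
    return(data.frame(
      protein_id = character(), start = integer(), end = integer(),
      n_windows = integer(), stringsAsFactors = FALSE
    ))
  }
  starts <- track$start_positions[ok]
  ends <- starts + track$window_size - 1L
  # a new region begins where a window's span no longer touches the
  # running union of the previous windows' spans
  brk <- c(0L, which(starts[-1L] > cummax(ends)[-length(ends)] + 1L),
           length(starts))
  out <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(j) {
    idx <- (brk[j] + 1L):brk[j + 1L]
    data.frame(
      protein_id = track$protein_id,
      start = starts[idx[1L]],
      end = max(ends[idx]),
      n_windows = length(idx),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Write a window track as TSV
#'
#' Two columns: window start position (1-based) and value.
#'
#' @param track A `window_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  utils::write.table(
    data.frame(position = track$start_positions, value = track$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Run-length partition of set residues
#'
#' Maximal runs of consecutive set residues are measured and every set
#' residue is attributed to its run's length class: isolated (`"1"`),
#' paired (`"2"`), or within runs of three or more (`"3+"`). Fractions
#' are residue-weighted (counts normalised by the total number of set
#' residues).
#'
#' @param record A `protein_record` or string.
#' @param residue_set Residue set (default L/I/V).
#' @return An object of class `run_partition`: list with `counts` and
#'   `fractions`, each named `"1"`, `"2"`, `"3+"`, and `total`. If the
#'   sequence has no set residues an empty partition is returned with a
#'   warning (`total = 0`, fractions `NA`).
#' @export
run_length_partition <- function(record, residue_set = c("L", "I", "V")) {
  residue_set <- toupper(residue_set)
  stopifnot(length(residue_set) > 0L, all(residue_set %in% AA_ALPHABET))
  hit <- seq_chars(record) %in% residue_set
  counts <- c("1" = 0L, "2" = 0L, "3+" = 0L)
  if (any(hit)) {
    r <- rle(hit)
    lens <- r$lengths[r$values]
    counts[["1"]] <- sum(lens[lens == 1L])
    counts[["2"]] <- sum(lens[lens == 2L])
    counts[["3+"]] <- sum(lens[lens >= 3L])
  } else {
    warning("no residues from the set present; empty partition")
  }
  total <- sum(counts)
  fractions <- if (total > 0L) counts / total else
    c("1" = NA_real_, "2" = NA_real_, "3+" = NA_real_)
  structure(
    list(counts = counts, fractions = fractions, total = total),
    class = "run_partition"
  )
}

#' @export
print.run_partition <- function(x, ...) {
  cat("<run_partition> total", x$total, "set residues\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Scan for CDK consensus phosphorylation sites
#'
#' Reports every position matching the minimal consensus `[S/T]P`; hits
#' that also match the full consensus `[S/T]PX[R/K]` are labeled
#' `"full"`. Overlapping hits are all reported. `matched_text` is the
#' 2-residue (minimal) or 4-residue (full) slice at the hit position.
#'
#' @param record A `protein_record` or string.
#' @return data.frame with `protein_id`, `position` (1-based start),
#'   `kind` (`"full"`/`"minimal"`), `matched_text`; zero rows if no hits.
#' @export
scan_cdk_sites <- function(record) {
  record <- as_protein_record(record)
  chars <- seq_chars(record)
  n <- length(chars)
  empty <- data.frame(
    protein_id = character(), position = integer(), kind = character(),
    matched_text = character(), stringsAsFactors = FALSE
  )
  if (n < 2L) return(empty)
  pos <- which(chars[-n] %in% c("S", "T") & chars[-1L] == "P")
  if (length(pos) == 0L) return(empty)
  full <- pos + 3L <= n & chars[pmin(pos + 3L, n)] %in% c("R", "K")
  txt <- ifelse(
    full,
    substring(record$sequence, pos, pos + 3L),
    substring(record$sequence, pos, pos + 1L)
  )
  data.frame(
    protein_id = record$id, position = pos,
    kind = ifelse(full, "full", "minimal"), matched_text = txt,
    stringsAsFactors = FALSE
  )
}
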