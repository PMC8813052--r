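# Proteome-scale disorder segmentation: consume per-residue disorder
# scores from an external predictor (file-based; the package never shells
# out to the predictor), smooth, segment into ordered/disordered regions
# above a length cutoff, and summarise per-class feature distributions.

#' Create a per-residue disorder track
#'
#' @param protein_id Identifier of the protein the scores belong to.
#' @param scores Numeric vector of per-residue scores in \[0, 1\], one per
#'   residue.
#' @return An object of class `disorder_track`.
#' @export
disorder_track <- function(protein_id, scores) {
  stopifnot(is.numeric(scores), length(scores) > 0L)
  if (any(is.na(scores)) || any(scores < 0) || any(scores > 1)) {
    stop("disorder scores must be in [0, 1] with no NA")
  }
  structure(
    list(protein_id = as.character(protein_id), scores = as.numeric(scores)),
    class = "disorder_track"
  )
}

#' @export
print.disorder_track <- function(x, ...) {
  cat(
    "<disorder_track>", x$protein_id, "length", length(x$scores),
    "mean", round(mean(x$scores), 3), "\n"
  )
  invisible(x)
}

#' Read disorder-score tracks from a tabular file
#'
#' Accepts the two dialects used by per-residue disorder predictors:
#' a two-column file (position, score) for a single protein, or a
#' combined three-column file (protein_id, position, score). Tab- or
#' whitespace-separated; a non-numeric header line and `#` comments are
#' skipped. Positions must run 1..n contiguously per protein.
#'
#' @param path Input path.
#' @param protein_id Required for the two-column dialect (ignored for the
#'   three-column one).
#' @return A named list of `disorder_track`.
#' @export
read_disorder_scores <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("no score rows in ", path)
  fields <- strsplit(trimws(lines), "[\t ]+")
  ncol <- length(fields[[1L]])
  # drop a header line (first field non-numeric in a 2-col file, second
  # field non-numeric in a 3-col file)
  probe <- if (ncol >= 3L) 2L else 1L
  if (is.na(suppressWarnings(as.numeric(fields[[1L]][probe])))) {
    fields <- fields[-1L]
  }
  if (ncol >= 3L) {
    ids <- vapply(fields, `[[`, "", 1L)
    pos <- as.integer(vapply(fields, `[[`, "", 2L))
    sc <- as.numeric(vapply(fields, `[[`, "", 3L))
  } else {
    if (is.null(protein_id)) {
      stop("protein_id is required for two-column score files")
    }
    ids <- rep(protein_id, length(fields))
    pos <- as.integer(vapply(fields, `[[`, "", 1L))
    sc <- as.numeric(vapply(fields, `[[`, "", 2L))
  }
  out <- lapply(split(seq_along(ids), ids), function(idx) {
    p <- pos[idx]
    s <- sc[idx][order(p)]
    if (!identical(sort(p), seq_along(p))) {
      stop("positions must be contiguous 1..n for protein ", ids[idx[1L]])
    }
    disorder_track(ids[idx[1L]], s)
  })
  out[unique(ids)]
}

#' Write disorder tracks to a combined three-column TSV
#'
#' @param tracks A `disorder_track` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_disorder_scores <- function(tracks, path) {
  if (inherits(tracks, "disorder_track")) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, function(t) {
    data.frame(
      protein_id = t$protein_id, position = seq_along(t$scores),
      score = t$scores, stringsAsFactors = FALSE
    )
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Smooth a disorder track by a centered moving average
#'
#' Window of `window` residues centered on each position (for even
#' windows, `floor(window/2)` residues to the left and
#' `window - 1 - floor(window/2)` to the right); at the edges the window
#' truncates to the available residues and the mean is taken over the
#' intersection. Output length equals input length.
#'
#' @param track A `disorder_track`.
#' @param window Moving-average window in residues (default 20).
#' @return A smoothed `disorder_track`.
#' @export
smooth_track <- function(track, window = 20L) {
  stopifnot(inherits(track, "disorder_track"), window >= 1L)
  s <- track$scores
  n <- length(s)
  if (window > n) {
    warning("smoothing window larger than sequence; using the global mean")
  }
  left <- floor(window / 2)
  right <- window - 1L - left
  cs <- cumsum(c(0, s))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  disorder_track(track$protein_id, (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Segment a protein into ordered/disordered regions
#'
#' Residues with smoothed score `>= threshold` are labeled disordered,
#' all others ordered; maximal same-label runs strictly longer than
#' `min_length` are emitted with per-segment statistics (composition,
#' complexity, hydropathy, fraction-L/I/V, mean score). Shorter runs are
#' dropped, not merged, so every emitted segment is a faithful slice of
#' the labeling.
#'
#' @param record The `protein_record` the track belongs to.
#' @param smoothed A `disorder_track` of the same length (normally the
#'   output of [smooth_track()]).
#' @param threshold Disorder call threshold (default 0.5, the usual
#'   predictor convention; not printed by most studies, so configurable).
#' @param min_length Strict length cutoff; only runs with
#'   `length > min_length` are emitted.
#' @return A list of `disorder_segment` objects (possibly empty). Each has
#'   `protein_id`, `start`, `end`, `label`, `mean_score`, `composition`,
#'   `complexity`, `hydropathy`, `fraction_liv`.
#' @export
segment_track <- function(record, smoothed, threshold = 0.5, min_length) {
  record <- as_protein_record(record)
  stopifnot(inherits(smoothed, "disorder_track"), min_length >= 1L)
  n <- nchar(record$sequence)
  if (length(smoothed$scores) != n) {
    stop(
      "track length ", length(smoothed$scores),
      " does not match sequence length ", n, " for ", sQuote(record$id)
    )
  }
  lab <- ifelse(smoothed$scores >= threshold, "disordered", "ordered")
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths > min_length
  segs <- lapply(which(keep), function(j) {
    sl <- protein_record(
      "slice", substr(record$sequence, starts[j], ends[j])
    )
    structure(
      list(
        protein_id = record$id,
        start = starts[j], end = ends[j], label = r$values[j],
        mean_score = mean(smoothed$scores[starts[j]:ends[j]]),
        composition = aa_composition(sl),
        complexity = shannon_complexity(sl),
        hydropathy = mean_hydropathy(sl),
        fraction_liv = fraction_of_set(sl, c("L", "I", "V"))
      ),
      class = "disorder_segment"
    )
  })
  segs
}

#' Flatten disorder segments to a BED-like data.frame
#'
#' @param segments List of `disorder_segment`.
#' @return data.frame with `protein_id`, `start`, `end` (1-based
#'   inclusive), `label`, `length`, `mean_score`, `complexity`,
#'   `hydropathy`, `fraction_liv`.
#' @export
segments_as_data_frame <- function(segments) {
  if (length(segments) == 0L) {
    return(data.frame(
      protein_id = character(), start = integer(), end = integer(),
      label = character(), length = integer(), mean_score = numeric(),
      complexity = numeric(), hydropathy = numeric(),
      fraction_liv = numeric(), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, lapply(segments, function(s) {
    data.frame(
      protein_id = s$protein_id, start = s$start, end = s$end,
      label = s$label, length = s$end - s$start + 1L,
      mean_score = s$mean_score, complexity = s$complexity,
      hydropathy = s$hydropathy, fraction_liv = s$fraction_liv,
      stringsAsFactors = FALSE
    )
  }))
}

# moment skewness; NA for n < 3 or zero variance
moment_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

summarize_class <- function(segs, min_length, features) {
  lens <- vapply(segs, function(s) s$end - s$start + 1L, integer(1L))
  segs <- segs[lens > min_length]
  out <- list(count = length(segs))
  if (length(segs) == 0L) return(out)
  for (f in features) {
    v <- vapply(segs, `[[`, numeric(1L), f)
    out[[f]] <- list(
      median = stats::median(v),
      q25 = unname(stats::quantile(v, 0.25, type = 7)),
      q75 = unname(stats::quantile(v, 0.75, type = 7)),
      skewness = moment_skewness(v)
    )
  }
  # residue-weighted mean composition
  lens <- vapply(segs, function(s) s$end - s$start + 1L, numeric(1L))
  cm <- vapply(
    segs, function(s) s$composition$fractions, numeric(20L)
  )
  out$mean_composition <- as.numeric(cm %*% lens) / sum(lens)
  names(out$mean_composition) <- AA_ALPHABET
  out
}

#' Summarise ordered/disordered segments proteome-wide
#'
#' Two length cutoffs are honored because different analyses use
#' different ones: complexity distributions are computed over segments
#' strictly longer than `complexity_min_length` (default 150 aa), while
#' composition, hydropathy and fraction-L/I/V use segments strictly
#' longer than `feature_min_length` (default 100 aa). Quartiles use
#' linear interpolation between order statistics (R quantile type 7).
#'
#' @param segments List of `disorder_segment` from one or more proteins.
#' @param complexity_min_length Strict cutoff for the complexity summary.
#' @param feature_min_length Strict cutoff for the feature summary.
#' @return A nested list: for each class (`ordered`, `disordered`),
#'   `complexity` (count + distribution stats at the 150-aa cutoff) and
#'   `features` (count, hydropathy / fraction_liv stats and mean
#'   composition at the 100-aa cutoff).
#' @export
summarize_proteome <- function(segments, complexity_min_length = 150L,
                               feature_min_length = 100L) {
  stopifnot(length(segments) >= 0L)
  labs <- vapply(segments, `[[`, "", "label")
  out <- list()
  for (cl in c("ordered", "disordered")) {
    segs <- segments[labs == cl]
    out[[cl]] <- list(
      complexity = summarize_class(
        segs, complexity_min_length, "complexity"
      ),
      features = summarize_class(
        segs, feature_min_length, c("hydropathy", "fraction_liv")
      )
    )
  }
  out$parameters <- list(
    complexity_min_length = complexity_min_length,
    feature_min_length = feature_min_length
  )
  out
}

#' Percentile of a value within an empirical distribution
#'
#' Fraction of distribution values `<=` the query value, times 100. Ties
#' count as covered (a value equal to the median of an odd-length list
#' sits at or above 50).
#'
#' @param value Query value.
#' @param distribution Non-empty numeric vector.
#' @return Percentile in \[0, 100\].
#' @export
percentile_of <- function(value, distribution) {
  stopifnot(length(distribution) > 0L)
  100 * mean(distribution <= value)
}

#' Surrogate disorder scores (charge/hydropathy heuristic)
#'
#' A simple deterministic stand-in for an external disorder predictor so
#' the segmentation pipeline is testable without one: windows of high
#' local charge fraction score high, windows of high mean hydropathy
#' score low. Per position `i` (window of 11 residues, truncated at the
#' edges) the raw score is `0.5 + 0.5 * FCR_win - 0.5 * (H_win / 4.5)`,
#' clipped to \[0, 1\], where `H_win` is the mean Kyte-Doolittle value.
#' This is a test harness, not a disorder predictor: it captures the
#' charge-rich/hydrophobe-poor character of disordered segments and
#' nothing else.
#'
#' @param record A `protein_record` or string.
#' @param window Local window size (default 11).
#' @return A `disorder_track`.
#' @export
surrogate_disorder_scores <- function(record, window = 11L) {
  record <- as_protein_record(record)
  chars <- seq_chars(record)
  n <- length(chars)
  charged <- as.numeric(chars %in% c(CHARGE_POSITIVE, CHARGE_NEGATIVE))
  hyd <- KD_HYDROPATHY[chars]
  left <- floor(window / 2)
  right <- window - 1L - left
  csc <- cumsum(c(0, charged))
  csh <- cumsum(c(0, hyd))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  w <- hi - lo + 1L
  fcr_win <- (csc[hi + 1L] - csc[lo]) / w
  h_win <- (csh[hi + 1L] - csh[lo]) / w
  raw <- 0.5 + 0.5 * fcr_win - 0.5 * (h_win / 4.5)
  disorder_track(record$id, pmin(pmax(raw, 0), 1))
}
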