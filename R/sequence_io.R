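#' The 20 standard amino acids (one-letter codes)
#'
#' Alphabet used for validation and as the fixed column order of all
#' composition vectors and matrices in this package (alphabetical).
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Create a protein record
#'
#' The atomic unit of every analysis: an identifier plus an amino-acid
#' sequence over the 20 standard one-letter codes. Lowercase input is
#' uppercased; a terminal "*" (stop) is stripped with a warning; any other
#' non-standard character is an error.
#'
#' @param id Short identifier; must not contain whitespace.
#' @param sequence Amino-acid sequence (single string).
#' @return An object of class `protein_record` with fields `id` and
#'   `sequence`.
#' @examples
#' protein_record("x", "MAQ")
#' @export
protein_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (grepl("[[:space:]]", id)) {
    stop("record id must not contain whitespace: ", sQuote(id))
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("\\*$", sequence)) {
    warning("stripping terminal stop character '*' from record ", sQuote(id))
    sequence <- sub("\\*+$", "", sequence)
  }
  if (!nzchar(sequence)) {
    stop("sequence of record ", sQuote(id), " is empty")
  }
  chars <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop(
      "record ", sQuote(id), " contains non-amino-acid character(s): ",
      paste(sQuote(bad), collapse = ", ")
    )
  }
  structure(list(id = id, sequence = sequence), class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  n <- nchar(x$sequence)
  head <- substr(x$sequence, 1L, 30L)
  cat(
    "<protein_record> ", x$id, " (", n, " aa)\n  ",
    head, if (n > 30L) "..." else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Coerce to a protein record
#'
#' Accepts an existing `protein_record` (returned unchanged) or a plain
#' character string (wrapped with the supplied id). Used by every metric
#' function so that quick interactive calls can pass bare strings.
#'
#' @param x A `protein_record` or a single character string.
#' @param id Identifier used when `x` is a bare string.
#' @return A `protein_record`.
#' @export
as_protein_record <- function(x, id = "seq") {
  if (inherits(x, "protein_record")) return(x)
  if (is.character(x) && length(x) == 1L) return(protein_record(id, x))
  stop("cannot coerce object of class ", class(x)[1L], " to protein_record")
}

# internal: sequence as character vector of residues
seq_chars <- function(record) {
  strsplit(as_protein_record(record)$sequence, "")[[1L]]
}

#' Define a region of a protein
#'
#' Coordinates are 1-based and inclusive throughout the package.
#'
#' @param protein_id Identifier of the parent protein.
#' @param start,end 1-based inclusive coordinates, `1 <= start <= end`.
#' @param label One of `"ordered"`, `"disordered"`, `"unlabeled"`.
#' @return An object of class `region`.
#' @export
region <- function(protein_id, start, end, label = "unlabeled") {
  stopifnot(
    is.numeric(start), is.numeric(end), length(start) == 1L,
    length(end) == 1L, start >= 1, end >= start
  )
  label <- match.arg(label, c("ordered", "disordered", "unlabeled"))
  structure(
    list(
      protein_id = as.character(protein_id),
      start = as.integer(start), end = as.integer(end), label = label
    ),
    class = "region"
  )
}

#' Extract a region from a protein record
#'
#' Returns a new record whose sequence is the inclusive 1-based slice; the
#' id is suffixed with the coordinates (e.g. `"Cdt1_1-297"`).
#'
#' @param record A `protein_record` (or string).
#' @param reg A `region`; its coordinates must lie within the record.
#' @return A `protein_record`.
#' @export
extract_region <- function(record, reg) {
  record <- as_protein_record(record)
  stopifnot(inherits(reg, "region"))
  n <- nchar(record$sequence)
  if (reg$end > n) {
    stop(
      "region ", reg$start, "-", reg$end, " out of range for record ",
      sQuote(record$id), " of length ", n
    )
  }
  protein_record(
    paste0(record$id, "_", reg$start, "-", reg$end),
    substr(record$sequence, reg$start, reg$end)
  )
}

#' Read a protein FASTA file
#'
#' Multi-record FASTA (wrapped or unwrapped lines). Sequences are
#' uppercased and validated against the 20-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @param on_invalid `"error"` aborts on the first invalid record;
#'   `"reject"` drops invalid records with a warning naming each one.
#' @return A list of `protein_record`, in file order.
#' @export
read_fasta <- function(path, on_invalid = c("error", "reject")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("[[:space:]].*$", "", names(set))
  out <- vector("list", length(set))
  keep <- logical(length(set))
  for (i in seq_along(set)) {
    rec <- tryCatch(
      protein_record(ids[i], as.character(set[[i]])),
      error = function(e) e
    )
    if (inherits(rec, "error")) {
      if (on_invalid == "error") stop(conditionMessage(rec))
      warning("rejecting record: ", conditionMessage(rec))
    } else {
      out[[i]] <- rec
      keep[i] <- TRUE
    }
  }
  out[keep]
}

#' Write protein records to a FASTA file
#'
#' @param records A list of `protein_record` (or a single record).
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "protein_record")) records <- list(records)
  stopifnot(length(records) > 0L)
  seqs <- vapply(records, function(r) as_protein_record(r)$sequence, "")
  ids <- vapply(records, function(r) as_protein_record(r)$id, "")
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

# fixture cache (read once per session)
.fixture_env <- new.env(parent = emptyenv())

fixture_records <- function() {
  if (is.null(.fixture_env$records)) {
    path <- system.file("extdata", "cdt1_constructs.fasta", package = "idrseq")
    recs <- read_fasta(path)
    names(recs) <- vapply(recs, `[[`, "", "id")
    .fixture_env$records <- recs
  }
  .fixture_env$records
}

#' Names of the packaged Cdt1 construct fixtures
#'
#' @return Character vector of valid construct names.
#' @seealso [load_fixture()], [fixture_manifest()]
#' @export
fixture_names <- function() names(fixture_records())

#' Load a packaged Cdt1 construct sequence
#'
#' The package ships the wild-type Drosophila Cdt1 N-terminal IDR
#' (residues 1-297) and ten derived constructs (aromatic substitutions,
#' uniform charge redistribution, deletions, a scrambled IDR and two
#' branched-hydrophobic substitution series) as protein sequences.
#'
#' @param name One of [fixture_names()], e.g. `"WT"`, `"Uniform"`,
#'   `"ScrIDR"`.
#' @return A `protein_record`.
#' @examples
#' wt <- load_fixture("WT")
#' nchar(wt$sequence) # 297
#' @export
load_fixture <- function(name) {
  recs <- fixture_records()
  if (!name %in% names(recs)) {
    stop(
      "unknown fixture ", sQuote(name), "; valid names: ",
      paste(names(recs), collapse = ", ")
    )
  }
  recs[[name]]
}

#' Manifest of the packaged construct fixtures
#'
#' @return A data.frame with columns `name`, `length`, `description`.
#' @export
fixture_manifest <- function() {
  path <- system.file(
    "extdata", "cdt1_constructs_manifest.tsv", package = "idrseq"
  )
  utils::read.delim(path, stringsAsFactors = FALSE)
}
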