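# fixture records, loaded once per test run
fx <- local({
  cache <- NULL
  function(name) {
    if (is.null(cache)) {
      recs <- lapply(fixture_names(), load_fixture)
      names(recs) <- fixture_names()
      cache <<- recs
    }
    cache[[name]]
  }
})

tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
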