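test_that("ncpr_track computes sliding net charge without padding", {
  t1 <- ncpr_track("KKKKK", 5L)
  expect_equal(t1$values, 1.0)
  expect_equal(t1$start_positions, 1L)

  t2 <- ncpr_track("KKKKKEEEEE", 5L)
  expect_equal(t2$values[1], 1.0)
  expect_equal(t2$values[length(t2$values)], -1.0)
  expect_length(t2$values, 6L)

  expect_error(ncpr_track("KK", 5L), "shorter than window")

  wt <- ncpr_track(fx("WT"))
  expect_length(wt$values, 293L)
  expect_true(any(wt$values >= 0.6) && any(wt$values <= -0.6))
})

test_that("track length bookkeeping holds for all inputs (property)", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(6:120, 1)
    w <- sample(2:6, 1)
    s <- paste(sample(AA_ALPHABET, n, TRUE), collapse = "")
    expect_length(ncpr_track(s, w)$values, n - w + 1L)
    expect_length(fraction_track(s, "L", w)$values, n - w + 1L)
  }
})

test_that("fraction_track measures windowed set density", {
  expect_equal(fraction_track("LLLLL", c("L", "I", "V"), 5L)$values, 1.0)
  expect_equal(fraction_track("LAAAA", c("L", "I", "V"), 5L)$values, 0.2)

  liv <- fraction_track(fx("WT"))
  hits <- liv$start_positions[liv$values >= 0.8]
  expect_equal(hits, 244L) # the single dense L/I/V patch, 244-248
})

test_that("threshold counting and region merging are consistent", {
  zero <- fraction_track(strrep("A", 30), "L", 5L)
  expect_equal(count_windows_at_or_above(zero, 0.5), 0L)
  expect_equal(nrow(threshold_regions(zero, 0.5)), 0L)

  liv <- fraction_track(fx("WT"))
  expect_equal(count_windows_at_or_above(liv, 0.8), 1L)
  # raw overlapping windows at 0.6 vs merged patches
  expect_equal(count_windows_at_or_above(liv, 0.6), 15L)
  regs <- threshold_regions(liv, 0.6)
  expect_equal(nrow(regs), 5L)
  expect_equal(sum(regs$n_windows), 15L)
  # each third of the IDR holds at least one patch
  expect_true(any(regs$start <= 100))
  expect_true(any(regs$start > 100 & regs$start <= 200))
  expect_true(any(regs$start > 200))
  # exact threshold values (3/5) are not lost to float noise
  t35 <- fraction_track("LLLAA", "L", 5L)
  expect_equal(count_windows_at_or_above(t35, 0.6), 1L)
})

test_that("run_length_partition attributes residues to run classes", {
  rp <- run_length_partition("LAALLAALLL")
  expect_equal(unname(rp$counts), c(1L, 2L, 3L))
  expect_equal(unname(rp$fractions), c(1 / 6, 2 / 6, 3 / 6))

  rp4 <- run_length_partition("VVVV")
  expect_equal(rp4$counts[["3+"]], 4L)
  expect_equal(rp4$fractions[["3+"]], 1.0)

  wt <- run_length_partition(fx("WT"))
  expect_equal(unname(round(wt$fractions, 2)), c(0.67, 0.22, 0.11))

  expect_warning(empty <- run_length_partition("AAAA"), "no residues")
  expect_equal(empty$total, 0L)
})

test_that("run partition counts sum to total set residues (property)", {
  set.seed(31)
  for (i in 1:10) {
    s <- paste(sample(AA_ALPHABET, sample(10:150, 1), TRUE), collapse = "")
    rp <- suppressWarnings(run_length_partition(s))
    expect_equal(
      sum(rp$counts),
      round(fraction_of_set(s, c("L", "I", "V")) * nchar(s))
    )
    if (rp$total > 0) expect_equal(sum(rp$fractions), 1.0)
  }
})

test_that("scan_cdk_sites matches the two consensus patterns", {
  h1 <- scan_cdk_sites("ASPRA")
  expect_equal(h1$position, 2L)
  expect_equal(h1$kind, "minimal") # SPRA: X=R but position 5 is A
  h2 <- scan_cdk_sites("ATPAK")
  expect_equal(h2$kind, "full")
  expect_equal(h2$matched_text, "TPAK")
  expect_equal(nrow(scan_cdk_sites("AAAA")), 0L)

  wt <- scan_cdk_sites(fx("WT"))
  expect_gte(nrow(wt), 1L)
  # the full site inside the TFKTPTKIP stretch: TPTK at position 256
  expect_true(any(wt$position == 256 & wt$kind == "full" &
                    wt$matched_text == "TPTK"))
  # every reported hit re-matches its pattern
  for (i in seq_len(nrow(wt))) {
    pat <- if (wt$kind[i] == "full") "^[ST]P.[RK]$" else "^[ST]P$"
    expect_match(wt$matched_text[i], pat)
  }
})

test_that("track TSV export writes position/value pairs", {
  tr <- ncpr_track("KKKKKEEEEE", 5L)
  p <- tempfile(fileext = ".tsv")
  write_track_tsv(tr, p)
  back <- read.delim(p)
  expect_equal(back$position, tr$start_positions)
  expect_equal(back$value, tr$values)
})
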