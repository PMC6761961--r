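# Windowed depth, ratio classification, scaffold selection.

test_that("window means follow the partial-tile rule", {
  # constant depth 6 over 1 Mb at 100 kb windows
  w <- window_depths(rep(6, 1000000), 100000, "chr1")
  expect_equal(nrow(w), 10)
  expect_true(all(w$depth == 6))
  # half 6x, half 0x in a single window
  w2 <- window_depths(c(rep(6, 500), rep(0, 500)), 1000)
  expect_equal(nrow(w2), 1)
  expect_equal(w2$depth, 3)
  # 250 kb at 100 kb windows: last window spans 50 kb
  w3 <- window_depths(rep(2, 250000), 100000)
  expect_equal(nrow(w3), 3)
  expect_equal(w3$end - w3$start, c(100000, 100000, 50000))
  # windows partition every base exactly once
  expect_equal(w3$start[-1], w3$end[-3])
  expect_equal(w3$start[1], 0)
  expect_equal(w3$end[3], 250000)
  expect_error(window_depths(rep(1, 10), 0), class = "xy_config_error")
})

test_that("depth-ratio classification follows the half-coverage rule", {
  cfg <- coverage_config()
  expect_equal(classify_window(3, 6, cfg), "X_HEMI")
  expect_equal(classify_window(6, 6, cfg, on_x = TRUE), "PAR")
  expect_equal(classify_window(6, 6, cfg, on_x = FALSE), "AUTOSOMAL")
  expect_equal(classify_window(0, 0, cfg), "NO_DATA")
  expect_equal(classify_window(6, 0.5, cfg), "NO_DATA")
  expect_equal(classify_window(12, 6, cfg), "UNASSIGNED")
  expect_error(classify_window(-1, 6, cfg), class = "xy_config_error")
  # vectorised
  expect_equal(classify_window(c(3, 6), c(6, 6), cfg, on_x = c(TRUE, TRUE)),
               c("X_HEMI", "PAR"))
})

test_that("swapping the sexes mirrors X_HEMI onto log2 ratio +1", {
  fx <- coverage_fixture()
  orig <- coverage_windows(fx$tracks_m$chrX, fx$tracks_f$chrX, 10000,
                           coverage_config(), "chrX", on_x = TRUE)
  swapped <- coverage_windows(fx$tracks_f$chrX, fx$tracks_m$chrX, 10000,
                              coverage_config(), "chrX", on_x = TRUE)
  hemi <- orig$label == "X_HEMI"
  expect_gt(sum(hemi), 0)
  expect_true(all(abs(swapped$log2_ratio[hemi] - 1) <= 0.25))
  expect_equal(swapped$log2_ratio, -orig$log2_ratio)
})

test_that("simulated windows recover their truth labels", {
  fx <- coverage_fixture()
  expect_gte(fx$score$accuracy, 0.95)
  # PAR windows form contiguous runs on the X
  wx <- fx$score$windows[fx$score$windows$chrom == "chrX", ]
  wx <- wx[order(wx$start), ]
  runs <- rle(wx$label == "PAR")
  expect_lte(sum(runs$values), length(fx$sim$truth$par_segments) + 1)
})

test_that("scaffold selection applies the preset thresholds", {
  set.seed(55)
  ref_seq <- random_dna(20000)
  reference <- c(ref1 = ref_seq)
  # exact substring scaffold
  exact <- substr(ref_seq, 5001, 5800)
  # scaffold at identity 0.75: conserved 60 nt seed region, then every 3rd
  # base mutated to bring overall identity to 0.75
  base <- substr(ref_seq, 9001, 9800)
  ch <- strsplit(base, "")[[1]]
  mut_pos <- seq(61, 660, by = 3)
  for (i in mut_pos) ch[i] <- setdiff(c("A","C","G","T"), ch[i])[1]
  seventyfive <- paste(ch, collapse = "")
  expected_identity <- 1 - length(mut_pos) / nchar(base)
  # scaffold aligning over only 45% of its length
  partial <- paste0(substr(ref_seq, 12001, 12360), random_dna(440))

  queries <- c(exact = exact, div = seventyfive, part = partial)
  anolis <- select_scaffolds(queries, reference, cfg = coverage_config(preset = "anolis"))
  chicken <- select_scaffolds(queries, reference, cfg = coverage_config(preset = "chicken"))
  expect_true("exact" %in% anolis$scaffold)
  expect_equal(anolis$identity[anolis$scaffold == "exact"], 1.0)
  expect_equal(anolis$q_aligned_frac[anolis$scaffold == "exact"], 1.0)
  # identity 0.75: excluded under anolis (>0.80), retained under chicken (>0.70)
  expect_false("div" %in% anolis$scaffold)
  expect_true("div" %in% chicken$scaffold)
  expect_equal(chicken$identity[chicken$scaffold == "div"], expected_identity,
               tolerance = 0.02)
  # 45% aligned: excluded under anolis (>0.50), retained under chicken (>0.40)
  expect_false("part" %in% anolis$scaffold)
  expect_true("part" %in% chicken$scaffold)
  # retained scaffolds come back ordered by reference coordinate
  expect_equal(chicken$ref_start, sort(chicken$ref_start))
  expect_error(select_scaffolds(queries, character(0)),
               class = "xy_config_error")
})

test_that("depth track round-trips through the TSV interface", {
  tracks <- list(chr1 = c(rep(3, 50), rep(6, 50)))
  path <- tempfile(fileext = ".tsv")
  write_depth_track(tracks, path)
  back <- read_depth_track(path)
  expect_equal(back$chr1, tracks$chr1)
})
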