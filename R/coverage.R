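# Windowed male/female read-depth comparison: the signature of a hemizygous
# X-specific region is half coverage in males (log2 M/F ~ -1) while
# pseudoautosomal and autosomal sequence shows equal coverage (log2 ~ 0).

#' Coverage analysis configuration
#'
#' @param window_autosome window size (nt) for autosomes (default 100 kb).
#' @param window_x window size (nt) for the candidate X (default 10 kb).
#' @param ratio_log2_tolerance half-width of the log2-ratio acceptance band
#'   around 0 and -1 (default 0.25, chosen so Poisson depth noise at 6x over
#'   10 kb windows misclassifies under 1% of windows).
#' @param min_depth minimum mean depth in both sexes for a window to be
#'   classified (default 1).
#' @param preset scaffold-selection thresholds: `"anolis"` (align over 50%
#'   of scaffold length at above 80% identity, for a close reference) or
#'   `"chicken"` (over 40% at above 70%, for a distant reference).
#' @return a `coverage_config` list with fields including
#'   `scaffold_min_len_frac` and `scaffold_min_identity`.
#' @export
coverage_config <- function(window_autosome = 100000L, window_x = 10000L,
                            ratio_log2_tolerance = 0.25, min_depth = 1,
                            preset = c("anolis", "chicken")) {
  preset <- match.arg(preset)
  if (window_autosome <= 0 || window_x <= 0) {
    xy_error("invalid 'window': window sizes must be > 0", "xy_config_error")
  }
  if (ratio_log2_tolerance <= 0 || ratio_log2_tolerance >= 0.5) {
    xy_error("invalid 'ratio_log2_tolerance': must be in (0, 0.5)",
             "xy_config_error")
  }
  thresholds <- list(anolis = c(0.50, 0.80), chicken = c(0.40, 0.70))[[preset]]
  structure(list(window_autosome = as.integer(window_autosome),
                 window_x = as.integer(window_x),
                 ratio_log2_tolerance = ratio_log2_tolerance,
                 min_depth = min_depth, preset = preset,
                 scaffold_min_len_frac = thresholds[1],
                 scaffold_min_identity = thresholds[2]),
            class = "coverage_config")
}

#' Select and order scaffolds against a reference genome
#'
#' Retains scaffolds whose best alignment covers more than `min_len_frac` of
#' their length at above `min_identity`, and orders them along the reference
#' so windows can be laid out in reference coordinates.
#'
#' @param query_sequences named character vector of scaffolds.
#' @param reference_sequences named character vector of reference
#'   chromosomes.
#' @param min_len_frac,min_identity selection thresholds in (0, 1]; defaults
#'   from `cfg`.
#' @param cfg a [coverage_config()] supplying preset thresholds.
#' @param aligner alignment function with the [seed_extend_align()]
#'   signature and columns.
#' @return data frame of retained scaffolds ordered by reference coordinate:
#'   `scaffold`, `ref`, `ref_start`, `ref_end`, `identity`,
#'   `q_aligned_frac`.
#' @export
select_scaffolds <- function(query_sequences, reference_sequences,
                             min_len_frac = cfg$scaffold_min_len_frac,
                             min_identity = cfg$scaffold_min_identity,
                             cfg = coverage_config(),
                             aligner = seed_extend_align) {
  if (!length(reference_sequences)) xy_error("empty reference", "xy_config_error")
  stopifnot(min_len_frac > 0, min_len_frac <= 1,
            min_identity > 0, min_identity <= 1)
  hits <- aligner(query_sequences, reference_sequences)
  keep <- hits[hits$q_aligned_frac > min_len_frac &
                 hits$identity > min_identity, , drop = FALSE]
  keep <- keep[order(keep$ref, keep$ref_start), , drop = FALSE]
  data.frame(scaffold = keep$query, ref = keep$ref,
             ref_start = keep$ref_start, ref_end = keep$ref_end,
             identity = keep$identity, q_aligned_frac = keep$q_aligned_frac,
             stringsAsFactors = FALSE)
}

#' Mean depth per window of a per-base depth track
#'
#' Tiles the track into `ceiling(L / window)` windows; the final partial
#' window averages over the bases it actually covers.
#'
#' @param track per-base depth: numeric vector or [S4Vectors::Rle].
#' @param window window size (nt).
#' @param chrom chromosome name attached to the output.
#' @return data frame `chrom`, `start`, `end` (0-based half-open), `depth`.
#' @export
window_depths <- function(track, window, chrom = "chr") {
  if (window <= 0) xy_error("invalid 'window': must be > 0", "xy_config_error")
  L <- length(track)
  if (L == 0L) xy_error("empty depth track", "xy_config_error")
  starts <- seq(1L, L, by = window)
  ends <- pmin(starts + window - 1L, L)
  rle <- methods::is(track, "Rle")
  depth <- if (rle) {
    IRanges::viewMeans(IRanges::Views(track, start = starts, end = ends))
  } else {
    vapply(seq_along(starts), function(i) mean(track[starts[i]:ends[i]]),
           numeric(1))
  }
  data.frame(chrom = chrom, start = starts - 1, end = ends,
             depth = as.numeric(depth), stringsAsFactors = FALSE)
}

#' Classify a window from male and female mean depths
#'
#' A window is `X_HEMI` when the male/female log2 depth ratio sits within
#' the tolerance band around -1 (half coverage in males), `AUTOSOMAL` (or
#' `PAR` on the candidate X) within the band around 0, `NO_DATA` when either
#' sex is below `min_depth`, and `UNASSIGNED` otherwise.
#'
#' @param male_depth,female_depth mean window depths (vectorised).
#' @param cfg a [coverage_config()].
#' @param on_x whether the window lies on the candidate X scaffold set.
#' @return character vector of labels.
#' @export
classify_window <- function(male_depth, female_depth, cfg = coverage_config(),
                            on_x = FALSE) {
  if (any(male_depth < 0, na.rm = TRUE) || any(female_depth < 0, na.rm = TRUE)) {
    xy_error("negative depth", "xy_config_error")
  }
  n <- max(length(male_depth), length(female_depth))
  m <- rep_len(male_depth, n); f <- rep_len(female_depth, n)
  on_x <- rep_len(on_x, n)
  out <- rep("UNASSIGNED", n)
  low <- is.na(m) | is.na(f) | m < cfg$min_depth | f < cfg$min_depth
  ratio <- suppressWarnings(log2(m / f))
  ratio[low] <- NA_real_
  tol <- cfg$ratio_log2_tolerance
  out[which(abs(ratio + 1) <= tol)] <- "X_HEMI"
  eq <- abs(ratio) <= tol
  out[which(eq & !on_x)] <- "AUTOSOMAL"
  out[which(eq & on_x)] <- "PAR"
  out[low] <- "NO_DATA"
  out
}

#' Windowed male/female coverage comparison for one chromosome
#'
#' @param male_track,female_track per-base depth tracks of equal length.
#' @param window window size (nt).
#' @param cfg a [coverage_config()].
#' @param chrom chromosome name.
#' @param on_x whether this chromosome is the candidate X.
#' @return data frame of windows with `male_depth`, `female_depth`,
#'   `log2_ratio`, `label`.
#' @export
coverage_windows <- function(male_track, female_track, window,
                             cfg = coverage_config(), chrom = "chr",
                             on_x = FALSE) {
  if (length(male_track) != length(female_track)) {
    xy_error("male and female tracks differ in length", "xy_config_error")
  }
  wm <- window_depths(male_track, window, chrom)
  wf <- window_depths(female_track, window, chrom)
  out <- data.frame(chrom = wm$chrom, start = wm$start, end = wm$end,
                    male_depth = wm$depth, female_depth = wf$depth,
                    log2_ratio = log2(wm$depth / wf$depth),
                    stringsAsFactors = FALSE)
  out$label <- classify_window(out$male_depth, out$female_depth, cfg, on_x)
  out
}

#' Genome-wide coverage scan
#'
#' Applies [coverage_windows()] per chromosome: autosomes at
#' `cfg$window_autosome`, the candidate X at the finer `cfg$window_x`.
#'
#' @param male_tracks,female_tracks named lists of per-base depth tracks.
#' @param cfg a [coverage_config()].
#' @param x_chrom name of the candidate X chromosome.
#' @return combined window data frame.
#' @export
coverage_scan <- function(male_tracks, female_tracks, cfg = coverage_config(),
                          x_chrom = "chrX") {
  chroms <- names(female_tracks)
  out <- lapply(chroms, function(ch) {
    on_x <- identical(ch, x_chrom)
    coverage_windows(male_tracks[[ch]], female_tracks[[ch]],
                     if (on_x) cfg$window_x else cfg$window_autosome,
                     cfg, chrom = ch, on_x = on_x)
  })
  do.call(rbind, out)
}

#' Score window labels against simulation truth
#'
#' Each window's expected label is the truth class at its midpoint
#' (`AUTOSOMAL`, `X_HEMI` or `PAR`).
#'
#' @param windows window table from [coverage_scan()].
#' @param truth a `sim_truth`.
#' @return list: `accuracy`, the `windows` table with an `expected` column,
#'   and `mean_male_depth_x_hemi` (mean male depth over truth hemizygous
#'   windows).
#' @export
score_window_labels <- function(windows, truth) {
  mid <- (windows$start + windows$end) / 2
  expected <- rep(NA_character_, nrow(windows))
  for (i in seq_len(nrow(truth$regions))) {
    r <- truth$regions[i, ]
    sel <- windows$chrom == r$chrom & mid >= r$start & mid < r$end
    expected[sel] <- if (r$class == "AUTOSOMAL") "AUTOSOMAL" else r$class
  }
  windows$expected <- expected
  ok <- !is.na(expected)
  hemi <- ok & expected == "X_HEMI"
  list(accuracy = mean(windows$label[ok] == expected[ok]),
       windows = windows,
       mean_male_depth_x_hemi = mean(windows$male_depth[hemi]))
}

#' Write a window table as BED-like TSV
#' @param windows window data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  write.table(windows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-base depth track
#'
#' Accepts 2-column `pos<TAB>depth` (1-based positions) or BED-like
#' 4-column `chrom start end depth` (0-based half-open) text files.
#'
#' @param path input path.
#' @param length track length; inferred from the maximum coordinate when
#'   `NULL`.
#' @return for 2-column input a numeric vector; for 4-column input a named
#'   list of numeric vectors per chromosome.
#' @export
read_depth_track <- function(path, length = NULL) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) == 2L) {
    L <- if (is.null(length)) max(tab[[1L]]) else length
    out <- numeric(L)
    out[tab[[1L]]] <- tab[[2L]]
    return(out)
  }
  if (ncol(tab) != 4L) xy_error("depth track must have 2 or 4 columns", "xy_io_error")
  chroms <- unique(tab[[1L]])
  setNames(lapply(chroms, function(ch) {
    sub <- tab[tab[[1L]] == ch, , drop = FALSE]
    L <- if (is.null(length)) max(sub[[3L]]) else length
    out <- numeric(L)
    for (i in seq_len(nrow(sub))) {
      out[(sub[i, 2L] + 1L):sub[i, 3L]] <- sub[i, 4L]
    }
    out
  }), chroms)
}

#' Write per-base depth tracks as BED-like runs
#' @param tracks named list of per-base depth vectors (or Rle).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(tracks, path) {
  rows <- lapply(names(tracks), function(ch) {
    r <- S4Vectors::Rle(as.numeric(tracks[[ch]]))
    ends <- cumsum(S4Vectors::runLength(r))
    data.frame(chrom = ch, start = c(0, head(ends, -1)), end = ends,
               depth = S4Vectors::runValue(r))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
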