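#' Simulate uniform-coverage short reads from a set of sequences
#'
#' Reads are drawn uniformly over the sequence set (start positions uniform,
#' sequences weighted by the number of valid start positions); the read
#' count is `round(depth * total_length / read_length)`.  Qualities are a
#' constant placeholder and base errors default to none.
#'
#' @param seqs named character vector of template sequences (one haplotype,
#'   or a transcript set).
#' @param depth target fold coverage of the sequence set.
#' @param read_length read length (nt); must not exceed the shortest
#'   sequence.
#' @param seed RNG seed.
#' @param stranded if `TRUE` all reads come from the sense strand
#'   (strand-specific RNA libraries); otherwise strands are sampled.
#' @param error_rate per-base substitution error probability.
#' @param id_prefix prefix for read identifiers.
#' @return data frame with columns `id`, `chrom`, `start` (0-based),
#'   `strand`, `seq`.
#' @export
simulate_reads <- function(seqs, depth, read_length, seed = NULL,
                           stranded = FALSE, error_rate = 0,
                           id_prefix = "r") {
  if (!length(seqs)) xy_error("empty genome: no sequences to sample reads from",
                              "xy_config_error")
  if (depth <= 0) xy_error("invalid 'depth': must be > 0", "xy_config_error")
  lens <- nchar(seqs)
  if (read_length > min(lens)) {
    xy_error(sprintf("invalid 'read_length': %d exceeds shortest sequence (%d nt)",
                     read_length, min(lens)), "xy_config_error")
  }
  with_seed(seed, {
    n_reads <- round(depth * sum(lens) / read_length)
    n_starts <- lens - read_length + 1L
    chrom_idx <- sample.int(length(seqs), n_reads, replace = TRUE,
                            prob = n_starts)
    start <- floor(runif(n_reads) * n_starts[chrom_idx])  # 0-based
    seq <- substr(seqs[chrom_idx], start + 1L, start + read_length)
    strand <- if (stranded) rep("+", n_reads) else
      sample(c("+", "-"), n_reads, replace = TRUE)
    rc <- strand == "-"
    if (any(rc)) seq[rc] <- revcomp(seq[rc])
    if (error_rate > 0 && n_reads > 0) {
      seq <- add_read_errors(seq, error_rate)
    }
    data.frame(
      id = sprintf("%s%06d|%s:%d:%s", id_prefix, seq_len(n_reads),
                   names(seqs)[chrom_idx], start, strand),
      chrom = names(seqs)[chrom_idx],
      start = start, strand = strand, seq = seq,
      stringsAsFactors = FALSE)
  })
}

add_read_errors <- function(seq, error_rate) {
  vapply(seq, function(s) {
    ch <- strsplit(s, "")[[1L]]
    hit <- which(runif(length(ch)) < error_rate)
    for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate whole-genome reads for one diploid individual
#'
#' Each haplotype is sampled at half the individual's total depth, so
#' autosomes reach the configured depth while the hemizygous X-specific
#' region in males reaches half of it.
#'
#' @param sim a `sim_genome` from [simulate_genome_pair()].
#' @param sex `"male"` (autosomes + X + Y) or `"female"` (autosomes + 2 X).
#' @param depth total diploid fold coverage (default from `cfg`).
#' @param read_length read length (nt).
#' @param seed RNG seed.
#' @param error_rate per-base substitution error probability.
#' @return data frame of reads (see [simulate_reads()]) with a `haplotype`
#'   column.
#' @export
simulate_sex_reads <- function(sim, sex = c("male", "female"), depth,
                               read_length = 100L, seed = NULL,
                               error_rate = 0) {
  sex <- match.arg(sex)
  autos <- sim$female[setdiff(names(sim$female), "chrX")]
  haplotypes <- if (sex == "female") {
    list(h1 = c(autos, chrX = unname(sim$female[["chrX"]])),
         h2 = c(autos, chrX = unname(sim$female[["chrX"]])))
  } else {
    list(h1 = c(autos, chrX = unname(sim$male[["chrX"]])),
         h2 = c(autos, chrY = unname(sim$male[["chrY"]])))
  }
  out <- lapply(seq_along(haplotypes), function(i) {
    r <- simulate_reads(haplotypes[[i]], depth / 2, read_length,
                        seed = derive_seed(seed, i),
                        error_rate = error_rate,
                        id_prefix = paste0(sex, "_h", i, "_"))
    r$haplotype <- names(haplotypes)[i]
    r
  })
  do.call(rbind, out)
}
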