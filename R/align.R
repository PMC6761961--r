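# Alignment layer.
#
# Two built-in aligners back the pipeline on synthetic data:
#  * map_reads_exact(): full-length exact matching of constant-width reads
#    (both strands) via Biostrings dictionaries -- adequate because simulated
#    reads carry no errors; and
#  * seed_extend_align(): exact 31-mer seeding with ungapped X-drop
#    extension, reporting the best hit per query with identity and aligned
#    fraction -- the "alignment contract" consumed by scaffold selection and
#    male-specificity validation.  Production data can substitute an external
#    aligner by supplying any function with the same signature and columns.

#' Exactly map constant-width reads to a reference (both strands)
#'
#' @param read_seqs character vector of read sequences (any mix of widths;
#'   widths are processed in groups).
#' @param reference named character vector of reference sequences.
#' @return data frame with one row per mapped read: `read` (index into
#'   `read_seqs`), `chrom`, `start` (0-based), `end`, `strand`.  Reads with
#'   multiple exact hits report the first.
#' @export
map_reads_exact <- function(read_seqs, reference) {
  ref <- Biostrings::DNAStringSet(reference)
  hits <- list()
  widths <- nchar(read_seqs)
  for (w in unique(widths)) {
    idx <- which(widths == w)
    for (strand in c("+", "-")) {
      seqs <- if (strand == "+") read_seqs[idx] else revcomp(read_seqs[idx])
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs))
      for (ch in names(reference)) {
        m <- Biostrings::matchPDict(pd, ref[[ch]])
        cnt <- lengths(m)
        has <- which(cnt > 0L)
        if (!length(has)) next
        first <- vapply(has, function(i) IRanges::start(m[[i]])[1L],
                        numeric(1))
        hits[[length(hits) + 1L]] <- data.frame(
          read = idx[has], chrom = ch, start = first - 1, end = first - 1 + w,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(read = integer(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0)))
  }
  all_hits <- do.call(rbind, hits)
  all_hits[!duplicated(all_hits$read), , drop = FALSE]
}

#' Per-base depth tracks from read mappings
#'
#' @param hits data frame from [map_reads_exact()] (columns `chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param ref_lengths named vector of reference sequence lengths.
#' @return named list of [S4Vectors::Rle] per-base coverage vectors.
#' @export
depth_from_hits <- function(hits, ref_lengths) {
  out <- lapply(names(ref_lengths), function(ch) {
    h <- hits[hits$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = h$start + 1L, end = h$end)
    IRanges::coverage(ir, width = ref_lengths[[ch]])
  })
  setNames(out, names(ref_lengths))
}

# k-mer position index of a reference set (data.table: kmer, chrom, pos)
ref_kmer_index <- function(reference, k) {
  parts <- lapply(names(reference), function(ch) {
    s <- reference[[ch]]
    L <- nchar(s)
    if (L < k) return(NULL)
    data.table::data.table(kmer = substring(s, 1:(L - k + 1L), k:L),
                           chrom = ch, pos = 1:(L - k + 1L))
  })
  idx <- data.table::rbindlist(parts)
  data.table::setkey(idx, kmer)
  idx
}

# ungapped X-drop extension along one diagonal; returns best segment
extend_diagonal <- function(qc, rc, qpos, rpos, k, match = 1, mismatch = -2,
                            xdrop = 30) {
  Lq <- length(qc); Lr <- length(rc)
  # right extension from the end of the seed
  score_run <- function(qi, ri, step) {
    best <- 0; cur <- 0; best_n <- 0L; n <- 0L
    while (TRUE) {
      qi <- qi + step; ri <- ri + step
      if (qi < 1L || qi > Lq || ri < 1L || ri > Lr) break
      n <- n + 1L
      cur <- cur + if (qc[qi] == rc[ri]) match else mismatch
      if (cur > best) { best <- cur; best_n <- n }
      if (best - cur > xdrop) break
    }
    best_n
  }
  nr <- score_run(qpos + k - 1L, rpos + k - 1L, 1L)
  nl <- score_run(qpos, rpos, -1L)
  qs <- qpos - nl; qe <- qpos + k - 1L + nr
  rs <- rpos - nl
  len <- qe - qs + 1L
  matches <- sum(qc[qs:qe] == rc[rs:(rs + len - 1L)])
  list(q_start = qs, q_end = qe, r_start = rs, r_end = rs + len - 1L,
       len = len, identity = matches / len,
       score = matches * match + (len - matches) * mismatch)
}

#' Seed-and-extend aligner (exact k-mer seeds, ungapped extension)
#'
#' Finds exact `k`-mer seed matches of each query (both strands) in the
#' reference, extends each seeded diagonal without gaps under an X-drop
#' rule, and reports the best-scoring hit per query.
#'
#' @param queries named character vector of query sequences.
#' @param reference named character vector of reference sequences.
#' @param k seed length (default 31).
#' @param match,mismatch,xdrop ungapped extension scoring.
#' @param max_diagonals cap on seeded diagonals examined per query/strand.
#' @return data frame with one row per query that produced a hit: `query`,
#'   `ref`, `ref_start`, `ref_end` (0-based half-open), `strand`,
#'   `identity` (over the aligned segment), `q_aligned_frac` (aligned
#'   segment length / query length), `score`.
#' @export
seed_extend_align <- function(queries, reference, k = 31L, match = 1,
                              mismatch = -2, xdrop = 30,
                              max_diagonals = 50L) {
  if (!length(reference)) xy_error("empty reference", "xy_config_error")
  if (is.null(names(queries))) names(queries) <- paste0("q", seq_along(queries))
  idx <- ref_kmer_index(reference, k)
  ref_chars <- lapply(reference, function(s) strsplit(s, "")[[1L]])
  rows <- vector("list", length(queries))
  kmer <- NULL  # data.table NSE
  for (qi in seq_along(queries)) {
    best <- NULL
    for (strand in c("+", "-")) {
      q <- if (strand == "+") queries[[qi]] else revcomp(queries[[qi]])
      Lq <- nchar(q)
      if (Lq < k || nrow(idx) == 0L) next
      qk <- data.table::data.table(kmer = substring(q, 1:(Lq - k + 1L), k:Lq),
                                   qpos = 1:(Lq - k + 1L))
      seeds <- idx[qk, on = "kmer", nomatch = NULL]
      if (!nrow(seeds)) next
      seeds$diag <- seeds$pos - seeds$qpos
      # one (earliest) seed per diagonal, heaviest diagonals first
      data.table::setorder(seeds, chrom, diag, qpos)
      firsts <- seeds[!duplicated(paste(seeds$chrom, seeds$diag)), ]
      tallies <- table(paste(seeds$chrom, seeds$diag))
      ord <- order(-as.integer(tallies[paste(firsts$chrom, firsts$diag)]))
      firsts <- firsts[head(ord, max_diagonals), ]
      qc <- strsplit(q, "")[[1L]]
      for (s in seq_len(nrow(firsts))) {
        hit <- extend_diagonal(qc, ref_chars[[firsts$chrom[s]]],
                               firsts$qpos[s], firsts$pos[s], k,
                               match, mismatch, xdrop)
        if (is.null(best) || hit$score > best$score) {
          best <- c(hit, list(ref = firsts$chrom[s], strand = strand, Lq = Lq))
        }
      }
    }
    if (!is.null(best)) {
      rows[[qi]] <- data.frame(
        query = names(queries)[qi], ref = best$ref,
        ref_start = best$r_start - 1, ref_end = best$r_end,
        strand = best$strand, identity = best$identity,
        q_aligned_frac = best$len / best$Lq, score = best$score,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(query = character(0), ref = character(0),
                      ref_start = numeric(0), ref_end = numeric(0),
                      strand = character(0), identity = numeric(0),
                      q_aligned_frac = numeric(0), score = numeric(0))
  }
  out
}
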