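# Y-specific transcript discovery by read subtraction: male RNA-seq reads
# are filtered against the female genome, then against the abundant k-mer
# signature of the female transcriptome, the few survivors are assembled
# into contigs, and each contig is validated as present in the male genome
# (100% identity over at least 90% of its length) and absent from the
# female genome.

as_read_vector <- function(reads) {
  if (is.data.frame(reads)) return(setNames(reads$seq, reads$id))
  if (!length(reads)) return(setNames(character(0), character(0)))
  if (is.null(names(reads))) return(setNames(reads, paste0("read", seq_along(reads))))
  reads
}

#' Drop reads containing ambiguous nucleotides
#' @param reads named character vector or read data frame.
#' @return named character vector without reads containing non-ACGT bases.
#' @export
remove_ambiguous_reads <- function(reads) {
  reads <- as_read_vector(reads)
  reads[!grepl("[^ACGT]", reads)]
}

#' Remove reads that map to a genome
#'
#' Returns exactly the reads with no qualifying alignment to the genome.
#' The default matcher is full-length exact matching on both strands,
#' matching the simulator's error-free reads; any mapper with the
#' [map_reads_exact()] interface can be substituted.
#'
#' @param reads named character vector (or read data frame).
#' @param genome named character vector of genome sequences.
#' @param mapper mapping function returning a data frame with a `read`
#'   index column.
#' @return the unmapped subset of `reads`.
#' @export
filter_genome_mapped <- function(reads, genome, mapper = map_reads_exact) {
  reads <- as_read_vector(reads)
  if (!length(reads)) return(reads)
  hits <- mapper(unname(reads), genome)
  mapped <- unique(hits$read)
  reads[setdiff(seq_along(reads), mapped)]
}

#' Build an abundant k-mer index from reads
#'
#' Counts every k-length window of every read (orientations are counted
#' as observed, not canonicalised), drops k-mers containing ambiguous
#' bases, and keeps those at or above `min_count`.
#'
#' @param reads named character vector (or read data frame).
#' @param k k-mer length (default 35).
#' @param min_count minimum frequency for a k-mer to enter the index
#'   (default 10; rarer k-mers are not part of the overall signature).
#' @return object of class `kmer_index` with fields `k`, `min_count`,
#'   `kmers` (character), `counts` (integer).
#' @export
build_kmer_index <- function(reads, k = 35L, min_count = 10L) {
  reads <- as_read_vector(reads)
  if (k < 1L) xy_error("invalid 'k': must be >= 1", "xy_config_error")
  lens <- nchar(reads)
  usable <- reads[lens >= k]
  if (length(reads) && !length(usable)) {
    xy_error(sprintf("invalid 'k': %d exceeds every read length", k),
             "xy_config_error")
  }
  kmers <- extract_kmers(usable, k)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  kmer <- NULL
  tab <- data.table::data.table(kmer = kmers)[, .N, by = kmer]
  keep <- tab[tab$N >= min_count, ]
  structure(list(k = as.integer(k), min_count = as.integer(min_count),
                 kmers = keep$kmer, counts = keep$N),
            class = "kmer_index")
}

extract_kmers <- function(seqs, k) {
  if (!length(seqs)) return(character(0))
  unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    substring(s, 1:(L - k + 1L), k:L)
  }), use.names = FALSE)
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: %d %d-mers at count >= %d\n",
              length(x$kmers), x$k, x$min_count))
  invisible(x)
}

#' Subtract reads carrying indexed k-mers
#'
#' A read survives only if none of its k-length windows (in either
#' orientation; the libraries are strand-specific but the genome is not)
#' matches an indexed k-mer exactly -- no mismatches, no indels.  Reads
#' shorter than `k` cannot be screened and are dropped with a warning.
#'
#' @param reads named character vector (or read data frame).
#' @param index a [build_kmer_index()] result.
#' @param both_strands also screen the reverse complement (default TRUE).
#' @return the surviving subset of `reads`; attribute `n_dropped_short`
#'   counts unscreenable reads.
#' @export
subtract_by_kmers <- function(reads, index, both_strands = TRUE) {
  stopifnot(inherits(index, "kmer_index"))
  reads <- as_read_vector(reads)
  short <- nchar(reads) < index$k
  if (any(short)) {
    warning(sprintf("%d reads shorter than k = %d dropped (cannot be screened)",
                    sum(short), index$k))
  }
  reads <- reads[!short]
  keep <- vapply(reads, function(s) {
    L <- nchar(s)
    wins <- substring(s, 1:(L - index$k + 1L), index$k:L)
    if (both_strands) wins <- c(wins, revcomp(wins))
    !any(wins %in% index$kmers)
  }, logical(1), USE.NAMES = FALSE)
  out <- reads[keep]
  attr(out, "n_dropped_short") <- sum(short)
  out
}

#' Greedy overlap assembly of a small read set
#'
#' Deterministic overlap-layout assembly sized for the few reads that
#' survive the subtraction filters: identical reads collapse, contained
#' reads are absorbed, then the pair with the longest exact suffix-prefix
#' overlap of at least `min_overlap` is merged repeatedly; ties break
#' lexicographically on contig identifiers so results are independent of
#' read input order.
#'
#' @param reads named character vector (or read data frame).
#' @param min_overlap minimum exact overlap (nt) to merge.
#' @return named character vector of contigs.
#' @export
assemble_contigs <- function(reads, min_overlap = 30L) {
  reads <- as_read_vector(reads)
  if (!length(reads)) return(setNames(character(0), character(0)))
  min_overlap <- as.integer(min_overlap)
  if (min_overlap >= max(nchar(reads))) {
    xy_error("invalid 'min_overlap': must be below the read length",
             "xy_config_error")
  }
  # canonical order (independent of input order), collapse duplicates
  seqs <- sort(unique(unname(reads)))
  ids <- sprintf("c%06d", seq_along(seqs))
  pool <- new.env(parent = emptyenv())
  for (i in seq_along(seqs)) assign(ids[i], seqs[i], envir = pool)
  alive <- ids

  # seed index: every min_overlap-length window of every contig (an overlap
  # of length L >= min_overlap implies the suffix seed of one contig equals
  # the window starting at position L - min_overlap + 1 of the other)
  k0 <- min_overlap
  windows_of <- function(id) {
    s <- get(id, envir = pool)
    L <- nchar(s)
    data.table::data.table(id = id, pos = 1:(L - k0 + 1L),
                           win = substring(s, 1:(L - k0 + 1L), k0:L))
  }
  win_tab <- data.table::rbindlist(lapply(alive, windows_of))
  data.table::setkey(win_tab, win)

  suffix_of <- function(id) {
    s <- get(id, envir = pool)
    substr(s, nchar(s) - k0 + 1L, nchar(s))
  }

  repeat {
    if (length(alive) < 2L) break
    sfx <- data.table::data.table(a = alive,
                                  win = vapply(alive, suffix_of, character(1)))
    cand <- win_tab[sfx, on = "win", nomatch = NULL, allow.cartesian = TRUE]
    cand <- cand[cand$id != cand$a & cand$id %in% alive, ]
    if (!nrow(cand)) break
    len_a <- nchar(vapply(cand$a, get, character(1), envir = pool))
    len_b <- nchar(vapply(cand$id, get, character(1), envir = pool))
    cand$L <- cand$pos + k0 - 1L           # implied overlap length
    cand <- cand[cand$L <= pmin(len_a, len_b), ]
    if (!nrow(cand)) break
    data.table::setorder(cand, -L, a, id)
    picked <- NULL
    for (r in seq_len(nrow(cand))) {
      a <- get(cand$a[r], envir = pool); b <- get(cand$id[r], envir = pool)
      L <- cand$L[r]
      if (substr(a, nchar(a) - L + 1L, nchar(a)) == substr(b, 1L, L)) {
        picked <- list(a_id = cand$a[r], b_id = cand$id[r], L = L,
                       a = a, b = b)
        break
      }
    }
    if (is.null(picked)) break
    win_tab <- win_tab[!win_tab$id %in% c(picked$a_id, picked$b_id), ]
    alive <- setdiff(alive, c(picked$a_id, picked$b_id))
    if (picked$L == nchar(picked$b)) {       # b contained at the end of a
      new_seq <- picked$a
    } else if (picked$L == nchar(picked$a)) {  # a is a prefix of b
      new_seq <- picked$b
    } else {
      new_seq <- paste0(picked$a,
                        substr(picked$b, picked$L + 1L, nchar(picked$b)))
    }
    new_id <- min(picked$a_id, picked$b_id)
    assign(new_id, new_seq, envir = pool)
    alive <- c(alive, new_id)
    win_tab <- rbind(win_tab, windows_of(new_id))
    data.table::setkey(win_tab, win)
  }
  out <- vapply(sort(alive), get, character(1), envir = pool)
  setNames(unname(out), paste0("contig", seq_along(out)))
}

#' Validate candidate contigs as male-specific
#'
#' A contig is `ACCEPTED` when its best male-genome hit has 100% identity
#' over at least `male_min_frac` of its length and the female genome shows
#' no significant hit (identity >= `female_min_identity` over >=
#' `female_min_frac` of the contig).
#'
#' @param contigs named character vector of candidate transcripts.
#' @param male_genome,female_genome named character vectors of genome
#'   sequences.
#' @param aligner alignment function per the [seed_extend_align()] contract.
#' @param male_min_frac minimum aligned fraction at 100% identity in the
#'   male genome (default 0.9).
#' @param female_min_identity,female_min_frac thresholds defining a
#'   significant female hit (defaults 0.8 and 0.5).
#' @return data frame with one row per contig: hit metrics and `status`
#'   (`ACCEPTED`, `REJECTED_FEMALE_PRESENT`, `REJECTED_LOW_MALE_IDENTITY`).
#' @export
validate_male_specific <- function(contigs, male_genome, female_genome,
                                   aligner = seed_extend_align,
                                   male_min_frac = 0.9,
                                   female_min_identity = 0.8,
                                   female_min_frac = 0.5) {
  if (!length(male_genome) || !length(female_genome)) {
    xy_error("empty genome", "xy_config_error")
  }
  if (!length(contigs)) {
    return(data.frame(id = character(0), length = integer(0),
                      male_identity = numeric(0), male_frac = numeric(0),
                      female_identity = numeric(0), female_frac = numeric(0),
                      status = character(0)))
  }
  if (is.null(names(contigs))) names(contigs) <- paste0("contig", seq_along(contigs))
  mh <- aligner(contigs, male_genome)
  fh <- aligner(contigs, female_genome)
  get <- function(hits, id, col) {
    v <- hits[hits$query == id, col]
    if (length(v)) v[1L] else NA_real_
  }
  out <- data.frame(id = names(contigs), length = nchar(contigs),
                    stringsAsFactors = FALSE)
  out$male_identity <- vapply(out$id, get, numeric(1), hits = mh, col = "identity")
  out$male_frac <- vapply(out$id, get, numeric(1), hits = mh, col = "q_aligned_frac")
  out$female_identity <- vapply(out$id, get, numeric(1), hits = fh, col = "identity")
  out$female_frac <- vapply(out$id, get, numeric(1), hits = fh, col = "q_aligned_frac")
  female_present <- !is.na(out$female_identity) &
    out$female_identity >= female_min_identity &
    out$female_frac >= female_min_frac
  male_ok <- !is.na(out$male_identity) &
    out$male_identity >= 1 - 1e-9 & out$male_frac >= male_min_frac
  out$status <- ifelse(female_present, "REJECTED_FEMALE_PRESENT",
                       ifelse(male_ok, "ACCEPTED", "REJECTED_LOW_MALE_IDENTITY"))
  rownames(out) <- NULL
  out
}

#' Full subtraction pipeline
#'
#' Runs ambiguity filtering, the focal-sex genome filter, the opposite-sex
#' k-mer subtraction, greedy assembly, and male/female genome validation.
#' To search for W-linked transcripts instead, swap the arguments
#' (female reads as `target_reads`, male genome as `other_genome`, ...).
#'
#' @param target_reads RNA-seq reads of the heterogametic-candidate sex.
#' @param other_reads RNA-seq reads of the other sex (k-mer signature).
#' @param other_genome genome of the other sex (mapping filter; also the
#'   absence check during validation).
#' @param target_genome genome of the target sex (presence check).
#' @param k,min_count k-mer filter parameters (defaults 35 and 10).
#' @param min_overlap assembly overlap (default 30).
#' @param aligner validation aligner.
#' @return list with `candidates` (validation table), `contigs`,
#'   `accepted` (named character vector of accepted transcripts), and
#'   per-stage survivor counts in `stats`.
#' @export
subtract_pipeline <- function(target_reads, other_reads, other_genome,
                              target_genome, k = 35L, min_count = 10L,
                              min_overlap = 30L,
                              aligner = seed_extend_align) {
  target <- remove_ambiguous_reads(target_reads)
  other <- remove_ambiguous_reads(other_reads)
  unmapped <- filter_genome_mapped(target, other_genome)
  survivors <- unmapped
  if (length(unmapped)) {
    idx <- build_kmer_index(other, k = k, min_count = min_count)
    survivors <- subtract_by_kmers(unmapped, idx)
  }
  contigs <- assemble_contigs(survivors, min_overlap = min_overlap)
  candidates <- validate_male_specific(contigs, target_genome, other_genome,
                                       aligner = aligner)
  accepted <- contigs[candidates$id[candidates$status == "ACCEPTED"]]
  list(candidates = candidates, contigs = contigs, accepted = accepted,
       stats = c(n_input = length(target), n_unmapped = length(unmapped),
                 n_after_kmers = length(survivors),
                 n_contigs = length(contigs), n_accepted = length(accepted)))
}

#' Match accepted contigs to planted Y-specific transcripts
#'
#' Maps each accepted contig to the truth transcript containing it (exact
#' substring, either orientation) and scores transcript-level precision and
#' recall.
#'
#' @param accepted named character vector of accepted contigs.
#' @param truth a `sim_truth` with `y_transcripts`.
#' @return list: `precision`, `recall`, `matched_ids`, `contig_map`.
#' @export
score_y_recovery <- function(accepted, truth) {
  y <- truth$y_transcripts
  map <- vapply(accepted, function(ctg) {
    hit <- names(y)[vapply(y, function(t) {
      grepl(ctg, t, fixed = TRUE) || grepl(revcomp(ctg), t, fixed = TRUE)
    }, logical(1))]
    if (length(hit)) hit[1L] else NA_character_
  }, character(1))
  matched <- unique(map[!is.na(map)])
  precision <- if (length(accepted)) mean(!is.na(map)) else 1
  recall <- if (length(y)) length(matched) / length(y) else 1
  list(precision = precision, recall = recall, matched_ids = matched,
       contig_map = map)
}
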