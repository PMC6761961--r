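# Synthetic diploid XY genome with ground truth.
#
# The female genome carries autosomes plus an X; the male genome carries the
# same autosomes, the X, and a Y that is identical to the X inside the PAR
# segments and an independently decayed copy elsewhere: point substitutions
# accumulate at twice the neutral rate since the stratum's recombination
# arrest, small structural changes (indels) accumulate in parallel, and
# non-retained genes are deleted outright.

# deterministic largest-remainder apportionment of n into parts ~ weights
apportion <- function(n, weights) {
  if (!length(weights)) return(integer(0))
  raw <- n * weights / sum(weights)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# place k non-overlapping gene intervals of length L uniformly in [s, e)
place_genes <- function(k, s, e, L) {
  if (k == 0L) return(numeric(0))
  avail <- (e - s) - k * L
  if (avail < 0) {
    xy_error(sprintf("invalid 'n_genes': %d genes of %d bp do not fit in a %d bp region",
                     k, L, e - s), "xy_config_error")
  }
  offs <- sort(floor(runif(k, 0, avail + 1)))
  s + offs + (seq_len(k) - 1L) * L
}

# point substitutions (JC-observed probability q) then indels (lambda per
# base, tract length uniform on 1..max_tract, insertion/deletion equiprobable)
mutate_seq <- function(seq, q_sub, indel_lambda, max_tract = 8L) {
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  hit <- which(runif(n) < q_sub)
  if (length(hit)) {
    for (i in hit) chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  }
  n_indel <- rpois(1L, indel_lambda * n)
  if (n_indel > 0) {
    pos <- sort(sample.int(n, min(n_indel, n)))
    pieces <- character(0)
    prev <- 1L
    for (p in pos) {
      if (p < prev) next  # swallowed by a previous deletion
      tract <- sample.int(max_tract, 1L)
      if (runif(1) < 0.5) {  # deletion downstream of p
        pieces <- c(pieces, paste(chars[prev:p], collapse = ""))
        prev <- min(n + 1L, p + tract + 1L)
      } else {               # insertion after p
        pieces <- c(pieces, paste(chars[prev:p], collapse = ""), random_dna(tract))
        prev <- p + 1L
      }
      if (prev > n) break
    }
    if (prev <= n) pieces <- c(pieces, paste(chars[prev:n], collapse = ""))
    return(paste(pieces, collapse = ""))
  }
  paste(chars, collapse = "")
}

# expected observed per-base divergence after t Myr on both lineages at
# neutral rate r (Jukes-Cantor)
jc_observed_divergence <- function(rate, t_ma) {
  0.75 * (1 - exp(-4 / 3 * 2 * rate * t_ma))
}

#' Simulate a male/female genome pair with ground truth
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed; the same `(cfg, seed)` pair always yields identical
#'   genomes and truth.
#' @return a list of class `sim_genome` with elements `male` and `female`
#'   (named character vectors of chromosome sequences), and `truth` (class
#'   `sim_truth`): `regions` (chrom/start/end/class/stratum/arrest_time),
#'   `genes` (placement, class, stratum, Y retention and transcripts),
#'   `y_transcript_ids`, and the X/PAR geometry.
#' @export
simulate_genome_pair <- function(cfg, seed = NULL) {
  validate_sim_config(cfg)
  with_seed(seed, {
    gene_len <- 3L * cfg$n_codons_per_gene
    n_auto <- length(cfg$autosome_lengths)
    auto_names <- paste0("chr", seq_len(n_auto))

    autosomes <- setNames(
      vapply(cfg$autosome_lengths, random_dna, character(1)), auto_names)
    x_seq <- random_dna(cfg$x_length)

    # X region table in coordinate order
    regs <- rbind(
      do.call(rbind, lapply(cfg$par_segments, function(p) {
        data.frame(start = p[1], end = p[2], class = "PAR",
                   stratum = NA_integer_, arrest_time = NA_real_)
      })),
      do.call(rbind, lapply(seq_along(cfg$strata), function(i) {
        s <- cfg$strata[[i]]
        data.frame(start = s$interval[1], end = s$interval[2], class = "X_HEMI",
                   stratum = i, arrest_time = s$arrest_time)
      }))
    )
    regs <- regs[order(regs$start), , drop = FALSE]

    # gene placement: n_genes per autosome; n_genes on X apportioned to
    # regions by length
    genes <- list()
    for (a in seq_len(n_auto)) {
      starts <- place_genes(cfg$n_genes, 0, cfg$autosome_lengths[a], gene_len)
      if (length(starts)) {
        genes[[length(genes) + 1L]] <- data.frame(
          chrom = auto_names[a], start = starts, end = starts + gene_len,
          class = "AUTOSOME", stratum = NA_integer_, arrest_time = NA_real_)
      }
    }
    x_counts <- apportion(cfg$n_genes, regs$end - regs$start)
    for (r in seq_len(nrow(regs))) {
      starts <- place_genes(x_counts[r], regs$start[r], regs$end[r], gene_len)
      if (length(starts)) {
        genes[[length(genes) + 1L]] <- data.frame(
          chrom = "chrX", start = starts, end = starts + gene_len,
          class = ifelse(regs$class[r] == "PAR", "PAR", "X_HEMI"),
          stratum = regs$stratum[r], arrest_time = regs$arrest_time[r])
      }
    }
    genes <- if (length(genes)) do.call(rbind, genes) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 class = character(0), stratum = integer(0),
                 arrest_time = numeric(0))
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
    genes$gene_id <- sprintf("g%03d_%s", seq_len(nrow(genes)), genes$chrom)

    # per-stratum Y retention
    genes$on_y <- genes$class == "PAR"
    for (i in seq_along(cfg$strata)) {
      in_s <- which(!is.na(genes$stratum) & genes$stratum == i)
      keep_n <- round(cfg$y_gene_retention[i] * length(in_s))
      if (keep_n > 0) {
        genes$on_y[sample(in_s, keep_n)] <- TRUE
      }
    }
    genes$y_retained <- genes$on_y & genes$class == "X_HEMI"

    # build Y piecewise in X coordinate order: PAR verbatim; strata decayed,
    # with non-retained genes deleted and retained gene copies recorded
    y_pieces <- character(0)
    y_transcripts <- character(0)
    for (r in seq_len(nrow(regs))) {
      if (regs$class[r] == "PAR") {
        y_pieces <- c(y_pieces, substr(x_seq, regs$start[r] + 1L, regs$end[r]))
        next
      }
      q <- jc_observed_divergence(cfg$syn_rate, regs$arrest_time[r])
      lam <- 2 * cfg$y_indel_rate * regs$arrest_time[r]
      g_here <- genes[!is.na(genes$stratum) & genes$stratum == regs$stratum[r], ,
                      drop = FALSE]
      g_here <- g_here[order(g_here$start), , drop = FALSE]
      cuts <- sort(unique(c(regs$start[r], regs$end[r], g_here$start, g_here$end)))
      for (p in seq_len(length(cuts) - 1L)) {
        s0 <- cuts[p]; e0 <- cuts[p + 1L]
        piece <- substr(x_seq, s0 + 1L, e0)
        gi <- which(g_here$start == s0 & g_here$end == e0)
        if (length(gi)) {
          if (!g_here$y_retained[gi]) next  # gene deleted from the Y
          mut <- mutate_seq(piece, q, lam, cfg$y_indel_max)
          y_pieces <- c(y_pieces, mut)
          y_transcripts[paste0(g_here$gene_id[gi], "_Y")] <- mut
        } else {
          y_pieces <- c(y_pieces, mutate_seq(piece, q, lam, cfg$y_indel_max))
        }
      }
    }
    y_seq <- paste(y_pieces, collapse = "")

    regions <- rbind(
      data.frame(chrom = auto_names,
                 start = 0, end = cfg$autosome_lengths,
                 class = "AUTOSOMAL", stratum = NA_integer_,
                 arrest_time = NA_real_),
      data.frame(chrom = "chrX", start = regs$start, end = regs$end,
                 class = regs$class, stratum = regs$stratum,
                 arrest_time = regs$arrest_time))
    rownames(regions) <- NULL

    truth <- structure(list(
      regions = regions,
      genes = genes,
      y_transcript_ids = names(y_transcripts),
      y_transcripts = y_transcripts,
      x_length = cfg$x_length,
      par_segments = cfg$par_segments,
      strata = cfg$strata
    ), class = "sim_truth")

    structure(list(
      female = c(autosomes, chrX = x_seq),
      male = c(autosomes, chrX = x_seq, chrY = y_seq),
      truth = truth
    ), class = "sim_genome")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d genes (%d on Y, %d Y-specific transcripts), %d X regions\n",
              nrow(x$genes), sum(x$genes$on_y), length(x$y_transcript_ids),
              sum(x$regions$chrom == "chrX")))
  invisible(x)
}

#' Transcript sequences implied by a simulated genome pair
#'
#' Transcripts equal their gene's genomic sequence (no splicing is
#' simulated).  The female transcriptome contains every autosomal and
#' X-linked gene; the male transcriptome additionally contains the decayed Y
#' copies of retained gametologues.
#'
#' @param sim a `sim_genome` from [simulate_genome_pair()].
#' @return list with named character vectors `male` and `female`.
#' @export
sim_transcripts <- function(sim) {
  g <- sim$truth$genes
  base <- setNames(substr(sim$female[g$chrom], g$start + 1L, g$end), g$gene_id)
  list(female = base, male = c(base, sim$truth$y_transcripts))
}
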