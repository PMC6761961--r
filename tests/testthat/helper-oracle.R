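# Independent Nei-Gojobori counting oracle, written directly from the
# counting rules with explicit per-codon enumeration (no shared code with
# the package implementation).

oracle_genetic_code <- Biostrings::GENETIC_CODE

oracle_translate <- function(codon) unname(oracle_genetic_code[codon])

oracle_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa <- oracle_translate(codon)
  s <- 0
  for (p in 1:3) {
    for (b in bases) {
      if (b == substr(codon, p, p)) next
      alt <- codon
      substr(alt, p, p) <- b
      alt_aa <- oracle_translate(alt)
      if (alt_aa == "*") next  # change to a stop: nonsynonymous site
      if (alt_aa == aa) s <- s + 1 / 3
    }
  }
  s
}

# all orderings of a small set of positions
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# per codon pair: average syn/nonsyn differences over stop-free pathways
oracle_codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  walk <- function(order, allow_stops) {
    cur <- c1
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_translate(nxt) == "*" && nxt != c2 && !allow_stops) {
        return(NULL)
      }
      if (oracle_translate(cur) == "*" || oracle_translate(nxt) == "*") {
        nd <- nd + 1
      } else if (oracle_translate(cur) == oracle_translate(nxt)) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd, nd)
  }
  paths <- oracle_perms(pos)
  counted <- Filter(Negate(is.null), lapply(paths, walk, allow_stops = FALSE))
  if (!length(counted)) counted <- lapply(paths, walk, allow_stops = TRUE)
  Reduce(`+`, counted) / length(counted)
}

oracle_ds <- function(seq1, seq2) {
  stopifnot(nchar(seq1) == nchar(seq2), nchar(seq1) %% 3 == 0)
  n <- nchar(seq1) / 3
  c1 <- substring(seq1, 3 * (1:n) - 2, 3 * (1:n))
  c2 <- substring(seq2, 3 * (1:n) - 2, 3 * (1:n))
  S <- 0; Sd <- 0
  for (i in seq_len(n)) {
    S <- S + (oracle_syn_sites(c1[i]) + oracle_syn_sites(c2[i])) / 2
    Sd <- Sd + oracle_codon_diffs(c1[i], c2[i])[1]
  }
  pS <- Sd / S
  list(pS = pS,
       ds = if (pS >= 0.75) NA_real_ else -0.75 * log(1 - 4 * pS / 3))
}

# sense codons used to enumerate toy alignments
oracle_sense_codons <- setdiff(names(oracle_genetic_code),
                               c("TAA", "TAG", "TGA"))
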