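# Codon bookkeeping shared by the dS estimator and the gametologue simulator.
# The standard genetic code is taken from Biostrings; codons are handled as
# indices 1..64 in lexicographic (A,C,G,T) order.

.codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.codon_env$tables)) return(.codon_env$tables)
  bases <- DNA_BASES
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # outer() order: first index varies fastest; rebuild in plain lexicographic order
  codons <- sort(codons)
  gc_map <- Biostrings::GENETIC_CODE
  aa <- unname(gc_map[codons])
  is_stop <- aa == "*"

  # neighbours: for codon i, position p (1..3), alternative base b
  nt_of <- function(cod, p) substr(cod, p, p)
  mutate_codon <- function(cod, p, b) {
    substr(cod, p, p) <- b
    cod
  }
  idx <- setNames(seq_along(codons), codons)

  syn_alt <- vector("list", 64L)     # synonymous single-nt neighbours (sense)
  nonsyn_alt <- vector("list", 64L)  # nonsynonymous non-stop neighbours
  S_sites <- numeric(64L)
  for (i in seq_along(codons)) {
    if (is_stop[i]) { syn_alt[[i]] <- integer(0); nonsyn_alt[[i]] <- integer(0); next }
    syn <- integer(0); nonsyn <- integer(0); s <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, nt_of(codons[i], p))) {
        j <- idx[[mutate_codon(codons[i], p, b)]]
        if (is_stop[j]) {
          # mutations to stop codons count as nonsynonymous sites but are
          # never proposed by the simulator
          next
        }
        if (aa[j] == aa[i]) { syn <- c(syn, j); s <- s + 1 } else nonsyn <- c(nonsyn, j)
      }
    }
    syn_alt[[i]] <- syn
    nonsyn_alt[[i]] <- nonsyn
    S_sites[i] <- s / 3
  }
  N_sites <- ifelse(is_stop, NA_real_, 3 - S_sites)

  .codon_env$tables <- list(
    codons = codons, index = idx, aa = aa, is_stop = is_stop,
    syn_alt = syn_alt, nonsyn_alt = nonsyn_alt,
    S_sites = S_sites, N_sites = N_sites
  )
  .codon_env$tables
}

# Pairwise synonymous/nonsynonymous difference counts for every ordered codon
# pair, averaging over all mutational pathways that avoid stop-codon
# intermediates (Nei-Gojobori counting).  Built once and cached.
ng86_pair_tables <- function() {
  if (!is.null(.codon_env$pair)) return(.codon_env$pair)
  tb <- codon_tables()
  n <- 64L
  Sd <- matrix(0, n, n)
  Nd <- matrix(0, n, n)
  ok <- matrix(TRUE, n, n)  # FALSE when either codon is a stop

  diff_pos <- function(a, b) which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  step_counts <- function(u, v) {
    # u -> v differ at exactly one position
    if (tb$aa[u] == tb$aa[v]) c(1, 0) else c(0, 1)
  }
  perms <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L), c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L))
  )
  mutate_to <- function(cod, p, target) {
    substr(cod, p, p) <- substr(target, p, p)
    cod
  }
  for (i in seq_len(n)) {
    if (tb$is_stop[i]) { ok[i, ] <- FALSE; next }
    for (j in seq_len(n)) {
      if (tb$is_stop[j]) { ok[i, j] <- FALSE; next }
      if (i == j) next
      pos <- diff_pos(tb$codons[i], tb$codons[j])
      d <- length(pos)
      paths <- perms[[as.character(d)]]
      acc <- matrix(NA_real_, length(paths), 2L)
      blocked <- logical(length(paths))
      for (k in seq_along(paths)) {
        cur <- tb$codons[i]
        sd <- 0; nd <- 0
        for (p in pos[paths[[k]]]) {
          nxt <- mutate_to(cur, p, tb$codons[j])
          u <- tb$index[[cur]]; v <- tb$index[[nxt]]
          if (tb$is_stop[v] && nxt != tb$codons[j]) { blocked[k] <- TRUE; break }
          sc <- if (tb$aa[v] == "*" || tb$aa[u] == "*") c(0, 1) else step_counts(u, v)
          sd <- sd + sc[1]; nd <- nd + sc[2]
          cur <- nxt
        }
        if (!blocked[k]) acc[k, ] <- c(sd, nd)
      }
      use <- !blocked
      if (!any(use)) {
        # every pathway crosses a stop codon: fall back to averaging over all
        # pathways, scoring steps through stops as nonsynonymous
        for (k in seq_along(paths)) {
          cur <- tb$codons[i]; sd <- 0; nd <- 0
          for (p in pos[paths[[k]]]) {
            nxt <- mutate_to(cur, p, tb$codons[j])
            u <- tb$index[[cur]]; v <- tb$index[[nxt]]
            sc <- if (tb$aa[v] == "*" || tb$aa[u] == "*") c(0, 1) else step_counts(u, v)
            sd <- sd + sc[1]; nd <- nd + sc[2]
            cur <- nxt
          }
          acc[k, ] <- c(sd, nd)
        }
        use <- rep(TRUE, length(paths))
      }
      Sd[i, j] <- mean(acc[use, 1])
      Nd[i, j] <- mean(acc[use, 2])
    }
  }
  .codon_env$pair <- list(Sd = Sd, Nd = Nd, ok = ok)
  .codon_env$pair
}

# split a DNA string into codon indices; non-ACGT codons map to NA
seq_to_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) {
    xy_error("sequence length is not a multiple of 3", "xy_length_error")
  }
  tb <- codon_tables()
  cods <- substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  out <- unname(tb$index[cods])
  out[is.na(out)] <- NA_integer_
  out
}

codons_to_seq <- function(idx) {
  paste(codon_tables()$codons[idx], collapse = "")
}

# random sense codon indices (no stops)
random_codons <- function(n) {
  tb <- codon_tables()
  sense <- which(!tb$is_stop)
  sample(sense, n, replace = TRUE)
}
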