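# Codon-level evolution of XY gametologues on a fixed time-calibrated
# species tree.  The mutation model is Jukes-Cantor-like at the codon level
# with separate synonymous and nonsynonymous acceptance: synonymous events
# arrive at `syn_rate` per synonymous site per Myr and pick uniformly among
# the synonymous single-nucleotide neighbours of a codon, nonsynonymous
# events likewise among non-stop nonsynonymous neighbours, so the expected
# pairwise dS between two lineages separated t Myr ago is 2 * syn_rate * t.

# evolve a codon-index vector for `duration` Myr
evolve_codons <- function(cod, duration, syn_rate, nonsyn_rate) {
  if (duration <= 0) return(cod)
  tb <- codon_tables()
  n_syn_opt <- lengths(tb$syn_alt)
  n_non_opt <- lengths(tb$nonsyn_alt)
  # sites = options / 3 (Nei-Gojobori convention)
  s_sites <- sum(n_syn_opt[cod]) / 3
  n_sites <- sum(n_non_opt[cod]) / 3
  n_s <- rpois(1L, syn_rate * duration * s_sites)
  n_n <- rpois(1L, nonsyn_rate * duration * n_sites)
  w_s <- n_syn_opt[cod]
  w_n <- n_non_opt[cod]
  for (e in seq_len(n_s)) {
    i <- sample.int(length(cod), 1L, prob = w_s)
    alts <- tb$syn_alt[[cod[i]]]
    cod[i] <- alts[sample.int(length(alts), 1L)]
    w_s[i] <- n_syn_opt[cod[i]]; w_n[i] <- n_non_opt[cod[i]]
  }
  for (e in seq_len(n_n)) {
    i <- sample.int(length(cod), 1L, prob = w_n)
    alts <- tb$nonsyn_alt[[cod[i]]]
    cod[i] <- alts[sample.int(length(alts), 1L)]
    w_s[i] <- n_syn_opt[cod[i]]; w_n[i] <- n_non_opt[cod[i]]
  }
  cod
}

# recursively evolve down a rooted ultrametric tree; returns a list of codon
# vectors per tip label.  The focal tip is replaced by an X/Y pair that
# split arrest_time Ma.
evolve_tree <- function(tree, root_cod, focal, arrest_time, syn_rate, nonsyn_rate) {
  ntip <- length(tree$tip.label)
  ages <- ape::branching.times(tree)
  node_age <- function(node) {
    if (node <= ntip) 0 else unname(ages[as.character(node)])
  }
  root <- ntip + 1L
  out <- list()
  recurse <- function(node, cod) {
    children <- tree$edge[tree$edge[, 1L] == node, 2L]
    for (ch in children) {
      dur <- node_age(node) - node_age(ch)
      if (ch <= ntip && tree$tip.label[ch] == focal) {
        # evolve to the recombination arrest, then duplicate into X and Y
        pre <- evolve_codons(cod, dur - arrest_time, syn_rate, nonsyn_rate)
        out[["X"]] <<- evolve_codons(pre, arrest_time, syn_rate, nonsyn_rate)
        out[["Y"]] <<- evolve_codons(pre, arrest_time, syn_rate, nonsyn_rate)
      } else {
        child_cod <- evolve_codons(cod, dur, syn_rate, nonsyn_rate)
        if (ch <= ntip) out[[tree$tip.label[ch]]] <<- child_cod
        else recurse(ch, child_cod)
      }
    }
  }
  recurse(root, root_cod)
  out
}

#' Simulate XY gametologue codon alignments on a species tree
#'
#' X and Y copies are identical until the stratum's recombination arrest and
#' accumulate independent synonymous and nonsynonymous substitutions
#' afterwards; outgroup orthologues diverge at the tree's node ages.  No
#' internal stop codons are ever introduced.
#'
#' @param cfg a [sim_config()] supplying rates, codon counts, and the strata
#'   arrest times.
#' @param species_tree rooted ultrametric `ape::phylo` with branch lengths
#'   in Myr; must contain `focal`.
#' @param n_per_stratum number of gametologues simulated per stratum
#'   (default: the expected retained count per stratum under `cfg`).
#' @param focal tip label of the species carrying the XY pair.
#' @param seed RNG seed.
#' @return list of class `gametologue_sims`: per-gene records with
#'   `gene_id`, `stratum`, `arrest_time`, and `alignment` (named character
#'   vector with taxa `X`, `Y`, and the outgroups).  The attribute
#'   `topology` holds the matching dating topology in which the focal tip is
#'   replaced by an `(X, Y)` pair.
#' @export
simulate_gametologues <- function(cfg, species_tree = default_species_tree(),
                                  n_per_stratum = NULL,
                                  focal = "Basiliscus", seed = NULL) {
  validate_sim_config(cfg)
  if (!focal %in% species_tree$tip.label) {
    xy_error(sprintf("focal species '%s' not in tree", focal), "xy_config_error")
  }
  ntip <- length(species_tree$tip.label)
  focal_tip <- which(species_tree$tip.label == focal)
  parent <- species_tree$edge[species_tree$edge[, 2L] == focal_tip, 1L]
  focal_branch_age <- unname(ape::branching.times(species_tree)[as.character(parent)])
  arrests <- vapply(cfg$strata, function(s) as.numeric(s$arrest_time), numeric(1))
  if (any(arrests > focal_branch_age)) {
    xy_error(sprintf(
      "invalid 'strata': arrest_time %.1f Ma exceeds the focal lineage's origin (%.1f Ma)",
      max(arrests), focal_branch_age), "xy_config_error")
  }
  if (is.null(n_per_stratum)) {
    n_x <- apportion(cfg$n_genes, vapply(
      c(cfg$par_segments, lapply(cfg$strata, function(s) s$interval)),
      function(iv) iv[2] - iv[1], numeric(1)))
    strat_counts <- n_x[seq_along(cfg$strata) + length(cfg$par_segments)]
    n_per_stratum <- pmax(1L, round(cfg$y_gene_retention * strat_counts))
  }
  with_seed(seed, {
    recs <- list()
    for (s in seq_along(arrests)) {
      for (g in seq_len(n_per_stratum[s])) {
        root_cod <- random_codons(cfg$n_codons_per_gene)
        tips <- evolve_tree(species_tree, root_cod, focal, arrests[s],
                            cfg$syn_rate, cfg$nonsyn_rate)
        aln <- vapply(tips, codons_to_seq, character(1))
        recs[[length(recs) + 1L]] <- list(
          gene_id = sprintf("gam_s%d_%02d", s, g),
          stratum = s, arrest_time = arrests[s], alignment = aln)
      }
    }
    structure(recs, class = "gametologue_sims",
              topology = xy_topology(species_tree, focal))
  })
}

#' Dating topology with the focal tip replaced by an (X, Y) pair
#'
#' @param species_tree rooted `ape::phylo`.
#' @param focal tip label to replace.
#' @return `ape::phylo` with tips `X` and `Y` sister to the focal position.
#' @export
xy_topology <- function(species_tree, focal = "Basiliscus") {
  if (!focal %in% species_tree$tip.label) {
    xy_error(sprintf("focal species '%s' not in tree", focal), "xy_config_error")
  }
  nw <- ape::write.tree(species_tree)
  ape::read.tree(text = sub(focal, "(X:1,Y:1)", nw, fixed = TRUE))
}
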