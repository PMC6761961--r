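# Shared, lazily built fixtures.  Everything is generated in code under
# fixed seeds; the heavier objects are cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# default study-condition simulation: genome pair + DNA reads + depth
# tracks + coverage windows scored against truth
coverage_fixture <- function() {
  cache_get("coverage", function() {
    cfg <- sim_config()
    sim <- simulate_genome_pair(cfg, seed = 42)
    reads_m <- simulate_sex_reads(sim, "male", cfg$depth_male,
                                  cfg$read_length, seed = 421)
    reads_f <- simulate_sex_reads(sim, "female", cfg$depth_female,
                                  cfg$read_length, seed = 422)
    ref_len <- nchar(sim$female)
    tracks_m <- depth_from_hits(map_reads_exact(reads_m$seq, sim$female),
                                ref_len)
    tracks_f <- depth_from_hits(map_reads_exact(reads_f$seq, sim$female),
                                ref_len)
    windows <- coverage_scan(tracks_m, tracks_f, coverage_config(),
                             x_chrom = "chrX")
    list(cfg = cfg, sim = sim, reads_m = reads_m, reads_f = reads_f,
         tracks_m = tracks_m, tracks_f = tracks_f, windows = windows,
         score = score_window_labels(windows, sim$truth))
  })
}

# subtraction run on the same simulated individuals, plus the sex-swapped
# mirror run
subtract_fixture <- function() {
  cache_get("subtract", function() {
    fx <- coverage_fixture()
    tx <- sim_transcripts(fx$sim)
    rna_m <- simulate_reads(tx$male, fx$cfg$rna_depth, fx$cfg$read_length,
                            seed = 431, stranded = TRUE, id_prefix = "rnaM")
    rna_f <- simulate_reads(tx$female, fx$cfg$rna_depth, fx$cfg$read_length,
                            seed = 432, stranded = TRUE, id_prefix = "rnaF")
    res <- subtract_pipeline(rna_m, rna_f, fx$sim$female, fx$sim$male)
    mirror <- subtract_pipeline(rna_f, rna_m, fx$sim$male, fx$sim$female)
    list(rna_m = rna_m, rna_f = rna_f, res = res, mirror = mirror,
         scores = score_y_recovery(res$accepted, fx$sim$truth))
  })
}

# small two-taxon tree for closed-form divergence checks
two_taxon_tree <- function(depth = 200) {
  ape::read.tree(text = sprintf("(Basiliscus:%g,Anolis:%g);", depth, depth))
}

# single-stratum config for gametologue-only simulations
gametologue_cfg <- function(arrest, n_codons = 300L) {
  sim_config(strata = list(list(interval = c(0, 500000), arrest_time = arrest)),
             par_segments = list(), y_gene_retention = 1,
             n_codons_per_gene = n_codons)
}
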