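# Synthetic-data generator: configuration validation, genome construction,
# read arithmetic, codon evolution, expression regimes.

test_that("configuration errors name the offending field", {
  expect_error(sim_config(x_length = -1), "x_length",
               class = "xy_config_error")
  expect_error(sim_config(par_segments = list(c(0, 600000)),
                          strata = list()),
               "par_segments", class = "xy_config_error")
  expect_error(
    sim_config(par_segments = list(c(0, 100000), c(50000, 500000)),
               strata = list()),
    "disjoint", class = "xy_config_error")
  expect_error(sim_config(y_gene_retention = c(1.5, 0.2)),
               "y_gene_retention", class = "xy_config_error")
  expect_error(sim_config(dosage_model = "partial:2.5"),
               "dosage_model", class = "xy_config_error")
  expect_error(sim_config(dosage_model = "half"),
               "dosage_model", class = "xy_config_error")
})

test_that("genome pair respects PAR identity and Y decay", {
  fx <- coverage_fixture()
  sim <- fx$sim
  x <- sim$male[["chrX"]]; y <- sim$male[["chrY"]]
  # first PAR segment is copied verbatim to the start of the Y
  p1 <- sim$truth$par_segments[[1]]
  expect_identical(substr(y, p1[1] + 1, p1[2]), substr(x, p1[1] + 1, p1[2]))
  # the Y is shorter: genes were deleted
  expect_lt(nchar(y), nchar(x))
  # female genome has no Y
  expect_false("chrY" %in% names(sim$female))
  # every Y-specific transcript is a retained hemizygous gene
  g <- sim$truth$genes
  expect_setequal(sim$truth$y_transcript_ids,
                  paste0(g$gene_id[g$y_retained], "_Y"))
  expect_true(all(g$class[g$y_retained] == "X_HEMI"))
})

test_that("same seed gives identical genomes and truth", {
  cfg <- sim_config(autosome_lengths = 50000, x_length = 60000,
                    par_segments = list(c(0, 10000)),
                    strata = list(list(interval = c(10000, 60000),
                                       arrest_time = 62)),
                    y_gene_retention = 0.2, n_genes = 5,
                    n_codons_per_gene = 100)
  s1 <- simulate_genome_pair(cfg, seed = 7)
  s2 <- simulate_genome_pair(cfg, seed = 7)
  expect_identical(s1$male, s2$male)
  expect_identical(s1$female, s2$female)
  expect_identical(s1$truth$genes, s2$truth$genes)
  s3 <- simulate_genome_pair(cfg, seed = 8)
  expect_false(identical(s1$male, s3$male))
})

test_that("retention fractions reproduce the published Y gene count", {
  # 287 X genes in one stratum with retention 13/287 leaves 13 on the Y
  cfg <- sim_config(autosome_lengths = 100000, x_length = 300000,
                    par_segments = list(c(0, 750)),
                    strata = list(list(interval = c(750, 300000),
                                       arrest_time = 62)),
                    y_gene_retention = 13 / 287, n_genes = 287,
                    n_codons_per_gene = 100, read_length = 50)
  sim <- simulate_genome_pair(cfg, seed = 3)
  g <- sim$truth$genes
  expect_equal(sum(g$chrom == "chrX"), 287)
  expect_equal(sum(g$y_retained), 13)
  expect_length(sim$truth$y_transcript_ids, 13)
})

test_that("PAR covering all of X leaves no male-specific region", {
  cfg <- sim_config(autosome_lengths = 50000, x_length = 60000,
                    par_segments = list(c(0, 60000)), strata = list(),
                    y_gene_retention = numeric(0), n_genes = 5,
                    n_codons_per_gene = 100)
  sim <- simulate_genome_pair(cfg, seed = 1)
  expect_identical(sim$male[["chrY"]], sim$male[["chrX"]])
  expect_true(all(sim$truth$regions$class[sim$truth$regions$chrom == "chrX"]
                  == "PAR"))
  expect_length(sim$truth$y_transcript_ids, 0)
})

test_that("read count follows depth x length / read_length", {
  seqs <- c(chr1 = random_dna(1000000))
  reads <- simulate_reads(seqs, depth = 6, read_length = 100, seed = 2)
  expect_equal(nrow(reads), 60000)
  expect_true(all(nchar(reads$seq) == 100))
  # reads are genuine substrings (or reverse complements) of the template
  idx <- sample(nrow(reads), 20)
  for (i in idx) {
    fwd <- substr(seqs[[1]], reads$start[i] + 1, reads$start[i] + 100)
    expect_equal(reads$seq[i],
                 if (reads$strand[i] == "+") fwd else revcomp(fwd))
  }
})

test_that("read simulation rejects bad inputs", {
  expect_error(simulate_reads(character(0), 6, 100), class = "xy_config_error")
  expect_error(simulate_reads(c(a = "ACGTACGT"), 6, read_length = 100),
               class = "xy_config_error")
})

test_that("summed read bases match the configured depth within 1%", {
  seqs <- c(chr1 = random_dna(1500000))
  reads <- simulate_reads(seqs, depth = 4, read_length = 100, seed = 9)
  realised <- nrow(reads) * 100 / nchar(seqs[[1]])
  expect_lt(abs(realised / 4 - 1), 0.01)
})

test_that("gametologue dS matches 2 * rate * arrest_time in expectation", {
  cfg <- gametologue_cfg(50, n_codons = 300L)
  gams <- simulate_gametologues(cfg, two_taxon_tree(85.7),
                                n_per_stratum = 40, seed = 12)
  ds <- vapply(gams, function(r)
    pairwise_ds(r$alignment[["X"]], r$alignment[["Y"]])$ds, numeric(1))
  expected <- 2 * cfg$syn_rate * 50
  se <- sd(ds) / sqrt(length(ds))
  expect_lt(abs(mean(ds) - expected), 2 * se + 0.002)
  # no internal stop codons anywhere
  for (r in gams[1:5]) {
    for (s in r$alignment) {
      cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
      expect_false(any(head(cods, -1) %in% c("TAA", "TAG", "TGA")))
    }
  }
})

test_that("arrest time zero gives identical X and Y copies", {
  cfg <- gametologue_cfg(0)
  gams <- simulate_gametologues(cfg, two_taxon_tree(85.7),
                                n_per_stratum = 1, seed = 4)
  aln <- gams[[1]]$alignment
  expect_identical(aln[["X"]], aln[["Y"]])
  expect_equal(pairwise_ds(aln[["X"]], aln[["Y"]])$ds, 0)
})

test_that("older strata show larger mean X/Y divergence", {
  cfg <- sim_config(n_codons_per_gene = 200L)  # strata at 62 and 20 Ma
  gams <- simulate_gametologues(cfg, default_species_tree(),
                                n_per_stratum = c(8, 8), seed = 6)
  ds <- vapply(gams, function(r)
    pairwise_ds(r$alignment[["X"]], r$alignment[["Y"]])$ds, numeric(1))
  strat <- vapply(gams, `[[`, integer(1), "stratum")
  expect_gt(mean(ds[strat == 1]), mean(ds[strat == 2]))
})

test_that("arrest beyond the focal lineage origin is rejected", {
  cfg <- gametologue_cfg(100)
  expect_error(simulate_gametologues(cfg, two_taxon_tree(85.7),
                                     n_per_stratum = 1, seed = 1),
               class = "xy_config_error")
})

test_that("expression regimes produce the expected median log2 ratios", {
  tr <- expression_truth(200, 500)
  med_of <- function(model, seed) {
    cfg <- sim_config(dosage_model = model, tissues = "liver")
    es <- simulate_expression(tr, cfg, seed = seed)
    median(mf_log2_ratios(es, "liver"))
  }
  expect_lt(abs(med_of("full", 31)), 0.05)
  expect_lt(abs(med_of("none", 32) - (-1)), 0.1)
  expect_lt(abs(med_of("partial:1.5", 33) - log2(1.5 / 2)), 0.1)
})

test_that("Y gametologue rows exist only for retained genes and only in males", {
  tr <- expression_truth(50, 50, n_y_retained = 5)
  cfg <- sim_config(tissues = c("liver", "brain"))
  es <- simulate_expression(tr, cfg, seed = 8)
  y_rows <- es$genes$gene_id[es$genes$class == "Y"]
  expect_length(y_rows, 5)
  s <- es$samples
  female_cols <- s$sample_id[s$sex == "female" & s$species == "focal"]
  male_cols <- s$sample_id[s$sex == "male" & s$species == "focal"]
  expect_true(all(es$values[y_rows, female_cols] == 0))
  expect_true(all(es$values[y_rows, male_cols] > 0))
})
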