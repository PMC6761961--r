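# End-to-end orchestration: one seed drives every stage, each stage consumes
# only the simulator's outputs, and the run report records recovery scores
# against the ground truth.

#' Write simulation ground truth as JSON
#' @param truth a `sim_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(list(
    regions = truth$regions, genes = truth$genes,
    y_transcript_ids = truth$y_transcript_ids,
    x_length = truth$x_length, par_segments = truth$par_segments
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Generate a self-contained fixture dataset on disk
#'
#' Simulates the default study conditions and writes every interface file:
#' male/female genomes (FASTA), DNA and RNA reads (gzipped FASTQ),
#' transcripts (FASTA), gametologue codon alignments (FASTA), the species
#' topology (Newick), the TPM matrix and sample metadata (TSV), and the
#' ground truth (JSON).
#'
#' @param seed root RNG seed; per-stage streams are derived from it.
#' @param outdir output directory (created if needed).
#' @param cfg a [sim_config()].
#' @param n_gametologues_per_stratum alignments written per stratum.
#' @return named list of file paths (the manifest), invisibly; the
#'   in-memory objects are attached as attribute `objects`.
#' @export
generate_fixtures <- function(seed, outdir, cfg = sim_config(),
                              n_gametologues_per_stratum = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, paste0(...))
  sim <- simulate_genome_pair(cfg, seed = derive_seed(seed, 1L))
  reads_m <- simulate_sex_reads(sim, "male", cfg$depth_male, cfg$read_length,
                                seed = derive_seed(seed, 2L),
                                error_rate = cfg$error_rate)
  reads_f <- simulate_sex_reads(sim, "female", cfg$depth_female,
                                cfg$read_length,
                                seed = derive_seed(seed, 3L),
                                error_rate = cfg$error_rate)
  tx <- sim_transcripts(sim)
  rna_m <- simulate_reads(tx$male, cfg$rna_depth, cfg$read_length,
                          seed = derive_seed(seed, 4L), stranded = TRUE,
                          id_prefix = "rnaM")
  rna_f <- simulate_reads(tx$female, cfg$rna_depth, cfg$read_length,
                          seed = derive_seed(seed, 5L), stranded = TRUE,
                          id_prefix = "rnaF")
  tree <- default_species_tree()
  gams <- simulate_gametologues(cfg, tree,
                                n_per_stratum = n_gametologues_per_stratum,
                                seed = derive_seed(seed, 6L))
  es <- simulate_expression(sim$truth, cfg, seed = derive_seed(seed, 7L))

  write_fasta(sim$male, p("male_genome.fa"))
  write_fasta(sim$female, p("female_genome.fa"))
  write_fastq(reads_m, p("male_dna.fastq.gz"))
  write_fastq(reads_f, p("female_dna.fastq.gz"))
  write_fastq(rna_m, p("male_rna.fastq.gz"))
  write_fastq(rna_f, p("female_rna.fastq.gz"))
  write_fasta(tx$male, p("male_transcripts.fa"))
  write_fasta(tx$female, p("female_transcripts.fa"))
  ape::write.tree(tree, p("species_tree.nwk"))
  dir.create(p("gametologues"), showWarnings = FALSE)
  for (rec in gams) {
    write_fasta(rec$alignment, file.path(outdir, "gametologues",
                                         paste0(rec$gene_id, ".fa")))
  }
  tpm_long <- data.frame(
    gene_id = rep(rownames(es$values), times = ncol(es$values)),
    sample_id = rep(colnames(es$values), each = nrow(es$values)),
    tpm = as.vector(es$values))
  write.table(tpm_long, p("tpm.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(es$samples, p("samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(es$genes, p("gene_classes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_sim_truth(sim$truth, p("truth.json"))

  manifest <- list(
    male_genome = p("male_genome.fa"), female_genome = p("female_genome.fa"),
    male_dna = p("male_dna.fastq.gz"), female_dna = p("female_dna.fastq.gz"),
    male_rna = p("male_rna.fastq.gz"), female_rna = p("female_rna.fastq.gz"),
    male_transcripts = p("male_transcripts.fa"),
    female_transcripts = p("female_transcripts.fa"),
    species_tree = p("species_tree.nwk"),
    gametologue_dir = p("gametologues"),
    tpm = p("tpm.tsv"), samples = p("samples.tsv"),
    gene_classes = p("gene_classes.tsv"), truth = p("truth.json"))
  attr(manifest, "objects") <- list(sim = sim, reads_m = reads_m,
                                    reads_f = reads_f, rna_m = rna_m,
                                    rna_f = rna_f, transcripts = tx,
                                    gametologues = gams, expression = es,
                                    tree = tree)
  invisible(manifest)
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes the enabled stages in order (simulate, coverage, subtract,
#' dating, dosage) under one root seed and reports per-stage results plus
#' recovery scores against the simulation truth.  Identical configuration
#' and seed yield an identical report.
#'
#' @param config list with elements `seed` (root seed), `stages` (character
#'   subset of the five stage names; default all), `cfg` (a [sim_config()]),
#'   `calibration_age_ma` (default 85.7), `n_boot` (default 100), and
#'   `outdir` (optional; report written there as JSON).
#' @return the run report (list).
#' @export
run_pipeline <- function(config = list()) {
  stages_all <- c("simulate", "coverage", "subtract", "dating", "dosage")
  stages <- if (is.null(config$stages)) stages_all else config$stages
  if (!all(stages %in% stages_all)) {
    xy_error("invalid 'stages': unknown stage name", "xy_config_error")
  }
  cfg <- if (is.null(config$cfg)) sim_config() else config$cfg
  seed <- if (is.null(config$seed)) 1L else config$seed
  report <- list(seed = seed, stages = stages)
  if (!length(stages)) {
    if (!is.null(config$outdir)) write_report(report, config$outdir)
    return(report)
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      xy_error(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "xy_stage_error")
    })
  }

  sim <- NULL
  if (any(stages != "simulate") || "simulate" %in% stages) {
    sim <- run_stage("simulate", function()
      simulate_genome_pair(cfg, seed = derive_seed(seed, 1L)))
    report$simulate <- list(
      n_genes = nrow(sim$truth$genes),
      n_y_transcripts = length(sim$truth$y_transcript_ids))
  }

  if ("coverage" %in% stages) {
    cov <- run_stage("coverage", function() {
      reads_m <- simulate_sex_reads(sim, "male", cfg$depth_male,
                                    cfg$read_length, derive_seed(seed, 2L))
      reads_f <- simulate_sex_reads(sim, "female", cfg$depth_female,
                                    cfg$read_length, derive_seed(seed, 3L))
      ref_len <- nchar(sim$female)
      tr_m <- depth_from_hits(map_reads_exact(reads_m$seq, sim$female), ref_len)
      tr_f <- depth_from_hits(map_reads_exact(reads_f$seq, sim$female), ref_len)
      windows <- coverage_scan(tr_m, tr_f, coverage_config(), x_chrom = "chrX")
      score_window_labels(windows, sim$truth)
    })
    report$coverage <- list(
      label_accuracy = cov$accuracy,
      mean_male_depth_x_hemi = cov$mean_male_depth_x_hemi,
      n_windows = nrow(cov$windows))
  }

  if ("subtract" %in% stages) {
    sub <- run_stage("subtract", function() {
      tx <- sim_transcripts(sim)
      rna_m <- simulate_reads(tx$male, cfg$rna_depth, cfg$read_length,
                              derive_seed(seed, 4L), stranded = TRUE,
                              id_prefix = "rnaM")
      rna_f <- simulate_reads(tx$female, cfg$rna_depth, cfg$read_length,
                              derive_seed(seed, 5L), stranded = TRUE,
                              id_prefix = "rnaF")
      res <- subtract_pipeline(rna_m, rna_f, sim$female, sim$male)
      scores <- score_y_recovery(res$accepted, sim$truth)
      list(res = res, scores = scores)
    })
    report$subtract <- list(
      stats = as.list(sub$res$stats),
      precision = sub$scores$precision, recall = sub$scores$recall)
  }

  if ("dating" %in% stages) {
    dat <- run_stage("dating", function() {
      tree <- if (is.null(config$species_tree)) default_species_tree()
              else config$species_tree
      gams <- simulate_gametologues(cfg, tree, seed = derive_seed(seed, 6L))
      s1 <- Filter(function(r) r$stratum == 1L, gams)
      dated <- date_xy_from_alignments(
        lapply(s1, `[[`, "alignment"), attr(gams, "topology"),
        calibration_tips = c("X", "Anolis"),
        calibration_age_ma = if (is.null(config$calibration_age_ma)) 85.7
                             else config$calibration_age_ma,
        n_boot = if (is.null(config$n_boot)) 100L else config$n_boot,
        seed = derive_seed(seed, 8L))
      mean_ds <- mean(vapply(s1, function(r)
        pairwise_ds(r$alignment[["X"]], r$alignment[["Y"]])$ds, numeric(1)))
      list(dated = dated, mean_ds = mean_ds,
           truth_arrest = s1[[1L]]$arrest_time)
    })
    report$dating <- list(
      xy_age_ma = dat$dated$xy_age_ma, ci95 = dat$dated$ci95,
      mean_stratum1_ds = dat$mean_ds, truth_arrest_ma = dat$truth_arrest)
  }

  if ("dosage" %in% stages) {
    dos <- run_stage("dosage", function() {
      es <- simulate_expression(sim$truth, cfg, derive_seed(seed, 7L))
      calls <- dosage_calls(es)
      list(calls = calls, consensus = attr(calls, "consensus"))
    })
    report$dosage <- list(
      calls = dos$calls, consensus = dos$consensus,
      expected_call = expected_dosage_call(cfg$dosage_model))
  }

  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

expected_dosage_call <- function(model) {
  f <- resolve_dosage_model(model, "any")[[1L]]
  if (f >= 2) "BALANCED" else if (f <= 1) "UNCOMPENSATED" else "INTERMEDIATE"
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
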