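#!/usr/bin/env Rscript
# Stage 2 -- sex-linkage detection from male/female read depth.
#
# Maps both sexes' genomic reads to the female-assembled reference, averages
# depth in 100 kb windows on autosomes and 10 kb windows on the candidate X,
# and classifies each window from the male/female log2 depth ratio: ~0 means
# two copies in both sexes (autosomal, or PAR on the X), ~-1 means
# hemizygous in males.  Scored against the simulation truth.

suppressPackageStartupMessages(library(xyturnover))

fx <- "scratch/fixtures"
if (!file.exists(file.path(fx, "female_genome.fa"))) {
  stop("run analysis/01_simulate.R first")
}
female <- read_fasta(file.path(fx, "female_genome.fa"))
reads_m <- read_fastq(file.path(fx, "male_dna.fastq.gz"))
reads_f <- read_fastq(file.path(fx, "female_dna.fastq.gz"))
truth <- jsonlite::read_json(file.path(fx, "truth.json"),
                             simplifyVector = TRUE)

message("mapping ", nrow(reads_m), " male and ", nrow(reads_f),
        " female reads")
ref_len <- nchar(female)
tracks_m <- depth_from_hits(map_reads_exact(reads_m$seq, female), ref_len)
tracks_f <- depth_from_hits(map_reads_exact(reads_f$seq, female), ref_len)

cfg <- coverage_config()
windows <- coverage_scan(tracks_m, tracks_f, cfg, x_chrom = "chrX")
score <- score_window_labels(windows, truth)

write_windows_bed(score$windows, "results/02_coverage_windows.bed")
message(sprintf("label accuracy %.3f; mean male depth over X-hemizygous windows %.2fx",
                score$accuracy, score$mean_male_depth_x_hemi))
message("window table written to results/02_coverage_windows.bed")
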