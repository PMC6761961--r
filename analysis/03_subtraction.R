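#!/usr/bin/env Rscript
# Stage 3 -- Y-specific transcript discovery by read subtraction.
#
# Male RNA-seq reads are filtered against the female genome, screened
# against the abundant 35-mer signature of the female transcriptome
# (frequency >= 10, exact matches only), assembled with the greedy overlap
# assembler, and validated: accepted transcripts show 100% identity over
# >= 90% of their length in the male genome and no significant female hit.
# The sex-swapped mirror run is the W-chromosome control: on an XY system
# it must come back empty.

suppressPackageStartupMessages(library(xyturnover))

fx <- "scratch/fixtures"
if (!file.exists(file.path(fx, "male_rna.fastq.gz"))) {
  stop("run analysis/01_simulate.R first")
}
male_genome <- read_fasta(file.path(fx, "male_genome.fa"))
female_genome <- read_fasta(file.path(fx, "female_genome.fa"))
rna_m <- read_fastq(file.path(fx, "male_rna.fastq.gz"))
rna_f <- read_fastq(file.path(fx, "female_rna.fastq.gz"))
truth <- jsonlite::read_json(file.path(fx, "truth.json"), simplifyVector = TRUE)

message("forward run: male-specific transcript discovery")
res <- subtract_pipeline(rna_m, rna_f, female_genome, male_genome)
print(res$stats)

# score against planted Y transcripts (the truth JSON stores ids; sequences
# live in the male transcript FASTA)
tx_male <- read_fasta(file.path(fx, "male_transcripts.fa"))
truth_obj <- structure(list(
  y_transcripts = tx_male[intersect(names(tx_male), truth$y_transcript_ids)]),
  class = "sim_truth")
sc <- score_y_recovery(res$accepted, truth_obj)
message(sprintf("accepted %d contigs; transcript precision %.2f recall %.2f",
                length(res$accepted), sc$precision, sc$recall))

message("mirror run: W-linked search with the sexes swapped")
mir <- subtract_pipeline(rna_f, rna_m, male_genome, female_genome)
message("mirror accepted: ", mir$stats[["n_accepted"]],
        " (zero expected on an XY system)")

write.table(res$candidates, "results/03_candidate_transcripts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_fasta(res$accepted, "results/03_accepted_y_transcripts.fa")
message("candidate table in results/03_candidate_transcripts.tsv")
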