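Package: xyturnover
Title: Detection and Dating of Sex Chromosome Turnover from Read Coverage,
    Transcript Subtraction, and Gametologue Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and characterise a sex chromosome system
    replacement from short-read genome and transcriptome data, exercised
    end-to-end on synthetic data with known ground truth.  The package
    implements male/female windowed read-depth ratios for sex-linkage
    detection (pseudoautosomal versus hemizygous regions), a k-mer
    subtraction pipeline that discovers Y-specific transcripts from
    sex-pooled RNA-seq reads, Nei-Gojobori synonymous divergence (dS)
    between XY gametologues with evolutionary strata assignment, dS-tree
    calibration with codon bootstrap confidence intervals to date the
    recombination arrest, and dosage-compensation statistics (fixed-median
    ratio tests, gametologue expression balance, tissue-specificity index).
    A simulation module generates diploid XY genomes with pseudoautosomal
    segments and age-structured strata, uniform-coverage reads, codon
    alignments evolving on a calibrated species tree, and TPM expression
    matrices under full, partial, or absent dosage compensation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    phangorn,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
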