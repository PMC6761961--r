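# TPM expression simulator.  Per-gene baseline means are log-normal;
# per-allele output is half the diploid baseline; the single male X allele
# in the hemizygous region is scaled by the tissue's dosage factor (full
# compensation 2, none 1, partial c in [1, 2]); gametologues with a
# retained Y copy express both alleles without upregulation, so their
# X+Y output balances the female X output.  Observed TPM adds log-normal
# multiplicative noise.

#' Minimal truth object for expression-only simulations
#'
#' Builds a gene table of the shape produced by [simulate_genome_pair()]
#' for studies that only need the expression model.
#'
#' @param n_autosome,n_x_hemi,n_par,n_y_retained gene counts per class
#'   (`n_y_retained` of the hemizygous genes keep a Y copy).
#' @return a `sim_truth`-like list with a `genes` data frame.
#' @export
expression_truth <- function(n_autosome = 500L, n_x_hemi = 500L, n_par = 0L,
                             n_y_retained = 0L) {
  stopifnot(n_y_retained <= n_x_hemi)
  classes <- c(rep("AUTOSOME", n_autosome), rep("X_HEMI", n_x_hemi),
               rep("PAR", n_par))
  genes <- data.frame(
    gene_id = sprintf("g%04d_%s", seq_along(classes),
                      c(rep("a", n_autosome), rep("x", n_x_hemi),
                        rep("p", n_par))),
    chrom = c(rep("chr1", n_autosome), rep("chrX", n_x_hemi + n_par)),
    class = classes, stringsAsFactors = FALSE)
  genes$y_retained <- FALSE
  if (n_y_retained > 0) {
    genes$y_retained[n_autosome + seq_len(n_y_retained)] <- TRUE
  }
  genes$on_y <- genes$y_retained | genes$class == "PAR"
  y_ids <- if (any(genes$y_retained)) {
    paste0(genes$gene_id[genes$y_retained], "_Y")
  } else character(0)
  structure(list(genes = genes, y_transcript_ids = y_ids),
            class = "sim_truth")
}

#' Simulate a TPM expression matrix
#'
#' @param truth a `sim_truth` (from [simulate_genome_pair()] or
#'   [expression_truth()]).
#' @param cfg a [sim_config()] supplying `tissues`, `dosage_model` and
#'   `tpm_dispersion`.
#' @param seed RNG seed.
#' @param outgroup_species outgroup species names; each contributes one
#'   sample per tissue in which former X genes are autosomal (two alleles,
#'   ancestral level).
#' @param mean_log,sd_log log-normal parameters of the per-gene baseline
#'   diploid mean TPM.
#' @param y_expression_factor per-allele activity of retained Y copies
#'   relative to the X allele (default 1: balanced gametologues).
#' @return an `expr_set`; the element `expected` records the expected mean
#'   per (gene, sex, tissue) of the focal species.
#' @export
simulate_expression <- function(truth, cfg, seed = NULL,
                                outgroup_species = c("outgroupA", "outgroupB"),
                                mean_log = log(30), sd_log = 1,
                                y_expression_factor = 1) {
  validate_sim_config(cfg)
  g <- truth$genes
  dosage <- resolve_dosage_model(cfg$dosage_model, cfg$tissues)
  with_seed(seed, {
    base <- exp(rnorm(nrow(g), mean_log, sd_log))  # diploid baseline mean
    names(base) <- g$gene_id
    y_ret <- if ("y_retained" %in% names(g)) g$y_retained else
      g$on_y & g$class == "X_HEMI"

    gene_rows <- data.frame(gene_id = g$gene_id,
                            class = ifelse(g$class == "X_HEMI", "X", g$class),
                            stringsAsFactors = FALSE)
    y_ids <- if (any(y_ret)) paste0(g$gene_id[y_ret], "_Y") else character(0)
    gene_rows <- rbind(gene_rows,
                       data.frame(gene_id = y_ids,
                                  class = rep("Y", length(y_ids)),
                                  stringsAsFactors = FALSE))

    focal <- expand.grid(sex = c("female", "male"), tissue = cfg$tissues,
                         stringsAsFactors = FALSE)
    focal$species <- "focal"
    outg <- if (length(outgroup_species)) {
      data.frame(sex = "pooled",
                 tissue = rep(cfg$tissues, times = length(outgroup_species)),
                 species = rep(outgroup_species, each = length(cfg$tissues)),
                 stringsAsFactors = FALSE)
    } else NULL
    samples <- rbind(focal, outg)
    samples$sample_id <- sprintf("%s_%s_%s", samples$species, samples$sex,
                                 samples$tissue)

    expected_for <- function(species, sex, tissue) {
      allele <- base / 2
      exp_gene <- numeric(nrow(g))
      if (species != "focal") {
        exp_gene[] <- base        # autosomal in the outgroup: two alleles
      } else if (sex == "female") {
        exp_gene[] <- base        # autosomes, PAR, and two X copies
      } else {
        exp_gene[] <- base
        hemi <- g$class == "X_HEMI"
        exp_gene[hemi & !y_ret] <- allele[hemi & !y_ret] * dosage[[tissue]]
        exp_gene[hemi & y_ret] <- allele[hemi & y_ret]  # balanced by the Y copy
      }
      exp_y <- if (species == "focal" && sex == "male") {
        allele[y_ret] * y_expression_factor
      } else rep(0, sum(y_ret))
      c(exp_gene, exp_y)
    }

    vals <- vapply(seq_len(nrow(samples)), function(i) {
      mu <- expected_for(samples$species[i], samples$sex[i], samples$tissue[i])
      noise <- exp(rnorm(length(mu), 0, cfg$tpm_dispersion))
      mu * noise
    }, numeric(nrow(gene_rows)))
    dimnames(vals) <- list(gene_rows$gene_id, samples$sample_id)

    es <- expr_set(vals, samples, gene_rows)
    exp_tab <- do.call(rbind, lapply(which(samples$species == "focal"),
      function(i) {
        data.frame(gene = gene_rows$gene_id, sex = samples$sex[i],
                   tissue = samples$tissue[i],
                   mean = expected_for("focal", samples$sex[i],
                                       samples$tissue[i]),
                   stringsAsFactors = FALSE)
      }))
    es$expected <- exp_tab
    es
  })
}
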