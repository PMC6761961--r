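#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic-data generator:
#' chromosome lengths, pseudoautosomal (PAR) segments, evolutionary strata
#' with their recombination-arrest times, per-stratum Y gene retention,
#' sequencing depths, codon substitution rates, and the expression model.
#'
#' Defaults describe the study conditions the downstream analyses assume: a
#' diploid genome with two autosomes and an X carrying two PAR segments and
#' two strata (arrest 62 and 20 Ma), both sexes sequenced at 6x with 100-nt
#' reads, a synonymous rate of 0.002 substitutions per synonymous site per
#' Myr, and partial dosage compensation (factor 1.5) in six tissues.
#'
#' @param autosome_lengths base-pair lengths of the autosomes.
#' @param x_length base-pair length of the X chromosome.
#' @param par_segments list of 0-based half-open `c(start, end)` intervals on
#'   the X that keep recombining (copied verbatim to the Y).
#' @param strata list of `list(interval = c(start, end), arrest_time = Ma)`
#'   entries; together with `par_segments` they must tile `[0, x_length)`
#'   without overlap.
#' @param y_gene_retention fraction of genes per stratum whose Y copy is
#'   retained (the rest are deleted from the Y).
#' @param n_genes number of genes placed uniformly on each chromosome.
#' @param read_length read length in nt.
#' @param depth_female,depth_male total (diploid) fold coverage per
#'   individual; each haplotype is sampled at half this depth.
#' @param syn_rate,nonsyn_rate synonymous / nonsynonymous substitution rates
#'   (per site per Myr).
#' @param n_codons_per_gene codons per gene (gene length is 3x this).
#' @param dosage_model `"full"`, `"none"`, or `"partial:<c>"` with
#'   `1 <= c <= 2`; either a single value for all tissues or a named
#'   per-tissue vector.
#' @param tissues tissue names for the expression simulator.
#' @param tpm_dispersion log-normal sigma (natural log) of the multiplicative
#'   TPM noise.
#' @param y_indel_rate rate of small structural changes (indels) per site per
#'   Myr on the non-recombining Y; a compact proxy for the structural decay
#'   that makes Y-specific sequence unalignable to the X.
#' @param y_indel_max maximum indel tract length (nt).
#' @param error_rate per-base read error rate (default 0; the downstream
#'   filters assume near-exact matching).
#' @param rna_depth fold coverage of simulated RNA-seq reads per transcript.
#' @return a validated `sim_config` object (list).
#' @export
sim_config <- function(autosome_lengths = c(250000L, 250000L),
                       x_length = 500000L,
                       par_segments = list(c(0L, 60000L), c(440000L, 500000L)),
                       strata = list(
                         list(interval = c(60000L, 260000L), arrest_time = 62),
                         list(interval = c(260000L, 440000L), arrest_time = 20)),
                       y_gene_retention = c(0.20, 0.15),
                       n_genes = 40L,
                       read_length = 100L,
                       depth_female = 6,
                       depth_male = 6,
                       syn_rate = 0.002,
                       nonsyn_rate = 0.0004,
                       n_codons_per_gene = 300L,
                       dosage_model = "partial:1.5",
                       tissues = c("blood", "brain", "heart", "liver",
                                   "kidney", "gonad"),
                       tpm_dispersion = 0.5,
                       y_indel_rate = 0.001,
                       y_indel_max = 8L,
                       error_rate = 0,
                       rna_depth = 30) {
  cfg <- list(autosome_lengths = as.numeric(autosome_lengths),
              x_length = as.numeric(x_length),
              par_segments = lapply(par_segments, as.numeric),
              strata = strata,
              y_gene_retention = as.numeric(y_gene_retention),
              n_genes = as.integer(n_genes),
              read_length = as.integer(read_length),
              depth_female = depth_female, depth_male = depth_male,
              syn_rate = syn_rate, nonsyn_rate = nonsyn_rate,
              n_codons_per_gene = as.integer(n_codons_per_gene),
              dosage_model = dosage_model, tissues = tissues,
              tpm_dispersion = tpm_dispersion,
              y_indel_rate = y_indel_rate, y_indel_max = as.integer(y_indel_max),
              error_rate = error_rate, rna_depth = rna_depth)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    xy_error(sprintf("invalid '%s': %s", field, why), "xy_config_error")
  }
  if (length(cfg$autosome_lengths) < 1L || any(cfg$autosome_lengths <= 0)) {
    bad("autosome_lengths", "all lengths must be > 0")
  }
  if (cfg$x_length <= 0) bad("x_length", "must be > 0")
  ivs <- c(cfg$par_segments,
           lapply(cfg$strata, function(s) as.numeric(s$interval)))
  labs <- c(rep("par_segments", length(cfg$par_segments)),
            rep("strata", length(cfg$strata)))
  for (i in seq_along(ivs)) {
    iv <- ivs[[i]]
    if (length(iv) != 2L || iv[1] < 0 || iv[2] > cfg$x_length || iv[1] >= iv[2]) {
      bad(labs[i], sprintf("interval [%s, %s) must be non-empty and within [0, x_length)",
                           iv[1], iv[2]))
    }
  }
  if (length(ivs)) {
    ord <- order(vapply(ivs, `[`, numeric(1), 1L))
    sorted <- ivs[ord]
    for (i in seq_along(sorted)[-1L]) {
      if (sorted[[i]][1] < sorted[[i - 1L]][2]) {
        bad(labs[ord[i]], "PAR and strata intervals must be disjoint")
      }
    }
    starts <- vapply(sorted, `[`, numeric(1), 1L)
    ends <- vapply(sorted, `[`, numeric(1), 2L)
    if (starts[1] != 0 || ends[length(ends)] != cfg$x_length ||
        any(starts[-1L] != ends[-length(ends)])) {
      bad("strata", "PAR and strata intervals must tile [0, x_length) completely")
    }
  } else {
    bad("par_segments", "PAR and strata intervals must tile [0, x_length)")
  }
  at <- vapply(cfg$strata, function(s) as.numeric(s$arrest_time), numeric(1))
  if (length(at) && any(at < 0)) bad("strata", "arrest_time must be >= 0")
  if (length(cfg$y_gene_retention) != length(cfg$strata)) {
    bad("y_gene_retention", "one retention fraction per stratum required")
  }
  if (any(cfg$y_gene_retention < 0 | cfg$y_gene_retention > 1)) {
    bad("y_gene_retention", "fractions must lie in [0, 1]")
  }
  if (cfg$n_genes < 0) bad("n_genes", "must be >= 0")
  if (cfg$read_length <= 0) bad("read_length", "must be > 0")
  if (cfg$depth_female <= 0) bad("depth_female", "must be > 0")
  if (cfg$depth_male <= 0) bad("depth_male", "must be > 0")
  if (cfg$syn_rate < 0) bad("syn_rate", "must be >= 0")
  if (cfg$nonsyn_rate < 0) bad("nonsyn_rate", "must be >= 0")
  if (cfg$n_codons_per_gene <= 0) bad("n_codons_per_gene", "must be > 0")
  if (!length(cfg$tissues)) bad("tissues", "must be non-empty")
  if (cfg$tpm_dispersion < 0) bad("tpm_dispersion", "must be >= 0")
  if (cfg$error_rate < 0 || cfg$error_rate > 1) bad("error_rate", "must be in [0, 1]")
  vapply(resolve_dosage_model(cfg$dosage_model, cfg$tissues), identity, numeric(1))
  invisible(cfg)
}

# dosage model -> per-tissue diploid-equivalent factor for the single male X
# allele: full -> 2, none -> 1, partial(c) -> c with 1 <= c <= 2
resolve_dosage_model <- function(model, tissues) {
  one <- function(m) {
    if (is.numeric(m)) {
      if (m < 1 || m > 2) xy_error("invalid 'dosage_model': partial factor must be in [1, 2]",
                                   "xy_config_error")
      return(as.numeric(m))
    }
    m <- as.character(m)
    if (m == "full") return(2)
    if (m == "none") return(1)
    if (grepl("^partial:", m)) {
      c_val <- suppressWarnings(as.numeric(sub("^partial:", "", m)))
      if (is.na(c_val) || c_val < 1 || c_val > 2) {
        xy_error("invalid 'dosage_model': partial factor must be in [1, 2]",
                 "xy_config_error")
      }
      return(c_val)
    }
    xy_error(sprintf("invalid 'dosage_model': unknown model '%s'", m),
             "xy_config_error")
  }
  if (length(model) == 1L && is.null(names(model))) {
    return(setNames(rep(one(model[[1L]]), length(tissues)), tissues))
  }
  if (is.null(names(model)) || !all(tissues %in% names(model))) {
    xy_error("invalid 'dosage_model': per-tissue models must be named for every tissue",
             "xy_config_error")
  }
  setNames(vapply(tissues, function(t) one(model[[t]]), numeric(1)), tissues)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  cat(sprintf("  autosomes: %s bp; X: %s bp (%d PAR segments, %d strata)\n",
              paste(format(x$autosome_lengths, big.mark = ","), collapse = ", "),
              format(x$x_length, big.mark = ","),
              length(x$par_segments), length(x$strata)))
  for (i in seq_along(x$strata)) {
    cat(sprintf("  stratum %d: [%s, %s) arrest %.1f Ma, Y retention %.2f\n", i,
                x$strata[[i]]$interval[1], x$strata[[i]]$interval[2],
                x$strata[[i]]$arrest_time, x$y_gene_retention[i]))
  }
  cat(sprintf("  %d genes/chromosome of %d codons; depth F %.1fx / M %.1fx; reads %d nt\n",
              x$n_genes, x$n_codons_per_gene, x$depth_female, x$depth_male,
              x$read_length))
  invisible(x)
}
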