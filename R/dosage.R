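# Expression-side analyses: median-scaling normalisation, ancestral
# expression inference from outgroup orthologues, fixed-median ratio tests
# with Benjamini-Hochberg correction, gametologue expression balance, and
# the tissue-specificity index.

#' Expression matrix container
#'
#' @param values numeric genes x samples TPM matrix with dimnames.
#' @param samples data frame with columns `sample_id`, `sex`, `tissue`,
#'   `species` (rows match columns of `values`).
#' @param genes data frame with columns `gene_id`, `class` (one of
#'   `AUTOSOME`, `X`, `Y`, `PAR`) and optionally `orth_group`.
#' @return object of class `expr_set`.
#' @export
expr_set <- function(values, samples, genes) {
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) {
    xy_error("invalid 'values': TPM must be >= 0", "xy_config_error")
  }
  if (nrow(values) != nrow(genes) || ncol(values) != nrow(samples)) {
    xy_error("invalid 'values': dimensions do not match metadata", "xy_config_error")
  }
  need_s <- c("sample_id", "sex", "tissue", "species")
  if (!all(need_s %in% names(samples)) || anyNA(samples[need_s])) {
    xy_error("invalid 'samples': metadata must be complete", "xy_config_error")
  }
  if (!all(c("gene_id", "class") %in% names(genes)) || anyNA(genes$class)) {
    xy_error("invalid 'genes': metadata must be complete", "xy_config_error")
  }
  rownames(values) <- genes$gene_id
  colnames(values) <- samples$sample_id
  structure(list(values = values, samples = samples, genes = genes),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples (%s)\n", nrow(x$values),
              ncol(x$values), paste(unique(x$samples$species), collapse = ", ")))
  invisible(x)
}

#' Median-scaling normalisation across samples
#'
#' Scales every sample so the median TPM of a shared set of one-to-one
#' orthologous genes (expressed in all samples) equals the grand median of
#' those per-sample medians.  Applying the procedure twice equals applying
#' it once.
#'
#' @param x an `expr_set` or a genes x samples matrix.
#' @param shared_genes gene identifiers of the shared orthologue set; every
#'   one must have TPM > 0 in every sample.
#' @return the normalised object, with per-sample scale factors in the
#'   attribute `scale_factors`.
#' @export
median_scale_normalize <- function(x, shared_genes) {
  mat <- if (inherits(x, "expr_set")) x$values else as.matrix(x)
  shared_genes <- intersect(shared_genes, rownames(mat))
  if (!length(shared_genes)) {
    xy_error("empty shared orthologue set", "xy_config_error")
  }
  sub <- mat[shared_genes, , drop = FALSE]
  if (any(sub <= 0)) {
    xy_error("shared orthologues must be expressed (TPM > 0) in all samples",
             "xy_config_error")
  }
  med <- apply(sub, 2L, median)
  grand <- median(med)
  factors <- grand / med
  out <- sweep(mat, 2L, factors, `*`)
  if (inherits(x, "expr_set")) {
    x$values <- out
    attr(x, "scale_factors") <- factors
    return(x)
  }
  attr(out, "scale_factors") <- factors
  out
}

#' Infer ancestral per-allele expression from outgroup orthologues
#'
#' The ancestral (proto-sex-chromosome) expression of an X-linked gene is
#' estimated as the median expression of its autosomal one-to-one
#' orthologues in outgroup species, divided by 2 to express it per allele.
#'
#' @param outgroup_tpms numeric vector of outgroup TPM values for one gene,
#'   or a genes x outgroups matrix.
#' @return per-allele ancestral level(s); `NA` (exclusion flag) for genes
#'   with no outgroup data.
#' @export
infer_ancestral_expression <- function(outgroup_tpms) {
  one <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    median(v) / 2
  }
  if (is.matrix(outgroup_tpms)) {
    apply(outgroup_tpms, 1L, one)
  } else {
    one(outgroup_tpms)
  }
}

#' One-sample fixed-median ratio test
#'
#' Wilcoxon signed-rank test of the log2 ratios against a fixed reference
#' median (0: equal expression; -1: halved expression).  This
#' operationalises the rank test "against a distribution with fixed median"
#' as a one-sample test, since a two-sample test against a constant is
#' degenerate.
#'
#' @param log2_ratios finite log2 expression ratios (at least 5).
#' @param fixed_median reference median (0 or -1 in the standard analysis).
#' @return list with `n`, `median`, `p` (unadjusted).
#' @export
ratio_test <- function(log2_ratios, fixed_median) {
  r <- log2_ratios[is.finite(log2_ratios)]
  if (length(r) < 5L) {
    xy_error("fewer than 5 finite ratios", "xy_config_error")
  }
  p <- if (all(r == fixed_median)) 1 else {
    suppressWarnings(
      wilcox.test(r, mu = fixed_median, exact = FALSE, correct = TRUE)$p.value)
  }
  list(n = length(r), median = median(r), p = p)
}

#' Per-gene male/female log2 expression ratios for one tissue
#'
#' Averages TPM over same-sex replicates, adds a 0.1 TPM pseudocount to
#' each side, and excludes genes below 1 TPM in both sexes (expression
#' floor).
#'
#' @param es an `expr_set` (focal species).
#' @param tissue tissue name.
#' @param classes gene classes to include (default `"X"`).
#' @param floor_tpm expression floor (default 1).
#' @param pseudocount added to each side before the log (default 0.1).
#' @return named numeric vector of log2(male/female) ratios.
#' @export
mf_log2_ratios <- function(es, tissue, classes = "X", floor_tpm = 1,
                           pseudocount = 0.1) {
  s <- es$samples
  keep_g <- es$genes$class %in% classes
  m_cols <- s$sample_id[s$tissue == tissue & s$sex == "male"]
  f_cols <- s$sample_id[s$tissue == tissue & s$sex == "female"]
  if (!length(m_cols) || !length(f_cols)) {
    xy_error(sprintf("no male/female samples for tissue '%s'", tissue),
             "xy_config_error")
  }
  m <- rowMeans(es$values[keep_g, m_cols, drop = FALSE])
  f <- rowMeans(es$values[keep_g, f_cols, drop = FALSE])
  ok <- m >= floor_tpm | f >= floor_tpm
  log2((m[ok] + pseudocount) / (f[ok] + pseudocount))
}

#' Dosage-compensation calls per tissue
#'
#' For every tissue, tests the male/female log2 ratios of X-linked genes
#' against fixed medians 0 and -1, applies Benjamini-Hochberg correction
#' across the whole (tissue x reference) family, and derives the call:
#' `INTERMEDIATE` iff both tests reject at `alpha`, `BALANCED` when only
#' the -1 reference is rejected, `UNCOMPENSATED` when only 0 is rejected,
#' `INCONCLUSIVE` otherwise.  The dataset-level consensus is the modal
#' tissue call.
#'
#' @param es an `expr_set`.
#' @param tissues tissues to analyse (default: all in the metadata).
#' @param alpha significance level after BH correction (default 0.05).
#' @param classes gene classes tested (default `"X"`).
#' @param floor_tpm,pseudocount see [mf_log2_ratios()].
#' @return data frame (one row per tissue) with `n_genes`,
#'   `median_log2_ratio`, `p_vs_0`, `p_vs_minus1` (BH-adjusted) and `call`;
#'   the attribute `consensus` holds the modal call.
#' @export
dosage_calls <- function(es, tissues = NULL, alpha = 0.05, classes = "X",
                         floor_tpm = 1, pseudocount = 0.1) {
  if (is.null(tissues)) {
    tissues <- unique(es$samples$tissue[es$samples$sex %in% c("male", "female")])
  }
  rows <- lapply(tissues, function(tis) {
    r <- mf_log2_ratios(es, tis, classes, floor_tpm, pseudocount)
    t0 <- ratio_test(r, 0)
    t1 <- ratio_test(r, -1)
    data.frame(tissue = tis, n_genes = t0$n, median_log2_ratio = t0$median,
               p_vs_0 = t0$p, p_vs_minus1 = t1$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  adj <- p.adjust(c(out$p_vs_0, out$p_vs_minus1), method = "BH")
  out$p_vs_0 <- adj[seq_len(nrow(out))]
  out$p_vs_minus1 <- adj[nrow(out) + seq_len(nrow(out))]
  rej0 <- out$p_vs_0 < alpha
  rej1 <- out$p_vs_minus1 < alpha
  out$call <- ifelse(rej0 & rej1, "INTERMEDIATE",
                     ifelse(rej1, "BALANCED",
                            ifelse(rej0, "UNCOMPENSATED", "INCONCLUSIVE")))
  tab <- sort(table(out$call), decreasing = TRUE)
  consensus <- if (length(tab) && (length(tab) == 1L || tab[1L] > tab[2L])) {
    names(tab)[1L]
  } else "INCONCLUSIVE"
  attr(out, "consensus") <- consensus
  out
}

#' Gametologue expression balance
#'
#' Compares the added expression of the X and Y copies in males with the X
#' expression in females: `log2((x_male + y_male + p) / (x_female + p))`
#' with a pseudocount `p` added once per side.
#'
#' @param x_male,y_male,x_female TPM values (vectorised).
#' @param pseudocount default 0.1.
#' @return log2 balance ratio(s); 0 means the male X+Y output matches the
#'   female X output.
#' @export
gametologue_balance <- function(x_male, y_male, x_female, pseudocount = 0.1) {
  log2((x_male + y_male + pseudocount) / (x_female + pseudocount))
}

#' Tissue-specificity index
#'
#' TSI = expression in the tissue with the highest expression divided by
#' the summed expression across all tissues; ranges from 1/T (uniform) to 1
#' (single-tissue).  The conventional specificity call threshold is 0.7.
#'
#' @param x numeric vector of per-tissue expression for one gene, or a
#'   genes x tissues matrix.
#' @return TSI value(s); all-zero genes are flagged `NA`.
#' @export
tsi <- function(x) {
  one <- function(v) {
    if (length(v) < 2L) xy_error("TSI needs >= 2 tissues", "xy_config_error")
    s <- sum(v)
    if (s == 0) return(NA_real_)
    max(v) / s
  }
  if (is.matrix(x)) apply(x, 1L, one) else one(x)
}

#' Per-gene log2 current/ancestral expression ratios
#'
#' @param es an `expr_set` (focal species).
#' @param tissue,sex sample selector.
#' @param ancestral named per-allele ancestral levels (from
#'   [infer_ancestral_expression()]); genes with `NA` are excluded.
#' @param classes gene classes (default `"X"`).
#' @param pseudocount added to each side (default 0.1).
#' @return named numeric vector of log2(current/ancestral).
#' @export
current_ancestral_ratios <- function(es, tissue, sex, ancestral,
                                     classes = "X", pseudocount = 0.1) {
  s <- es$samples
  cols <- s$sample_id[s$tissue == tissue & s$sex == sex]
  if (!length(cols)) xy_error("no samples match", "xy_config_error")
  keep <- es$genes$class %in% classes & es$genes$gene_id %in% names(ancestral)
  cur <- rowMeans(es$values[keep, cols, drop = FALSE])
  anc <- ancestral[es$genes$gene_id[keep]]
  ok <- !is.na(anc)
  log2((cur[ok] + pseudocount) / (anc[ok] + pseudocount))
}
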