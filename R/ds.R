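#' Pairwise synonymous divergence between two coding sequences
#'
#' Nei-Gojobori (1986) counting: synonymous and nonsynonymous sites are
#' averaged over the two sequences, differences are counted per codon pair by
#' averaging over all mutational pathways that avoid stop-codon
#' intermediates, and the proportion of synonymous differences is corrected
#' for multiple hits with the Jukes-Cantor formula
#' \eqn{dS = -\frac{3}{4}\log(1 - \frac{4}{3} p_S)}.
#'
#' Codons containing non-ACGT characters (gaps, ambiguity codes) in either
#' sequence are excluded pairwise from the site and difference counts.
#'
#' @param cds_a,cds_b DNA strings of equal length, a multiple of 3, with no
#'   internal stop codons.
#' @return a list with elements `ds`, `dn`, `pS`, `pN`, `S`, `N`, `Sd`, `Nd`
#'   and `n_codons_used`.
#' @examples
#' pairwise_ds(strrep("GGT", 10), paste0(strrep("GGT", 9), "GGC"))$ds
#' @export
pairwise_ds <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) {
    xy_error("coding sequences differ in length", "xy_length_error")
  }
  ca <- seq_to_codons(toupper(cds_a))
  cb <- seq_to_codons(toupper(cds_b))
  tb <- codon_tables()
  # internal stop check ignores a terminal stop and ambiguous codons
  check_stops <- function(ci, label) {
    known <- which(!is.na(ci))
    internal <- known[known < length(ci)]
    if (any(tb$is_stop[ci[internal]])) {
      xy_error(sprintf("internal stop codon in %s", label), "xy_stop_error")
    }
  }
  check_stops(ca, "first sequence")
  check_stops(cb, "second sequence")

  usable <- !is.na(ca) & !is.na(cb) & !tb$is_stop[ca] & !tb$is_stop[cb]
  usable[is.na(usable)] <- FALSE
  if (!any(usable)) xy_error("no usable codons in alignment", "xy_length_error")
  ca <- ca[usable]; cb <- cb[usable]

  pt <- ng86_pair_tables()
  S <- (sum(tb$S_sites[ca]) + sum(tb$S_sites[cb])) / 2
  N <- (sum(tb$N_sites[ca]) + sum(tb$N_sites[cb])) / 2
  Sd <- sum(pt$Sd[cbind(ca, cb)])
  Nd <- sum(pt$Nd[cbind(ca, cb)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  if (pS >= 0.75) {
    xy_error(sprintf("synonymous sites saturated (pS = %.3f >= 0.75)", pS),
             "xy_saturation_error")
  }
  ds <- -0.75 * log(1 - 4 * pS / 3)
  dn <- if (pN < 0.75) -0.75 * log(1 - 4 * pN / 3) else NA_real_
  list(ds = ds, dn = dn, pS = pS, pN = pN, S = S, N = N, Sd = Sd, Nd = Nd,
       n_codons_used = length(ca))
}

#' Pairwise dS distance matrix for a codon alignment
#'
#' @param alignment named character vector of aligned coding sequences
#'   (equal lengths, multiple of 3).
#' @return symmetric numeric matrix of dS values with taxon dimnames.  A
#'   saturated pair raises an error naming the pair.
#' @export
ds_matrix <- function(alignment) {
  taxa <- names(alignment)
  if (is.null(taxa) || anyDuplicated(taxa)) {
    xy_error("alignment must have unique taxon names", "xy_config_error")
  }
  n <- length(alignment)
  m <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      d <- tryCatch(
        pairwise_ds(alignment[[i]], alignment[[j]])$ds,
        xy_saturation_error = function(e) {
          xy_error(sprintf("saturated pair: %s / %s", taxa[i], taxa[j]),
                   "xy_saturation_error")
        }
      )
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}
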