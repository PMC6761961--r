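#' Assign an XY gametologue to an evolutionary stratum
#'
#' Presence of the Y copy in an outgroup species of the same family is the
#' authoritative evidence: a gametologue whose Y copy predates the focal /
#' outgroup species split belongs to the older stratum (1), otherwise to the
#' younger stratum (2).  When presence evidence is missing, the dS threshold
#' provides a provisional call (dS above the threshold suggests the older
#' stratum).  When both are available the presence evidence overrides the
#' threshold.
#'
#' @param ds numeric vector of pairwise X/Y dS values (`NA` when the X copy
#'   could not be analysed).
#' @param outgroup_presence logical vector: Y copy detected in the outgroup
#'   species (`NA` when untested).
#' @param ds_threshold provisional dS cutoff separating older from younger
#'   gametologues (default 0.2).
#' @return integer vector of stratum assignments (1, 2, or `NA` when neither
#'   line of evidence is available).
#' @export
classify_stratum <- function(ds, outgroup_presence, ds_threshold = 0.2) {
  n <- max(length(ds), length(outgroup_presence))
  ds <- rep_len(as.numeric(ds), n)
  pres <- rep_len(as.logical(outgroup_presence), n)
  out <- rep(NA_integer_, n)
  out[!is.na(pres) & pres] <- 1L
  out[!is.na(pres) & !pres] <- 2L
  prov <- is.na(pres) & !is.na(ds)
  out[prov] <- ifelse(ds[prov] > ds_threshold, 1L, 2L)
  out
}

#' Published XY gametologue evidence table
#'
#' Loads the packaged table of the twelve protein-coding Y-linked genes of
#' *Basiliscus vittatus*: pairwise X/Y dS and whether the Y copy amplified in
#' *Corytophanes hernandesii* (the second corytophanid clade).
#'
#' @return data frame with columns `gene`, `type`, `ds`, `y_in_outgroup`
#'   (logical) and `stratum` (from [classify_stratum()]).
#' @export
gametologue_table <- function() {
  path <- system.file("extdata", "gametologue_evidence.tsv",
                      package = "xyturnover", mustWork = TRUE)
  tab <- read.table(path, header = TRUE, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE)
  tab$y_in_outgroup <- tolower(tab$y_in_outgroup) == "yes"
  tab$stratum <- classify_stratum(tab$ds, tab$y_in_outgroup)
  tab
}
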